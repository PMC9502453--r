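test_that("MSP parsing handles well-formed, incomplete and malformed entries", {
    msp <- c(
        "Name: alpha",
        "DB#: REC1",
        "Instrument_type: ESI-QFT",
        "Ion_mode: P",
        "Precursor_type: [M+H]+",
        "PrecursorMZ: 301.10728",
        "MW: 300.1",
        "Collision_energy: 35 V",
        "Num Peaks: 2",
        "100.1 50",
        "200.2 100",
        "",
        "NAME=beta",
        "DB#=REC2",
        "INSTRUMENT_TYPE=LC-ESI-QTOF",
        "ION_MODE=P",
        "PRECURSOR_TYPE=[M+Na]+",
        "Num Peaks: 1",
        "150.0\t80",
        "")
    f <- withr::local_tempfile(lines = msp)
    recs <- readSpectra(f, canonicalize = FALSE)
    expect_equal(nSpectra(recs), 2L)
    expect_equal(parseReport(recs)$n_skipped, 0L)
    ## order preserved
    expect_equal(recordIds(recs), c("REC1", "REC2"))
    m <- spectrumMeta(recs)
    ## both metadata dialects parsed
    expect_equal(m$collision_energy_value, c(35, NA))
    expect_equal(m$collision_energy_unit[1], "V")
    expect_equal(m$precursor_type, c("[M+H]+", "[M+Na]+"))
    ## missing fields are absent, not guessed
    expect_true(is.na(m$precursor_mz[2]))

    ## a malformed peak line skips that entry only
    f2 <- withr::local_tempfile(lines = c(msp, "Name: gamma",
                                          "Num Peaks: 1", "abc def", ""))
    expect_message(recs2 <- readSpectra(f2, canonicalize = FALSE),
                   "malformed")
    expect_equal(nSpectra(recs2), 2L)
    expect_equal(parseReport(recs2)$n_skipped, 1L)

    expect_error(readSpectra(file.path(tempdir(), "no_such_file.msp")),
                 "cannot read")
})

test_that("spectra round-trip through both dialects", {
    ds <- generateSynth(tinySynthConfig(n_compounds = 5))
    for (dialect in c("msp", "tabular")) {
        f <- withr::local_tempfile()
        writeSpectra(ds$records, f, dialect = dialect)
        back <- readSpectra(f, dialect = dialect, canonicalize = FALSE)
        expect_equal(nSpectra(back), nSpectra(ds$records))
        expect_equal(recordIds(back), recordIds(ds$records))
        expect_equal(peakLists(back), peakLists(ds$records),
                     tolerance = 0)
        m0 <- spectrumMeta(ds$records); m1 <- spectrumMeta(back)
        expect_equal(m1$precursor_mz, m0$precursor_mz)
        expect_equal(m1$collision_energy_value, m0$collision_energy_value)
    }
})

test_that("collision-energy fields parse across vendor spellings", {
    ce <- parseCollisionEnergy(c("35", "35 V", "35 eV", "35V", "HCD 35%",
                                 "NCE 40.5%", "", "n/a"))
    expect_equal(ce$value, c(35, 35, 35, 35, 35, 40.5, NA, NA))
    expect_equal(ce$unit, c(NA, "V", "eV", "V", "%", "%", NA, NA))
})

test_that("instrument standardisation is canonical, flagged and idempotent", {
    out <- standardizeInstrument(c("ESI-QFT", "LC-ESI-QFT", "MYSTERY-9000"))
    expect_equal(as.character(out),
                 c("LC-ESI-QFT", "LC-ESI-QFT", "MYSTERY-9000"))
    expect_equal(attr(out, "flagged"), c(FALSE, FALSE, TRUE))
    ## idempotence: f(f(x)) == f(x) for arbitrary labels
    labels <- c("ESI-QTOF", "Q-TOF", "esi-itft", "weird", "LC-ESI-QQ")
    once <- as.character(standardizeInstrument(labels))
    twice <- as.character(standardizeInstrument(once))
    expect_identical(twice, once)
})

test_that("sparse matrices round-trip bit-exactly", {
    set.seed(5)
    m <- matrix(0, 3, 5, dimnames = list(paste0("s", 1:3), paste0("b", 1:5)))
    m[sample(15, 7)] <- runif(7)
    f <- withr::local_tempfile()
    writeSparseMatrix(m, f)
    back <- readSparseMatrix(f)
    expect_identical(as.matrix(back), m)

    ## SpectralMatrix keeps its grid
    ds <- generateSynth(tinySynthConfig(n_compounds = 4))
    sm <- binSpectra(ds$records, ds$config$grid)
    writeSparseMatrix(sm, f)
    back2 <- readSparseMatrix(f)
    expect_s4_class(back2, "SpectralMatrix")
    expect_equal(nBins(back2), nBins(sm))
    expect_identical(as.matrix(matrixValues(back2)),
                     as.matrix(matrixValues(sm)))

    ## degenerate: zero rows
    empty <- matrix(numeric(0), 0, 4,
                    dimnames = list(NULL, paste0("b", 1:4)))
    writeSparseMatrix(empty, f)
    expect_equal(dim(readSparseMatrix(f)), c(0L, 4L))

    ## sparse encoding stores exactly the nonzeros
    one <- matrix(0, 4, 4); one[2, 3] <- 0.25
    writeSparseMatrix(one, f)
    expect_equal(sum(startsWith(readLines(f), "x\t")), 1L)
})

test_that("compound ids fall back inchikey -> smiles -> name", {
    meta <- data.frame(
        record_id = c("a", "b", "c", "d"),
        inchikey = c("KEY1", NA, NA, NA),
        smiles = c("CCO", "OC1=CC=CC=C1", NA, NA),
        name = c("x", "y", "Gamma Acid", NA),
        stringsAsFactors = FALSE)
    id <- deriveCompoundId(meta, canonicalize = FALSE)
    expect_equal(id, c("KEY1", "OC1=CC=CC=C1", "gamma acid", "d"))
    ## canonicalisation merges equivalent SMILES spellings
    meta2 <- data.frame(record_id = c("a", "b"),
                        inchikey = NA_character_,
                        smiles = c("OC1=CC=CC=C1", "c1ccccc1O"),
                        name = c("p1", "p2"), stringsAsFactors = FALSE)
    id2 <- deriveCompoundId(meta2, canonicalize = TRUE)
    expect_equal(id2[1], id2[2])
})
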