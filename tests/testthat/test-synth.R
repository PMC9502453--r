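test_that("bit-peak maps have the right shape and are seed-deterministic", {
    cfg <- tinySynthConfig(seed = 51)
    map <- makeBitPeakMap(cfg)
    expect_length(map, 166L)
    expect_true(all(lengths(map) == 3L))
    ## bins are drawn from the grid, no two bits share a bin
    all_mz <- unlist(map)
    expect_true(all(all_mz %in% binCenters(cfg$grid)))
    expect_equal(anyDuplicated(all_mz), 0L)
    expect_identical(makeBitPeakMap(cfg), map)
    ## pigeonhole: 10 bits, 1 peak each, 10-bin grid -> a permutation
    cfg10 <- synthConfig(n_bits = 10, peaks_per_active_bit = 1,
                         grid = makeGrid(50.0, 50.9, 0.1), seed = 1)
    map10 <- makeBitPeakMap(cfg10)
    expect_setequal(unlist(map10), binCenters(cfg10$grid))
    ## grid too small errors
    expect_error(makeBitPeakMap(synthConfig(
        n_bits = 100, peaks_per_active_bit = 3,
        grid = makeGrid(50.0, 51.0, 0.1))), "need")
})

test_that("generated records pass default curation completely", {
    ds <- generateSynth(synthConfig(n_compounds = 60, seed = 52))
    cured <- cureSpectra(ds$records)
    expect_equal(nSpectra(cured$records), nSpectra(ds$records))
    ## every record's compound has a fingerprint
    expect_true(all(compoundIds(ds$records) %in%
                        rownames(ds$fingerprints)))
    ## spectra-per-compound within the configured range
    counts <- table(compoundIds(ds$records))
    expect_true(all(counts >= 2 & counts <= 8))
})

test_that("active-bit fraction matches the configured probability", {
    ds <- generateSynth(synthConfig(n_compounds = 300, seed = 53,
                                    grid = makeGrid(45, 120, 0.1)))
    frac <- mean(ds$fingerprints)
    se <- sqrt(0.23 * 0.77 / length(ds$fingerprints))
    expect_lt(abs(frac - 0.23), 3 * se)
})

test_that("the noise-free limit reproduces the exact bit-peak union", {
    cfg <- tinySynthConfig(seed = 54, n_compounds = 6,
                           bit_dropout = 0, noise_peaks = c(0L, 0L),
                           intensity_noise_cv = 0)
    ds <- generateSynth(cfg)
    meta <- spectrumMeta(ds$records)
    for (cid in unique(meta$compound_id)) {
        idx <- which(meta$compound_id == cid)
        pks <- peakLists(ds$records)[idx]
        active <- which(ds$fingerprints[cid, ] == 1L)
        expected_mz <- sort(unlist(ds$bit_peak_map[active],
                                   use.names = FALSE))
        if (length(expected_mz) >= 2) {
            ## every spectrum of the compound is identical: the union of
            ## its active bits' characteristic peaks
            for (p in pks) expect_equal(unname(p[, "mz"]), expected_mz)
            for (p in pks[-1])
                expect_equal(p[, "intensity"], pks[[1]][, "intensity"])
        }
    }
})

test_that("a compound with no active bits yields noise-only spectra", {
    cfg <- tinySynthConfig(seed = 55, n_compounds = 5,
                           active_bit_probability = 0)
    ds <- generateSynth(cfg)
    expect_true(all(ds$fingerprints == 0L))
    char_mz <- unlist(ds$bit_peak_map)
    for (p in peakLists(ds$records)) {
        expect_gte(nrow(p), 2L)   # topped up to pass the min-peak rule
        ## noise m/z are continuous draws, never the characteristic centers
        expect_false(any(p[, "mz"] %in% char_mz))
    }
})

test_that("generation is byte-deterministic under config + seed", {
    cfg <- tinySynthConfig(seed = 56, n_compounds = 8)
    a <- generateSynth(cfg); b <- generateSynth(cfg)
    expect_identical(spectrumMeta(a$records), spectrumMeta(b$records))
    expect_identical(peakLists(a$records), peakLists(b$records))
    expect_identical(a$fingerprints, b$fingerprints)
    av <- generateAdversarial(cfg); bv <- generateAdversarial(cfg)
    expect_identical(peakLists(av$records), peakLists(bv$records))
    ## adversarial spectra ignore the fingerprints but keep the metadata
    ## contract (they too pass curation)
    expect_equal(nSpectra(cureSpectra(av$records)$records),
                 nSpectra(av$records))
})

test_that("spectrum-aligned targets copy each compound's fingerprint", {
    ds <- generateSynth(tinySynthConfig(seed = 57, n_compounds = 6))
    y <- spectrumTargets(ds)
    expect_equal(rownames(y), recordIds(ds$records))
    meta <- spectrumMeta(ds$records)
    i <- 4L
    expect_equal(unname(y[i, ]),
                 unname(ds$fingerprints[meta$compound_id[i], ]))
})
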