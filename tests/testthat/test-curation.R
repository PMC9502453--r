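test_that("precursor consistency follows adduct mass offsets", {
    meta <- data.frame(
        precursor_type = c("[M+H]+", "[M+H]+", "[M+H]+", "[M+Na]+",
                           "[M+Zr]2+"),
        molecular_weight = c(180.063, 180.063, NA, 180.063, 180.063),
        precursor_mz = c(181.071, 180.063, 181.071, 203.052, 200))
    out <- checkPrecursor(meta, tolerance = 0.01)
    ## 180.063 + 1.00728 = 181.07028 -> |delta| = 0.0007
    expect_equal(out[1], "consistent")
    ## |180.063 - 181.07028| = 1.007 > 0.01
    expect_equal(out[2], "inconsistent")
    expect_equal(out[3], "unknown")          # MW absent
    ## 180.063 + 22.98922 = 203.05222
    expect_equal(out[4], "consistent")
    expect_equal(out[5], "unknown")          # unrecognized adduct
})

test_that("metadata filter applies each rule with first-failure accounting", {
    rows <- list(
        list(id = "ok", over = list()),
        list(id = "ce80", over = list(collision_energy_value = 80)),
        list(id = "ce3", over = list(collision_energy_value = 3)),
        list(id = "chloride", over = list(precursor_type = "[M+Cl]-",
                                          precursor_mz = NA_real_)),
        list(id = "neg", over = list(ionisation_mode = "negative")),
        list(id = "noce", over = list(collision_energy_value = NA_real_)),
        list(id = "iontrap", over = list(instrument_type = "LC-ESI-IT")),
        list(id = "orbi", over = list(instrument_type = "LC-ESI-Orbitrap")),
        list(id = "badmz", over = list(precursor_mz = 310.0)),
        list(id = "pctq", over = list(collision_energy_unit = "%")))
    recs <- makeRecordSet(rows, replicate(length(rows), defaultPeaks(),
                                          simplify = FALSE))
    res <- metadataFilter(recs)
    expect_equal(recordIds(res$records), "ok")
    ff <- res$report@firstFailure
    names(ff) <- recordIds(recs)
    expect_equal(unname(ff[c("ce80", "ce3")]), rep("ce_range", 2))
    expect_equal(unname(ff["chloride"]), "adduct")
    expect_equal(unname(ff["neg"]), "negative_mode")
    expect_equal(unname(ff["noce"]), "missing_annotation")
    expect_equal(unname(ff["iontrap"]), "ion_trap")
    expect_equal(unname(ff["orbi"]), "excluded_instrument")
    expect_equal(unname(ff["badmz"]), "precursor_inconsistent")
    ## percent CE on a non-HCD instrument is ambiguous -> discarded
    expect_equal(unname(ff["pctq"]), "ce_unit_incompatible")
    ## conservation: kept + discards == input
    expect_equal(res$report@kept + sum(res$report@counts),
                 res$report@nInput)
    ## percent CE on an HCD-class instrument is fine
    hcd <- makeRecordSet(list(list(id = "h", over = list(
        instrument_type = "LC-ESI-QFT", collision_energy_unit = "%"))),
        list(defaultPeaks()))
    expect_equal(nSpectra(metadataFilter(hcd)$records), 1L)
})

test_that("spectrum filter trims above-precursor peaks before counting", {
    rows <- list(list(id = "a", over = list(precursor_mz = 300.1,
                                            molecular_weight = NA_real_)),
                 list(id = "b", over = list(precursor_mz = 300.1,
                                            molecular_weight = NA_real_)),
                 list(id = "c", over = list()))
    peaks <- list(
        cbind(mz = c(150.0, 299.9, 310.2), intensity = c(10, 20, 30)),
        cbind(mz = c(310.2, 320.5), intensity = c(10, 20)),
        cbind(mz = 150.0, intensity = 100))
    recs <- makeRecordSet(rows, peaks)
    res <- spectrumFilter(recs)
    ## record a: 310.2 removed, kept with 2 peaks
    expect_equal(recordIds(res$records), "a")
    expect_equal(nrow(peakLists(res$records)[[1]]), 2L)
    ## record b: nothing survives; record c: single peak
    expect_equal(sort(unname(res$report@counts)), c(2L))
    ## a peak exactly at the precursor m/z is retained
    eq <- makeRecordSet(list(list(id = "e", over = list(
        precursor_mz = 200.0, molecular_weight = NA_real_))),
        list(cbind(mz = c(100, 200.0), intensity = c(50, 100))))
    res_eq <- spectrumFilter(eq)
    expect_equal(nrow(peakLists(res_eq$records)[[1]]), 2L)
})

test_that("strict filter keeps only [M+H]+ records with enough peaks", {
    rows <- list(
        list(id = "na20", over = list(precursor_type = "[M+Na]+",
                                      precursor_mz = 323.08922)),
        list(id = "h4", over = list()),
        list(id = "h5", over = list()))
    peaks <- list(defaultPeaks(20), defaultPeaks(4), defaultPeaks(5))
    recs <- makeRecordSet(rows, peaks)
    res <- strictFilter(recs)
    expect_equal(recordIds(res$records), "h5")
    expect_equal(unname(res$report@counts["adduct_not_strict"]), 1L)
    expect_equal(unname(res$report@counts["too_few_peaks_strict"]), 1L)
    ## monotone narrowing
    expect_true(all(recordIds(res$records) %in% recordIds(recs)))
})

test_that("curation cascade is idempotent and conserves counts", {
    ds <- generateSynth(tinySynthConfig(seed = 3))
    first <- cureSpectra(ds$records)
    second <- cureSpectra(first$records)
    expect_equal(recordIds(second$records), recordIds(first$records))
    expect_equal(peakLists(second$records), peakLists(first$records))
    for (rep in first$reports)
        expect_equal(rep@kept + sum(rep@counts), rep@nInput)
})
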