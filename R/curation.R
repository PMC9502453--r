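## Two-stage record-filter cascade: metadata-level rules first (annotation
## completeness, ionisation mode, precursor/MW consistency, instrument class,
## collision-energy range, adduct), then spectrum-level rules (peak trimming
## above the precursor, minimum peak counts). Every discard is attributed to
## the FIRST failing rule, in the fixed order below, so reports are
## reproducible and conserve counts.

#' Curation settings
#'
#' Defaults follow common practice for repository-scale LC-MS/MS curation:
#' collision energies between 5 and 70 V, the four most common positive-mode
#' adducts, at least 2 peaks per spectrum (5 for the strict subset), and a
#' 0.01 Da precursor-consistency tolerance.
#'
#' @param ce_min,ce_max allowed collision-energy range (V).
#' @param allowed_adducts adducts retained by \code{\link{metadataFilter}}.
#' @param strict_adducts adducts retained by \code{\link{strictFilter}}.
#' @param min_peaks minimum surviving peaks per spectrum.
#' @param strict_min_peaks minimum peaks for the strict subset.
#' @param ion_trap_patterns regexes (case-insensitive) identifying ion-trap
#'   instruments.
#' @param excluded_instrument_patterns regexes identifying the APPI / APCI /
#'   linear-trap / Orbitrap platforms excluded for scarcity.
#' @param hcd_patterns regexes identifying HCD-class instruments, the only
#'   ones for which a percent (normalised) collision energy is meaningful.
#' @param precursor_tolerance precursor/MW consistency tolerance (Da).
#' @return a list of class \code{CurationConfig}.
#' @export
curationConfig <- function(ce_min = 5, ce_max = 70,
                           allowed_adducts = c("[M+H]+", "[M+Na]+",
                                               "[M+K]+", "[M+NH4]+"),
                           strict_adducts = "[M+H]+",
                           min_peaks = 2L, strict_min_peaks = 5L,
                           ion_trap_patterns = c("ION.?TRAP", "-IT$", "QIT"),
                           excluded_instrument_patterns =
                               c("APPI", "APCI", "(^|-)LT($|-)", "ORBITRAP"),
                           hcd_patterns = c("QFT", "ITFT", "ORBITRAP", "HCD",
                                            "EXACTIVE"),
                           precursor_tolerance = 0.01) {
    stopifnot(ce_min < ce_max, min_peaks >= 1L,
              strict_min_peaks >= min_peaks)
    structure(list(ce_min = ce_min, ce_max = ce_max,
                   allowed_adducts = allowed_adducts,
                   strict_adducts = strict_adducts,
                   min_peaks = as.integer(min_peaks),
                   strict_min_peaks = as.integer(strict_min_peaks),
                   ion_trap_patterns = ion_trap_patterns,
                   excluded_instrument_patterns = excluded_instrument_patterns,
                   hcd_patterns = hcd_patterns,
                   precursor_tolerance = precursor_tolerance),
              class = "CurationConfig")
}

#' Per-stage curation report
#'
#' @slot rules rule names in evaluation order.
#' @slot counts discards attributed to each rule (first failure).
#' @slot kept number of records kept.
#' @slot nInput number of records examined.
#' @slot firstFailure per input record, the first failing rule or NA if kept.
#' @export
setClass("CurationReport",
         representation(rules = "character", counts = "integer",
                        kept = "integer", nInput = "integer",
                        firstFailure = "character"))

setValidity("CurationReport", function(object) {
    if (object@kept + sum(object@counts) != object@nInput)
        "kept + discarded must equal input count"
    else TRUE
})

setMethod("show", "CurationReport", function(object) {
    cat(sprintf("CurationReport: %d in, %d kept, %d discarded\n",
                object@nInput, object@kept, sum(object@counts)))
    for (r in object@rules)
        if (object@counts[r] > 0)
            cat(sprintf("  %-24s %d\n", r, object@counts[r]))
})

#' @export
as.data.frame.CurationReport <- function(x, ...) {
    data.frame(rule = c(x@rules, "kept"),
               count = c(unname(x@counts[x@rules]), x@kept))
}

.makeReport <- function(rules, firstFailure) {
    counts <- vapply(rules, function(r)
        sum(firstFailure == r, na.rm = TRUE), integer(1))
    new("CurationReport", rules = rules, counts = counts,
        kept = sum(is.na(firstFailure)),
        nInput = length(firstFailure), firstFailure = firstFailure)
}

## Proton/adduct mass offsets (Da) for the singly charged positive adducts.
.ADDUCT_DELTA <- c("[M+H]+" = 1.00728, "[M+Na]+" = 22.98922,
                   "[M+K]+" = 38.96316, "[M+NH4]+" = 18.03383)

#' Precursor / molecular-weight consistency
#'
#' For an adduct \code{[M+X]+} the precursor m/z should equal MW plus the
#' adduct mass offset. Returns \code{"consistent"} when the absolute
#' deviation is within tolerance, \code{"inconsistent"} when not, and
#' \code{"unknown"} when MW, precursor m/z or the adduct offset is
#' unavailable.
#'
#' @param x a \linkS4class{SpectrumSet} or its metadata data.frame.
#' @param tolerance maximum allowed deviation (Da).
#' @return character vector over records with values consistent /
#'   inconsistent / unknown.
#' @export
checkPrecursor <- function(x, tolerance = 0.01) {
    meta <- if (is(x, "SpectrumSet")) spectrumMeta(x) else x
    delta <- .ADDUCT_DELTA[.normalizeAdduct(meta$precursor_type)]
    expect <- meta$molecular_weight + delta
    out <- rep("unknown", nrow(meta))
    known <- is.finite(expect) & is.finite(meta$precursor_mz)
    out[known] <- ifelse(
        abs(meta$precursor_mz[known] - expect[known]) <= tolerance,
        "consistent", "inconsistent")
    out
}

.matchAny <- function(x, patterns) {
    hit <- rep(FALSE, length(x))
    for (p in patterns)
        hit <- hit | grepl(p, x, ignore.case = TRUE)
    hit & !is.na(x)
}

#' Metadata-level record filter
#'
#' Applies, in order: (1) instrument and collision-energy annotations
#' present; (2) collision-energy unit compatible with the instrument class
#' (percent energies only make sense on HCD-class instruments); (3) positive
#' ionisation mode; (4) precursor m/z consistent with MW under the adduct
#' (only records with a \emph{proven} inconsistency are discarded);
#' (5) no ion-trap instrument; (6) collision energy within
#' [\code{ce_min}, \code{ce_max}]; (7) instrument not in the excluded
#' APPI/APCI/LT/Orbitrap group; (8) adduct among the allowed set. Each
#' discard is attributed to its first failing rule.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param config a \code{\link{curationConfig}}.
#' @return list with the kept \code{records} and the \code{report}
#'   (\linkS4class{CurationReport}).
#' @export
metadataFilter <- function(x, config = curationConfig()) {
    meta <- spectrumMeta(x)
    n <- nrow(meta)
    rules <- c("missing_annotation", "ce_unit_incompatible", "negative_mode",
               "precursor_inconsistent", "ion_trap", "ce_range",
               "excluded_instrument", "adduct")
    fail <- rep(NA_character_, n)
    mark <- function(bad, rule) ifelse(is.na(fail) & bad, rule, fail)

    fail <- mark(is.na(meta$instrument_type) | !nzchar(meta$instrument_type) |
                     is.na(meta$collision_energy_value), "missing_annotation")
    pct <- !is.na(meta$collision_energy_unit) &
        meta$collision_energy_unit == "%"
    fail <- mark(pct & !.matchAny(meta$instrument_type, config$hcd_patterns),
                 "ce_unit_incompatible")
    fail <- mark(meta$ionisation_mode != "positive", "negative_mode")
    fail <- mark(checkPrecursor(meta, config$precursor_tolerance) ==
                     "inconsistent", "precursor_inconsistent")
    fail <- mark(.matchAny(meta$instrument_type, config$ion_trap_patterns),
                 "ion_trap")
    fail <- mark(!is.na(meta$collision_energy_value) &
                     (meta$collision_energy_value < config$ce_min |
                          meta$collision_energy_value > config$ce_max),
                 "ce_range")
    fail <- mark(.matchAny(meta$instrument_type,
                           config$excluded_instrument_patterns),
                 "excluded_instrument")
    fail <- mark(!(.normalizeAdduct(meta$precursor_type) %in%
                       .normalizeAdduct(config$allowed_adducts)), "adduct")

    list(records = x[which(is.na(fail))], report = .makeReport(rules, fail))
}

#' Spectrum-level record filter
#'
#' First removes, from every spectrum, the peaks with m/z strictly greater
#' than the precursor m/z (fragment ions cannot be heavier than their
#' precursor; peaks exactly at the precursor are retained). Records left
#' with fewer than \code{min_peaks} peaks are then discarded.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param config a \code{\link{curationConfig}}.
#' @return list with the kept \code{records} (peaks trimmed) and the
#'   \code{report}.
#' @export
spectrumFilter <- function(x, config = curationConfig()) {
    meta <- spectrumMeta(x)
    peaks <- peakLists(x)
    for (i in seq_along(peaks)) {
        pm <- meta$precursor_mz[i]
        if (is.finite(pm))
            peaks[[i]] <- peaks[[i]][peaks[[i]][, 1L] <= pm, , drop = FALSE]
    }
    npk <- vapply(peaks, nrow, integer(1))
    fail <- ifelse(npk < config$min_peaks, "too_few_peaks", NA_character_)
    keep <- which(is.na(fail))
    trimmed <- new("SpectrumSet", meta = meta[keep, , drop = FALSE],
                   peaks = peaks[keep])
    list(records = trimmed, report = .makeReport("too_few_peaks", fail))
}

#' Strict high-quality subset filter
#'
#' Narrows an already-cured set further, keeping only records whose adduct is
#' in \code{strict_adducts} (by default \code{[M+H]+}) and whose spectra have
#' at least \code{strict_min_peaks} peaks.
#'
#' @param x a \linkS4class{SpectrumSet} that already passed
#'   \code{\link{metadataFilter}} and \code{\link{spectrumFilter}}.
#' @param config a \code{\link{curationConfig}}.
#' @return list with the kept \code{records} and the \code{report}.
#' @export
strictFilter <- function(x, config = curationConfig()) {
    meta <- spectrumMeta(x)
    npk <- vapply(peakLists(x), nrow, integer(1))
    fail <- rep(NA_character_, nrow(meta))
    bad_adduct <- !(.normalizeAdduct(meta$precursor_type) %in%
                        .normalizeAdduct(config$strict_adducts))
    fail[bad_adduct] <- "adduct_not_strict"
    fail[is.na(fail) & npk < config$strict_min_peaks] <- "too_few_peaks_strict"
    list(records = x[which(is.na(fail))],
         report = .makeReport(c("adduct_not_strict", "too_few_peaks_strict"),
                              fail))
}

#' Run the full curation cascade
#'
#' Convenience wrapper: \code{\link{metadataFilter}} then
#' \code{\link{spectrumFilter}}, optionally followed by
#' \code{\link{strictFilter}}.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param config a \code{\link{curationConfig}}.
#' @param strict also apply the strict subset filter?
#' @return list with \code{records} and a list of per-stage \code{reports}.
#' @export
cureSpectra <- function(x, config = curationConfig(), strict = FALSE) {
    s1 <- metadataFilter(x, config)
    s2 <- spectrumFilter(s1$records, config)
    reports <- list(metadata = s1$report, spectrum = s2$report)
    records <- s2$records
    if (strict) {
        s3 <- strictFilter(records, config)
        reports$strict <- s3$report
        records <- s3$records
    }
    list(records = records, reports = reports)
}

#' Write a curation report as a tab-separated table
#'
#' @param report a \linkS4class{CurationReport}.
#' @param path output file.
#' @export
writeCurationReport <- function(report, path) {
    write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
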