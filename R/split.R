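## Compound-grouped partitioning. All spectra of one compound must land in
## the same set, otherwise validation and test performance is optimistic:
## the network would be evaluated on molecules it has effectively seen.
## Because spectra-per-compound is heavily skewed, compounds are assigned
## greedily to the set with the largest spectrum-count deficit so the
## SPECTRUM-level fractions track the targets.

#' Compound-grouped train/validation/test split
#'
#' Compounds are shuffled under \code{seed} and assigned one at a time to
#' the set whose spectrum-count deficit (target minus current) is largest;
#' ties go to train, then validation, then test. Every record of a compound
#' therefore shares one set, and spectrum-level fractions approximate the
#' targets despite unequal spectra per compound.
#'
#' @param x a \linkS4class{SpectrumSet}, or a data.frame with
#'   \code{record_id} and \code{compound_id} columns.
#' @param fractions numeric length-3 (train, validation, test), summing to 1.
#' @param seed RNG seed, recorded in the result.
#' @return list of class \code{SplitAssignment} with \code{records}
#'   (data.frame record_id, compound_id, set), \code{compounds} (data.frame
#'   compound_id, set), \code{fractions}, \code{seed}.
#' @export
groupSplit <- function(x, fractions = c(0.72, 0.15, 0.13), seed = 1L) {
    meta <- if (is(x, "SpectrumSet")) spectrumMeta(x) else x
    stopifnot(length(fractions) == 3L,
              abs(sum(fractions) - 1) < 1e-8,
              all(fractions > 0))
    if (any(is.na(meta$compound_id)))
        stop("every record needs a compound_id")
    sets <- c("train", "val", "test")
    counts <- table(meta$compound_id)
    compounds <- names(counts)
    if (length(compounds) < 3L)
        stop("need at least 3 compounds to form 3 disjoint sets")
    total <- sum(counts)
    target <- fractions * total

    set.seed(seed)
    ord <- sample(length(compounds))
    assigned <- setNames(character(length(compounds)), compounds)
    current <- c(train = 0, val = 0, test = 0)
    for (ci in ord) {
        deficit <- target - current
        pick <- sets[which.max(deficit)]   # ties resolve to train > val > test
        assigned[compounds[ci]] <- pick
        current[pick] <- current[pick] + counts[ci]
    }
    rec <- data.frame(record_id = meta$record_id,
                      compound_id = meta$compound_id,
                      set = unname(assigned[meta$compound_id]),
                      stringsAsFactors = FALSE)
    structure(list(records = rec,
                   compounds = data.frame(compound_id = compounds,
                                          set = unname(assigned),
                                          stringsAsFactors = FALSE),
                   fractions = setNames(fractions, sets),
                   seed = as.integer(seed)),
              class = "SplitAssignment")
}

#' @export
print.SplitAssignment <- function(x, ...) {
    tab <- table(factor(x$records$set, levels = c("train", "val", "test")))
    frac <- tab / sum(tab)
    cat(sprintf("SplitAssignment (seed %d):\n", x$seed))
    for (s in names(tab))
        cat(sprintf("  %-5s %6d spectra (%.1f%%)\n", s, tab[s],
                    100 * frac[s]))
    invisible(x)
}

#' Record ids of one split set
#'
#' @param split a \code{SplitAssignment}.
#' @param set one of \code{"train"}, \code{"val"}, \code{"test"}.
#' @return character vector of record ids.
#' @export
splitRecords <- function(split, set = c("train", "val", "test")) {
    set <- match.arg(set)
    split$records$record_id[split$records$set == set]
}

#' Write a split assignment as two tab-separated files
#'
#' @param split a \code{SplitAssignment}.
#' @param record_path,compound_path output files for the record-level and
#'   compound-level tables.
#' @export
writeSplit <- function(split, record_path, compound_path) {
    write.table(split$records, record_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(split$compounds, compound_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(NULL)
}
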