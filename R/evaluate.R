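## Multi-task evaluation: per-task confusion counts, sensitivity,
## specificity and non-error rate; per-spectrum Jaccard-Tanimoto
## similarities; candidate-library ranking; and chemical-space diagnostics
## (classical MDS on 1 - JT distances, active-bit analysis).

#' Per-task confusion counts
#'
#' @param pred,truth binary matrices of identical shape (spectra by tasks).
#' @return data.frame with one row per task: \code{TP}, \code{TN},
#'   \code{FP}, \code{FN}.
#' @export
confusionByTask <- function(pred, truth) {
    if (!all(dim(pred) == dim(truth)))
        stop("prediction and truth shapes differ")
    data.frame(task = seq_len(ncol(truth)),
               TP = colSums(truth == 1 & pred == 1),
               TN = colSums(truth == 0 & pred == 0),
               FP = colSums(truth == 0 & pred == 1),
               FN = colSums(truth == 1 & pred == 0))
}

#' Non-error rate from confusion counts
#'
#' Per task, the mean of sensitivity \code{TP/(TP+FN)} and specificity
#' \code{TN/(TN+FP)}; overall, the mean over the tasks where both classes
#' were observed (single-class tasks have an undefined rate and are
#' excluded, their indices reported). 0.5 corresponds to random
#' classification, 1 to error-free prediction.
#'
#' @param confusion data.frame from \code{\link{confusionByTask}}.
#' @return list with \code{ner} (overall mean), \code{per_task} (data.frame
#'   task, Sn, Sp, NER), \code{excluded} (task indices with a single
#'   observed class).
#' @export
nerScore <- function(confusion) {
    sn <- with(confusion, ifelse(TP + FN > 0, TP / (TP + FN), NA_real_))
    sp <- with(confusion, ifelse(TN + FP > 0, TN / (TN + FP), NA_real_))
    ner_t <- (sn + sp) / 2
    defined <- is.finite(ner_t)
    if (!any(defined))
        stop("no task has both classes observed; NER undefined")
    list(ner = mean(ner_t[defined]),
         per_task = data.frame(task = confusion$task, Sn = sn, Sp = sp,
                               NER = ner_t),
         excluded = confusion$task[!defined])
}

#' Full evaluation report
#'
#' @param pred,truth binary fingerprint matrices (spectra by bits).
#' @return list with \code{ner}, \code{per_task}, \code{excluded},
#'   \code{jt} (per-spectrum similarities) and \code{mean_jt}.
#' @export
evaluationReport <- function(pred, truth) {
    conf <- confusionByTask(pred, truth)
    ner <- nerScore(conf)
    jts <- jtRows(truth, pred)
    c(ner, list(jt = jts, mean_jt = mean(jts)))
}

#' Rank candidate structures against a predicted fingerprint
#'
#' Candidates are sorted by descending Jaccard-Tanimoto similarity to the
#' predicted fingerprint; ties are broken by lexicographic candidate id so
#' the ranking is deterministic.
#'
#' @param fp_pred predicted binary fingerprint (vector).
#' @param library binary matrix of candidate fingerprints with candidate
#'   ids as row names.
#' @param true_id optional id of the true compound; its rank (first
#'   position at its similarity, after tie-breaking) is reported.
#' @return data.frame \code{candidate_id}, \code{jt}, \code{rank}; when
#'   \code{true_id} is given, the attribute \code{"true_rank"} holds its
#'   rank.
#' @export
rankCandidates <- function(fp_pred, library, true_id = NULL) {
    if (!nrow(library)) stop("empty candidate library")
    sims <- apply(library, 1L, function(row) jt(row, fp_pred))
    ord <- order(-sims, rownames(library), method = "radix")
    out <- data.frame(candidate_id = rownames(library)[ord],
                      jt = sims[ord], rank = seq_along(ord),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    if (!is.null(true_id))
        attr(out, "true_rank") <-
            if (true_id %in% out$candidate_id)
                out$rank[match(true_id, out$candidate_id)] else NA_integer_
    out
}

#' Classical MDS embedding of fingerprints
#'
#' Embeds fingerprints with Torgerson (classical metric) multidimensional
#' scaling on the distance \code{1 - JT}. Orientation is arbitrary in MDS;
#' here each axis's sign is fixed so its largest-magnitude coordinate is
#' positive, making the embedding deterministic.
#'
#' @param fps binary fingerprint matrix (at least 3 rows) or a precomputed
#'   distance matrix (class \code{dist} or square symmetric matrix).
#' @param n_dims requested embedding dimension.
#' @return coordinate matrix; if fewer than \code{n_dims} positive
#'   eigenvalues exist, fewer columns are returned with a warning.
#' @export
mdsEmbed <- function(fps, n_dims = 2L) {
    if (inherits(fps, "dist")) {
        d <- fps
    } else if (is.matrix(fps) && isSymmetric(unname(fps)) &&
               nrow(fps) == ncol(fps) && all(abs(diag(fps)) < 1e-12)) {
        d <- stats::as.dist(fps)
    } else {
        if (nrow(fps) < 3L) stop("need at least 3 fingerprints")
        d <- stats::as.dist(1 - jtMatrix(fps))
    }
    fit <- stats::cmdscale(d, k = n_dims, eig = TRUE)
    pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
    coords <- fit$points
    if (ncol(coords) < n_dims)
        warning(sprintf("only %d positive eigenvalue(s); returning %d dims",
                        pos, ncol(coords)))
    for (j in seq_len(ncol(coords))) {
        i_max <- which.max(abs(coords[, j]))
        if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
    }
    coords
}

#' Active-bit analysis of well- and poorly-predicted compounds
#'
#' Splits compounds into a low-accuracy group (mean per-compound JT below
#' \code{threshold_low}) and a high-accuracy group (above
#' \code{threshold_high}) and summarises the percentage of active bits in
#' each group's TRUE fingerprints. Full-scale studies find the
#' high-accuracy group has substantially more active bits: complex
#' structures produce more informative spectra.
#'
#' @param compound_jt named numeric vector: mean JT per compound.
#' @param fingerprints binary matrix of true fingerprints with compound ids
#'   as row names.
#' @param threshold_low,threshold_high group cut-offs on mean JT.
#' @return list with per-group summaries (n, median, q1, q3 of the active
#'   percentage; \code{defined = FALSE} for an empty group).
#' @export
activeBitAnalysis <- function(compound_jt, fingerprints,
                              threshold_low = 0.25, threshold_high = 0.75) {
    pct_active <- 100 * rowMeans(fingerprints)
    summarise <- function(ids) {
        if (!length(ids))
            return(list(defined = FALSE, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_))
        v <- pct_active[ids]
        q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        list(defined = TRUE, n = length(ids), median = q[2],
             q1 = q[1], q3 = q[3])
    }
    low_ids <- names(compound_jt)[compound_jt < threshold_low]
    high_ids <- names(compound_jt)[compound_jt > threshold_high]
    list(low = summarise(intersect(low_ids, rownames(fingerprints))),
         high = summarise(intersect(high_ids, rownames(fingerprints))))
}

#' Mean per-compound similarity
#'
#' @param jt_values per-spectrum similarities.
#' @param compound_ids compound id per spectrum.
#' @return named numeric vector of mean similarities per compound.
#' @export
compoundMeanJt <- function(jt_values, compound_ids) {
    tapply(jt_values, compound_ids, mean)
}
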