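## Binarization and ensembling. The sigmoid outputs are probabilities, but
## each bit is represented differently in the training data, so a per-bit
## threshold is chosen to minimise false positives plus false negatives
## (the Bayes decision under equal error costs). Five independently
## initialised replicates are combined by per-bit majority voting to damp
## the effect of random weight initialisation.

#' Bayes-optimal per-bit thresholds
#'
#' For each task, sweeps the midpoints of adjacent sorted distinct scores
#' (with virtual endpoints at 0 and 1, so the all-positive and all-negative
#' decisions are also reachable) and picks the threshold minimising FP + FN
#' on the supplied data; ties are broken toward the candidate closest to
#' 0.5. Tasks whose truth column has a single class get threshold 0.5. The
#' chosen threshold attains the same error count as an exhaustive sweep
#' over any grid on [0, 1].
#'
#' @param scores probability matrix (spectra by tasks).
#' @param truth binary matrix of the same shape.
#' @return numeric vector of thresholds, one per task, strictly in (0, 1).
#' @export
bayesThresholds <- function(scores, truth) {
    stopifnot(all(dim(scores) == dim(truth)), nrow(scores) >= 1)
    vapply(seq_len(ncol(scores)), function(t) {
        s <- scores[, t]
        y <- truth[, t]
        if (length(unique(y)) < 2L) return(0.5)
        u <- sort(unique(c(0, s, 1)))
        if (length(u) < 2L) return(0.5)
        cand <- (u[-1] + u[-length(u)]) / 2
        err <- vapply(cand, function(th)
            sum(y == 0 & s >= th) + sum(y == 1 & s < th), numeric(1))
        best <- which(err == min(err))
        cand[best][which.min(abs(cand[best] - 0.5))]
    }, numeric(1))
}

#' Binarize probabilities with per-bit thresholds
#'
#' @param scores probability matrix (spectra by tasks).
#' @param thresholds one threshold per task; a score at or above its
#'   threshold maps to 1.
#' @return binary integer matrix.
#' @export
applyThresholds <- function(scores, thresholds) {
    stopifnot(ncol(scores) == length(thresholds))
    out <- (scores >= matrix(thresholds, nrow(scores), ncol(scores),
                             byrow = TRUE)) * 1L
    dimnames(out) <- dimnames(scores)
    out
}

#' Train a replicate ensemble
#'
#' Trains \code{n_replicates} networks that differ only in their
#' weight-initialisation / shuffling seed (\code{base_seed + replicate}),
#' then estimates each replicate's Bayes thresholds on its training-set
#' scores. Validation data are used for early stopping only.
#'
#' @param hp a \code{\link{hyperparameters}} list.
#' @param x_train,y_train,x_val,y_val features and binary fingerprint
#'   targets.
#' @param n_replicates odd number of replicates (default 5).
#' @param base_seed base seed; replicate r uses \code{base_seed + r}.
#' @param max_epochs epoch cap per replicate.
#' @param l1_shared L1 weight decay on the shared layer (see
#'   \code{\link{trainNetwork}}).
#' @param verbose print training progress?
#' @return a \linkS4class{FingerprintEnsemble}.
#' @export
trainEnsemble <- function(hp, x_train, y_train, x_val, y_val,
                          n_replicates = 5L, base_seed = 1L,
                          max_epochs = 300L, l1_shared = 0,
                          verbose = FALSE) {
    if (n_replicates %% 2L == 0L)
        stop("replicate count must be odd for majority voting")
    reps <- vector("list", n_replicates)
    ths <- vector("list", n_replicates)
    seeds <- base_seed + seq_len(n_replicates)
    for (r in seq_len(n_replicates)) {
        net <- buildNetwork(hp, n_inputs = ncol(x_train),
                            n_tasks = ncol(y_train), seed = seeds[r])
        net <- trainNetwork(net, x_train, y_train, x_val, y_val,
                            max_epochs = max_epochs, l1_shared = l1_shared,
                            verbose = verbose)
        p_train <- predict(net, x_train)
        th <- bayesThresholds(p_train, y_train)
        th <- pmin(pmax(th, 1e-6), 1 - 1e-6)
        reps[[r]] <- net
        ths[[r]] <- th
    }
    new("FingerprintEnsemble", replicates = reps, thresholds = ths,
        seeds = as.integer(seeds))
}

#' Predict binary fingerprints by majority voting
#'
#' Each replicate's probabilities are binarized with its own thresholds and
#' the final bit is the most frequent value across replicates.
#'
#' @param object a \linkS4class{FingerprintEnsemble}.
#' @param newdata feature matrix.
#' @param ... ignored.
#' @return binary integer matrix (spectra by bits).
#' @export
setMethod("predict", "FingerprintEnsemble", function(object, newdata, ...) {
    votes <- .replicateBits(object, newdata)
    k <- length(votes)
    total <- Reduce(`+`, votes)
    out <- (total > k / 2) * 1L
    rownames(out) <- rownames(newdata)
    out
})

.replicateBits <- function(ensemble, newdata) {
    lapply(seq_along(ensemble@replicates), function(r)
        applyThresholds(predict(ensemble@replicates[[r]], newdata),
                        ensemble@thresholds[[r]]))
}

#' Replicate-to-replicate prediction stability
#'
#' For every spectrum and bit, the standard deviation of the binary
#' predictions across replicates, averaged over bits and then spectra.
#' Zero means all replicates agree everywhere; published full-scale runs
#' report values around 0.02-0.04.
#'
#' @param ensemble a \linkS4class{FingerprintEnsemble} with at least two
#'   replicates.
#' @param newdata feature matrix.
#' @return the mean per-bit standard deviation (a single number).
#' @export
replicateStability <- function(ensemble, newdata) {
    if (length(ensemble@replicates) < 2L)
        stop("stability needs at least two replicates")
    votes <- .replicateBits(ensemble, newdata)
    k <- length(votes)
    sum1 <- Reduce(`+`, votes)
    sum2 <- Reduce(`+`, lapply(votes, function(v) v^2))
    ## sample standard deviation per (spectrum, bit)
    sds <- sqrt(pmax(sum2 - sum1^2 / k, 0) / (k - 1))
    mean(rowMeans(sds))
}
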