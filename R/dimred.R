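## Sparse PCA by alternating regression/Procrustes updates (elastic-net
## style): loadings are soft-thresholded projections, the rotation is the
## Procrustes solution, and explained variance of the (non-orthogonal)
## sparse components is the QR-adjusted variance of the score matrix so the
## cumulative series can never exceed 100%. With a zero penalty the
## algorithm reduces exactly to ordinary PCA.

.denseCentered <- function(x) {
    if (is(x, "SpectralMatrix")) x <- x@values
    x <- as.matrix(x)
    ctr <- colMeans(x)
    list(x = sweep(x, 2L, ctr), center = ctr)
}

.adjustedEvr <- function(xc, b) {
    s <- xc %*% as.matrix(b)
    totvar <- sum(xc^2)
    if (totvar <= 0) return(rep(0, ncol(s)))
    qr_s <- qr(s)
    r <- qr.R(qr_s)
    d <- diag(r)^2
    ## qr() may pivot; undo to keep component order
    d[qr_s$pivot] <- diag(r)^2
    d / totvar
}

#' Fit sparse principal components
#'
#' Column-mean-centers the matrix internally and extracts \code{k}
#' components whose loadings are sparsified either by an L1 soft-threshold
#' weight (\code{sparsity}, in units of the largest projection magnitude,
#' 0 = ordinary PCA) or by a per-component cardinality bound (\code{nnz},
#' keep only the largest-magnitude loadings). Scores are the centered data
#' times the loadings.
#'
#' @param x a \linkS4class{SpectralMatrix}, sparse Matrix or base matrix
#'   (rows = spectra).
#' @param k number of components, at most \code{min(dim(x))}.
#' @param sparsity relative L1 penalty in [0, 1); 0 disables thresholding.
#' @param nnz optional integer: number of nonzero loadings per component
#'   (overrides \code{sparsity}).
#' @param seed kept for interface stability; the fit is deterministic.
#' @param max_iter,tol alternating-update iteration controls.
#' @return an \linkS4class{SpcaModel}.
#' @export
fitSpca <- function(x, k, sparsity = 0, nnz = NULL, seed = 1L,
                    max_iter = 200L, tol = 1e-8) {
    dc <- .denseCentered(x)
    xc <- dc$x
    n <- nrow(xc)
    p <- ncol(xc)
    if (k > min(n, p))
        stop(sprintf("k = %d exceeds min(n, p) = %d", k, min(n, p)))
    sv <- svd(xc, nu = 0, nv = k)
    v <- sv$v[, seq_len(k), drop = FALSE]

    if (sparsity <= 0 && is.null(nnz)) {
        b <- v
    } else {
        a <- v
        b_old <- v
        for (iter in seq_len(max_iter)) {
            cc <- crossprod(xc, xc %*% a)            # p x k projections
            b <- cc
            for (j in seq_len(k)) {
                cj <- cc[, j]
                if (!is.null(nnz)) {
                    keep <- order(abs(cj), decreasing = TRUE)[seq_len(min(nnz, p))]
                    bj <- numeric(p)
                    bj[keep] <- cj[keep]
                } else {
                    lam <- sparsity * max(abs(cj))
                    bj <- sign(cj) * pmax(abs(cj) - lam, 0)
                }
                nb <- sqrt(sum(bj^2))
                b[, j] <- if (nb > 0) bj / nb else 0
            }
            ## Procrustes rotation update
            m <- crossprod(xc, xc %*% b)
            sm <- svd(m)
            a <- sm$u %*% t(sm$v)
            if (max(abs(b - b_old)) < tol) break
            b_old <- b
        }
    }
    rownames(b) <- colnames(xc)
    sc <- xc %*% b
    evr <- .adjustedEvr(xc, b)
    new("SpcaModel",
        loadings = methods::as(Matrix::Matrix(b, sparse = TRUE),
                               "CsparseMatrix"),
        center = dc$center, scores = sc, evr = as.numeric(evr),
        penalty = if (is.null(nnz)) sparsity else -as.numeric(nnz))
}

#' Project spectra onto a fitted SPCA model
#'
#' Held-out spectra are centered with the training column means and
#' multiplied by the training loadings; no statistic of the new data is
#' used, so there is no information leakage.
#'
#' @param object an \linkS4class{SpcaModel}.
#' @param newdata a \linkS4class{SpectralMatrix}, sparse Matrix or base
#'   matrix with the same number of columns the model was fitted on.
#' @param ... ignored.
#' @return score matrix, rows matching \code{newdata}.
#' @export
setMethod("predict", "SpcaModel", function(object, newdata, ...) {
    if (is(newdata, "SpectralMatrix")) newdata <- newdata@values
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != nrow(object@loadings))
        stop("newdata has ", ncol(newdata), " columns; model expects ",
             nrow(object@loadings))
    sweep(newdata, 2L, object@center) %*% as.matrix(object@loadings)
})

#' Choose the number of components from explained variance
#'
#' @param cum_evr cumulative explained-variance series (non-decreasing).
#' @param target fraction of variance to reach, in (0, 1].
#' @return the smallest \code{k} whose cumulative explained variance is at
#'   least \code{target}; if the target is unreachable, the maximum
#'   component count with a warning.
#' @export
selectK <- function(cum_evr, target) {
    stopifnot(target > 0, target <= 1)
    hit <- which(cum_evr >= target)
    if (!length(hit)) {
        warning(sprintf("target %.3f unreachable (max %.3f); using all %d",
                        target, max(cum_evr), length(cum_evr)))
        return(length(cum_evr))
    }
    hit[1]
}
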