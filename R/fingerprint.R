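## MACCS substructure-key fingerprints and Jaccard-Tanimoto similarity.
## The key dictionary numbers substructural patterns 1..166; position 0 of
## the underlying toolkit vector is unused and dropped, so fingerprints here
## are exactly 166 bits with index = key id.

.N_MACCS <- 166L

#' MACCS-key fingerprints from SMILES
#'
#' Computes the 166-bit MACCS substructure-key fingerprint of each structure
#' via OpenBabel. The computation is deterministic: identical canonical
#' structures give identical fingerprints.
#'
#' @param smiles character vector of SMILES strings.
#' @return binary integer matrix with one row per structure and 166 columns
#'   (column \code{t} = MACCS key \code{t}); row names are the input SMILES
#'   names when present, else the SMILES themselves.
#' @export
maccs <- function(smiles) {
    out <- matrix(0L, length(smiles), .N_MACCS)
    for (i in seq_along(smiles)) {
        s <- smiles[i]
        if (is.na(s) || !nzchar(s))
            stop("empty structure at position ", i)
        fp <- tryCatch({
            mol <- ChemmineOB::forEachMol("SMILES", paste0(s, "\tq"),
                                          identity)
            ChemmineOB::fingerprint_OB(mol, "MACCS")
        }, error = function(e) NULL)
        if (is.null(fp) || length(fp) < .N_MACCS)
            stop("cannot parse structure at position ", i, ": ", s)
        out[i, ] <- as.integer(fp[seq_len(.N_MACCS)] != 0)
    }
    rownames(out) <- if (!is.null(names(smiles))) names(smiles) else smiles
    colnames(out) <- paste0("maccs", seq_len(.N_MACCS))
    out
}

#' Jaccard-Tanimoto similarity of two binary fingerprints
#'
#' \code{a / (a + b + c)} where \code{a} counts bits active in both vectors
#' and \code{b}, \code{c} count bits active in only one. Two all-zero
#' fingerprints are identical and score 1 by convention.
#'
#' @param fp_true,fp_pred binary vectors of equal length.
#' @return similarity in [0, 1].
#' @export
jt <- function(fp_true, fp_pred) {
    if (length(fp_true) != length(fp_pred))
        stop("fingerprint lengths differ")
    a <- sum(fp_true == 1 & fp_pred == 1)
    b <- sum(fp_true == 1 & fp_pred == 0)
    c <- sum(fp_true == 0 & fp_pred == 1)
    if (a + b + c == 0) return(1)
    a / (a + b + c)
}

#' Row-wise Jaccard-Tanimoto similarities between two binary matrices
#'
#' @param truth,pred binary matrices of identical shape, rows = spectra.
#' @return numeric vector of per-row similarities.
#' @export
jtRows <- function(truth, pred) {
    stopifnot(all(dim(truth) == dim(pred)))
    a <- rowSums(truth == 1 & pred == 1)
    u <- rowSums(truth == 1 | pred == 1)
    ifelse(u == 0, 1, a / u)
}

#' All-pairs Jaccard-Tanimoto similarity matrix
#'
#' @param fps binary matrix, one fingerprint per row.
#' @return symmetric similarity matrix.
#' @export
jtMatrix <- function(fps) {
    fps <- as.matrix(fps)
    a <- tcrossprod(fps)
    r <- rowSums(fps)
    denom <- outer(r, r, "+") - a
    s <- ifelse(denom == 0, 1, a / denom)
    dimnames(s) <- list(rownames(fps), rownames(fps))
    s
}

#' Random-fingerprint similarity baseline
#'
#' Generates random fingerprints with the same number of active bits as the
#' true fingerprint (active positions chosen uniformly) and returns their
#' Jaccard-Tanimoto similarity to it. This is the floor any predictive model
#' must beat: for a fingerprint with \code{k} active bits of \code{T} the
#' expected similarity is the hypergeometric mean of \code{a / (2k - a)}.
#'
#' @param fp_true binary vector.
#' @param n_random number of random fingerprints.
#' @param seed RNG seed.
#' @return numeric vector of \code{n_random} similarities.
#' @export
randomBaseline <- function(fp_true, n_random, seed = 1L) {
    stopifnot(n_random >= 1)
    set.seed(seed)
    k <- sum(fp_true == 1)
    T <- length(fp_true)
    vapply(seq_len(n_random), function(i) {
        rnd <- integer(T)
        if (k > 0) rnd[sample.int(T, k)] <- 1L
        jt(fp_true, rnd)
    }, numeric(1))
}

#' Mean random baseline over a fingerprint set
#'
#' @param truth binary matrix of true fingerprints (rows = spectra or
#'   compounds).
#' @param n_random random fingerprints per row.
#' @param seed RNG seed.
#' @return mean similarity over all rows and draws.
#' @export
randomBaselineMean <- function(truth, n_random = 10L, seed = 1L) {
    vals <- vapply(seq_len(nrow(truth)), function(i)
        mean(randomBaseline(truth[i, ], n_random, seed = seed + i)),
        numeric(1))
    mean(vals)
}

#' Write a fingerprint table
#'
#' Tab-separated: \code{compound_id} plus one 0/1 column per bit.
#'
#' @param fps binary matrix with row names as compound ids.
#' @param path output file.
#' @export
writeFingerprints <- function(fps, path) {
    df <- data.frame(compound_id = rownames(fps), fps, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a fingerprint table written by \code{\link{writeFingerprints}}
#'
#' @param path file to read.
#' @return binary integer matrix with compound ids as row names.
#' @export
readFingerprints <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- df[[1]]
    m
}
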