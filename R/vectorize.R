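## Spectral binning: each peak's m/z is rounded half-up to the grid
## resolution, each bin keeps the maximum intensity among its peaks, and each
## spectrum is scaled by its own maximum so the largest entry is exactly 1.

#' Create an m/z binning grid
#'
#' @param mz_min,mz_max first and last bin centers (Da).
#' @param step bin width (Da).
#' @return a \linkS4class{BinGrid}. With the defaults (45.0 to 704.5 Da at
#'   0.1 Da) the grid has 6596 bins.
#' @examples
#' nBins(makeGrid())                 # 6596
#' binCenters(makeGrid(0, 1, 0.5))   # 0.0 0.5 1.0
#' @export
makeGrid <- function(mz_min = 45.0, mz_max = 704.5, step = 0.1) {
    if (!is.finite(step) || step <= 0) stop("step must be positive")
    if (!isTRUE(mz_min < mz_max)) stop("mz_min must be below mz_max")
    new("BinGrid", mzMin = mz_min, mzMax = mz_max, step = step)
}

#' Bin index for m/z values
#'
#' Assigns each m/z to the nearest bin center, rounding half-up (ties go to
#' the higher bin). Values whose nearest center falls outside the grid get
#' \code{NA}.
#'
#' @param mz numeric vector of m/z values.
#' @param grid a \linkS4class{BinGrid}.
#' @return integer vector of 1-based bin indices, NA for out-of-range.
#' @export
binIndex <- function(mz, grid) {
    ## the 1e-9 guard keeps decimal half-up semantics for values such as
    ## 100.05 whose binary representation falls a hair below the tie point
    j <- floor((mz - grid@mzMin) / grid@step + 0.5 + 1e-9)
    j[j < 0 | j >= nBins(grid)] <- NA
    as.integer(j) + 1L
}

#' Vectorize one spectrum onto a grid
#'
#' Each bin takes the maximum intensity among the peaks that round into it;
#' peaks rounding outside the grid are dropped; the vector is then divided by
#' its maximum so the largest entry is exactly 1. An all-out-of-range
#' spectrum yields an all-zero vector with a warning.
#'
#' @param peaks two-column mz/intensity matrix.
#' @param grid a \linkS4class{BinGrid}.
#' @return numeric vector of length \code{nBins(grid)}.
#' @export
spectrumToVector <- function(peaks, grid) {
    v <- numeric(nBins(grid))
    if (!nrow(peaks)) {
        warning("spectrum has no peaks; returning all-zero vector")
        return(v)
    }
    j <- binIndex(peaks[, 1L], grid)
    ok <- !is.na(j)
    if (!any(ok)) {
        warning("all peaks outside the bin grid; returning all-zero vector")
        return(v)
    }
    agg <- tapply(peaks[ok, 2L], j[ok], max)
    v[as.integer(names(agg))] <- agg
    mx <- max(v)
    if (mx > 0) v <- v / mx
    v
}

#' Vectorize a SpectrumSet into a sparse binned matrix
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param grid a \linkS4class{BinGrid}.
#' @return a \linkS4class{SpectralMatrix} with one row per record, in record
#'   order; row names are record ids.
#' @export
binSpectra <- function(x, grid = makeGrid()) {
    n <- nSpectra(x)
    peaks <- peakLists(x)
    ii <- jj <- vector("list", n)
    vv <- vector("list", n)
    for (r in seq_len(n)) {
        p <- peaks[[r]]
        if (!nrow(p)) next
        j <- binIndex(p[, 1L], grid)
        ok <- !is.na(j)
        if (!any(ok)) next
        agg <- tapply(p[ok, 2L], j[ok], max)
        mx <- max(agg)
        ii[[r]] <- rep.int(r, length(agg))
        jj[[r]] <- as.integer(names(agg))
        vv[[r]] <- as.numeric(agg) / mx
    }
    m <- Matrix::sparseMatrix(
        i = unlist(ii), j = unlist(jj), x = unlist(vv),
        dims = c(n, nBins(grid)),
        dimnames = list(recordIds(x), sprintf("%.10g", binCenters(grid))))
    new("SpectralMatrix", values = methods::as(m, "CsparseMatrix"),
        grid = grid)
}

#' Fraction of exactly-zero entries
#'
#' @param m a \linkS4class{SpectralMatrix}, sparse Matrix or base matrix.
#' @return the zero fraction, in [0, 1].
#' @export
sparsity <- function(m) {
    if (is(m, "SpectralMatrix")) m <- m@values
    if (!length(m) || prod(dim(m)) == 0) stop("empty matrix")
    if (is(m, "sparseMatrix")) {
        m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
        nz <- sum(m@x != 0)
        return(1 - nz / prod(dim(m)))
    }
    sum(m == 0) / length(m)
}
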