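## Central S4 containers. Validity methods enforce the structural invariants
## that downstream algorithms rely on (sorted peaks, [0,1] intensities,
## row-maximum normalisation), so that any object reaching the modelling code
## is already well-formed.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Fixed m/z binning grid
#'
#' Defines the uniform grid used to vectorize product-ion spectra: bins are
#' centered at \code{mzMin + j * step} for \code{j = 0 .. nBins - 1}, and an
#' observed m/z is assigned to the nearest center (ties to the higher bin).
#' The default grid, 45.0 to 704.5 Da at 0.1 Da, has 6596 bins.
#'
#' @slot mzMin lowest bin center (Da).
#' @slot mzMax highest bin center (Da).
#' @slot step bin width (Da).
#' @export
setClass("BinGrid",
         representation(mzMin = "numeric", mzMax = "numeric", step = "numeric"),
         prototype(mzMin = 45.0, mzMax = 704.5, step = 0.1))

setValidity("BinGrid", function(object) {
    msg <- NULL
    if (length(object@mzMin) != 1L || length(object@mzMax) != 1L ||
        length(object@step) != 1L)
        msg <- c(msg, "mzMin, mzMax and step must be scalars")
    else {
        if (!is.finite(object@step) || object@step <= 0)
            msg <- c(msg, "step must be a positive number")
        if (!isTRUE(object@mzMin < object@mzMax))
            msg <- c(msg, "mzMin must be smaller than mzMax")
    }
    if (is.null(msg)) TRUE else msg
})

#' A collection of MS/MS spectral records
#'
#' Column-oriented container for spectral-library entries: a metadata table
#' (one row per record) plus a parallel list of peak matrices. Records keep
#' their file order. Use \code{readSpectra} to build one from an MSP-style
#' library and \code{[} to subset.
#'
#' @slot meta data.frame with columns \code{record_id}, \code{compound_id},
#'   \code{name}, \code{smiles}, \code{inchikey}, \code{instrument_type},
#'   \code{ionisation_mode}, \code{precursor_type}, \code{precursor_mz},
#'   \code{molecular_weight}, \code{collision_energy_value},
#'   \code{collision_energy_unit}. Missing values are \code{NA}, never guessed.
#' @slot peaks list of numeric matrices with columns \code{mz},
#'   \code{intensity}, sorted by ascending m/z.
#' @export
setClass("SpectrumSet",
         representation(meta = "data.frame", peaks = "list"))

.SPECTRUM_META_COLS <- c("record_id", "compound_id", "name", "smiles",
                         "inchikey", "instrument_type", "ionisation_mode",
                         "precursor_type", "precursor_mz", "molecular_weight",
                         "collision_energy_value", "collision_energy_unit")

setValidity("SpectrumSet", function(object) {
    msg <- NULL
    missing_cols <- setdiff(.SPECTRUM_META_COLS, colnames(object@meta))
    if (length(missing_cols))
        msg <- c(msg, paste("missing metadata columns:",
                            paste(missing_cols, collapse = ", ")))
    if (nrow(object@meta) != length(object@peaks))
        msg <- c(msg, "meta rows and peaks list length differ")
    if (anyDuplicated(object@meta$record_id))
        msg <- c(msg, "record_id values must be unique")
    for (i in seq_along(object@peaks)) {
        p <- object@peaks[[i]]
        if (!is.matrix(p) || ncol(p) != 2L) {
            msg <- c(msg, sprintf("peaks[[%d]] is not a 2-column matrix", i))
            break
        }
        if (nrow(p)) {
            if (any(!is.finite(p)) || any(p[, 1L] <= 0) || any(p[, 2L] < 0)) {
                msg <- c(msg, sprintf("peaks[[%d]] has invalid mz/intensity", i))
                break
            }
            if (is.unsorted(p[, 1L])) {
                msg <- c(msg, sprintf("peaks[[%d]] not sorted by mz", i))
                break
            }
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Binned spectral intensity matrix
#'
#' Rows are spectra, columns are the m/z bins of a \linkS4class{BinGrid};
#' entries are relative intensities in [0, 1], each nonempty row normalised so
#' its maximum is exactly 1. Stored sparsely: real spectral matrices are more
#' than 97\% zeros.
#'
#' @slot values sparse \code{dgCMatrix} of intensities.
#' @slot grid the \linkS4class{BinGrid} the columns refer to.
#' @export
setClass("SpectralMatrix",
         representation(values = "dgCMatrix", grid = "BinGrid"))

setValidity("SpectralMatrix", function(object) {
    msg <- NULL
    v <- object@values
    if (ncol(v) != nBins(object@grid))
        msg <- c(msg, "column count does not match the bin grid")
    if (length(v@x)) {
        if (any(v@x < 0) || any(v@x > 1))
            msg <- c(msg, "intensities must lie in [0, 1]")
    }
    if (is.null(rownames(v)))
        msg <- c(msg, "row ids (record ids) are required")
    if (is.null(msg)) TRUE else msg
})

#' Sparse principal component model
#'
#' Loadings, training scores and adjusted explained variance of a sparse PCA
#' fit (see \code{\link{fitSpca}}). Centering is part of the model so held-out
#' spectra are projected with training statistics only.
#'
#' @slot loadings sparse variables-by-components loading matrix (unit columns).
#' @slot center training column means used for centering.
#' @slot scores training score matrix.
#' @slot evr adjusted explained-variance ratio per component.
#' @slot penalty the sparsity penalty the model was fitted with.
#' @export
setClass("SpcaModel",
         representation(loadings = "dgCMatrix", center = "numeric",
                        scores = "matrix", evr = "numeric",
                        penalty = "numeric"))

setValidity("SpcaModel", function(object) {
    msg <- NULL
    if (nrow(object@loadings) != length(object@center))
        msg <- c(msg, "center length must equal loading rows")
    if (ncol(object@scores) != ncol(object@loadings))
        msg <- c(msg, "scores and loadings disagree on component count")
    if (length(object@evr) != ncol(object@loadings))
        msg <- c(msg, "one explained-variance value per component required")
    if (any(object@evr < -1e-12))
        msg <- c(msg, "explained variance cannot be negative")
    if (is.null(msg)) TRUE else msg
})

#' Multi-task feed-forward network
#'
#' A fully connected network mapping spectral features to per-bit activation
#' probabilities: shared hidden layer of \code{N} units, dropout, a second
#' ("task-specific") hidden layer of \code{NTS} units, and a sigmoid output
#' node per fingerprint bit. Built by \code{\link{buildNetwork}} and fitted by
#' \code{\link{trainNetwork}}.
#'
#' @slot weights list of weight matrices and bias vectors (W1, b1, W2, b2,
#'   W3, b3).
#' @slot hp hyperparameter list (see \code{\link{hyperparameters}}).
#' @slot nInputs input dimension.
#' @slot nTasks number of output bits.
#' @slot seed integer seed the initial weights were drawn under.
#' @slot history per-epoch training and validation loss (empty until trained).
#' @export
setClass("MultiTaskNet",
         representation(weights = "list", hp = "list", nInputs = "integer",
                        nTasks = "integer", seed = "integer",
                        history = "data.frame"))

#' Replicate ensemble with Bayes thresholds
#'
#' Five (generally an odd number of) independently initialised and trained
#' \linkS4class{MultiTaskNet} replicates, each with its own per-bit
#' binarization thresholds; final bit labels are obtained by majority voting
#' across replicates.
#'
#' @slot replicates list of trained \linkS4class{MultiTaskNet} objects.
#' @slot thresholds list of numeric threshold vectors, parallel to replicates.
#' @slot seeds integer seeds used for the replicates.
#' @export
setClass("FingerprintEnsemble",
         representation(replicates = "list", thresholds = "list",
                        seeds = "integer"))

setValidity("FingerprintEnsemble", function(object) {
    msg <- NULL
    k <- length(object@replicates)
    if (k < 1L) msg <- c(msg, "at least one replicate required")
    if (k %% 2L == 0L)
        msg <- c(msg, "replicate count must be odd (majority voting)")
    if (length(object@thresholds) != k)
        msg <- c(msg, "one threshold vector per replicate required")
    for (th in object@thresholds)
        if (any(th <= 0 | th >= 1)) {
            msg <- c(msg, "thresholds must lie strictly inside (0, 1)")
            break
        }
    if (is.null(msg)) TRUE else msg
})

## ------------------------------------------------------------------ accessors

#' @describeIn nSpectra number of records in a SpectrumSet.
#' @export
setMethod("nSpectra", "SpectrumSet", function(x) nrow(x@meta))

#' @describeIn nSpectra number of rows of a SpectralMatrix.
#' @export
setMethod("nSpectra", "SpectralMatrix", function(x) nrow(x@values))

#' @describeIn recordIds record ids of a SpectrumSet.
#' @export
setMethod("recordIds", "SpectrumSet", function(x) x@meta$record_id)

#' @describeIn recordIds row ids of a SpectralMatrix.
#' @export
setMethod("recordIds", "SpectralMatrix", function(x) rownames(x@values))

#' @describeIn compoundIds compound ids of a SpectrumSet.
#' @export
setMethod("compoundIds", "SpectrumSet", function(x) x@meta$compound_id)

#' @describeIn spectrumMeta metadata table of a SpectrumSet.
#' @export
setMethod("spectrumMeta", "SpectrumSet", function(x) x@meta)

#' @describeIn peakLists peak matrices of a SpectrumSet.
#' @export
setMethod("peakLists", "SpectrumSet", function(x) x@peaks)

#' @describeIn nBins bin count of a grid.
#' @export
setMethod("nBins", "BinGrid", function(x)
    as.integer(round((x@mzMax - x@mzMin) / x@step)) + 1L)

#' @describeIn nBins bin count of a binned matrix.
#' @export
setMethod("nBins", "SpectralMatrix", function(x) nBins(x@grid))

#' @describeIn binCenters centers of a grid.
#' @export
setMethod("binCenters", "BinGrid", function(x)
    x@mzMin + (seq_len(nBins(x)) - 1L) * x@step)

#' @describeIn binCenters centers of the grid behind a binned matrix.
#' @export
setMethod("binCenters", "SpectralMatrix", function(x) binCenters(x@grid))

#' @describeIn matrixValues sparse values of a SpectralMatrix.
#' @export
setMethod("matrixValues", "SpectralMatrix", function(x) x@values)

#' @describeIn loadings loadings of an SpcaModel.
#' @export
setMethod("loadings", "SpcaModel", function(x) x@loadings)

#' @describeIn scores training scores of an SpcaModel.
#' @export
setMethod("scores", "SpcaModel", function(x) x@scores)

#' @describeIn explainedVariance per-component (or cumulative) adjusted
#'   explained-variance ratio of an SpcaModel.
#' @export
setMethod("explainedVariance", "SpcaModel", function(x, cumulative = FALSE) {
    if (cumulative) cumsum(x@evr) else x@evr
})

#' Subset a SpectrumSet
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param i integer, logical or character (record id) index.
#' @param j,...,drop ignored.
#' @return a \linkS4class{SpectrumSet} with the selected records, in the
#'   requested order.
#' @export
setMethod("[", "SpectrumSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@meta$record_id)
    new("SpectrumSet",
        meta = x@meta[i, , drop = FALSE],
        peaks = x@peaks[i])
})

setMethod("show", "BinGrid", function(object) {
    cat(sprintf("BinGrid: %.4g..%.4g Da, step %.4g Da, %d bins\n",
                object@mzMin, object@mzMax, object@step, nBins(object)))
})

setMethod("show", "SpectrumSet", function(object) {
    n <- nSpectra(object)
    cat(sprintf("SpectrumSet with %d record%s, %d compound%s\n",
                n, if (n == 1L) "" else "s",
                length(unique(object@meta$compound_id)),
                if (length(unique(object@meta$compound_id)) == 1L) "" else "s"))
    if (n) {
        npk <- vapply(object@peaks, nrow, integer(1))
        cat(sprintf("  peaks per spectrum: median %g (range %d..%d)\n",
                    median(npk), min(npk), max(npk)))
    }
})

setMethod("show", "SpectralMatrix", function(object) {
    v <- object@values
    cat(sprintf("SpectralMatrix: %d spectra x %d bins, %.1f%% zero\n",
                nrow(v), ncol(v),
                100 * (1 - length(v@x) / max(1, prod(dim(v))))))
})

setMethod("show", "SpcaModel", function(object) {
    cat(sprintf(paste0("SpcaModel: %d components over %d variables, ",
                       "%.1f%% cumulative explained variance\n"),
                ncol(object@loadings), nrow(object@loadings),
                100 * sum(object@evr)))
})

setMethod("show", "MultiTaskNet", function(object) {
    cat(sprintf("MultiTaskNet: %d -> %d -> %d -> %d (%s hidden, sigmoid out)%s\n",
                object@nInputs, object@hp$n_neurons, object@hp$n_task_specific,
                object@nTasks, object@hp$activation,
                if (nrow(object@history)) sprintf(", trained %d epochs",
                                                  nrow(object@history)) else ""))
})

setMethod("show", "FingerprintEnsemble", function(object) {
    cat(sprintf("FingerprintEnsemble: %d replicates, %d tasks\n",
                length(object@replicates),
                length(object@thresholds[[1]])))
})
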