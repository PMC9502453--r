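#' @import methods
#' @importFrom stats predict rnorm runif rbinom sd quantile median var qt
#'   setNames
#' @importFrom utils head read.delim write.table
NULL

#' Number of spectra in an object
#'
#' @param x a \linkS4class{SpectrumSet} or \linkS4class{SpectralMatrix}.
#' @return integer count of spectra.
#' @export
setGeneric("nSpectra", function(x) standardGeneric("nSpectra"))

#' Record identifiers
#'
#' @param x an object holding spectral records.
#' @return character vector of record ids, one per spectrum.
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' Compound identifiers
#'
#' @param x an object holding spectral records.
#' @return character vector of compound ids, one per spectrum.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Per-record metadata
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @return a data.frame with one row per record.
#' @export
setGeneric("spectrumMeta", function(x) standardGeneric("spectrumMeta"))

#' Peak lists
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @return list of two-column matrices (mz, intensity), one per record.
#' @export
setGeneric("peakLists", function(x) standardGeneric("peakLists"))

#' Number of m/z bins of a grid or binned matrix
#'
#' @param x a \linkS4class{BinGrid} or \linkS4class{SpectralMatrix}.
#' @return integer bin count.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Bin center m/z values
#'
#' @param x a \linkS4class{BinGrid} or \linkS4class{SpectralMatrix}.
#' @return numeric vector of bin centers (Da), ascending.
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' Matrix of binned intensities
#'
#' @param x a \linkS4class{SpectralMatrix}.
#' @return sparse \code{dgCMatrix}, rows = spectra, columns = bins.
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))

#' Component loadings of a fitted dimensionality-reduction model
#'
#' @param x a \linkS4class{SpcaModel}.
#' @return sparse loadings matrix, variables by components.
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))

#' Component scores of a fitted dimensionality-reduction model
#'
#' @param x a \linkS4class{SpcaModel}.
#' @return dense score matrix, spectra by components.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Explained-variance ratios
#'
#' @param x a \linkS4class{SpcaModel}.
#' @param cumulative return the cumulative series?
#' @return numeric vector, one value per component.
#' @export
setGeneric("explainedVariance",
           function(x, cumulative = FALSE) standardGeneric("explainedVariance"))
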