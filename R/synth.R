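## Synthetic spectrum-fingerprint generator. Emulates the statistical
## structure the pipeline must exploit: binary fingerprints with ~23%
## active bits, a fixed global mapping from each bit to a small set of
## characteristic m/z bins, several spectra per compound with
## multiplicative intensity noise, per-spectrum loss of a bit's peaks
## (acquisition variability), spurious noise peaks, and repository-style
## metadata that passes the default curation rules. It makes no attempt at
## physically realistic fragmentation chemistry; only the statistical
## learning problem is emulated.

#' Synthetic-dataset settings
#'
#' @param n_compounds number of distinct molecules.
#' @param spectra_per_compound inclusive range of spectra per compound.
#' @param n_bits fingerprint length.
#' @param active_bit_probability per-bit activation probability (0.23
#'   mirrors the ~77\% zero fraction of real MACCS fingerprints).
#' @param peaks_per_active_bit characteristic bins per bit.
#' @param noise_peaks inclusive range of spurious peaks per spectrum.
#' @param intensity_noise_cv coefficient of variation of the multiplicative
#'   (log-normal) intensity noise.
#' @param bit_dropout probability that an active bit's peaks are missing
#'   from a given spectrum.
#' @param block_size correlation knob: bits are grouped into blocks of this
#'   size sharing a latent activation (1 = independent bits, the default).
#' @param grid the \linkS4class{BinGrid} characteristic bins are drawn
#'   from.
#' @param seed RNG seed; identical config + seed gives byte-identical
#'   datasets.
#' @return a list of class \code{SynthConfig}.
#' @export
synthConfig <- function(n_compounds = 300L, spectra_per_compound = c(2L, 8L),
                        n_bits = 166L, active_bit_probability = 0.23,
                        peaks_per_active_bit = 3L, noise_peaks = c(0L, 10L),
                        intensity_noise_cv = 0.3, bit_dropout = 0.1,
                        block_size = 1L, grid = makeGrid(), seed = 1L) {
    stopifnot(n_compounds >= 1, n_bits >= 1,
              active_bit_probability >= 0, active_bit_probability <= 1,
              bit_dropout >= 0, bit_dropout <= 1,
              peaks_per_active_bit >= 1, intensity_noise_cv >= 0,
              length(spectra_per_compound) == 2L,
              spectra_per_compound[1] <= spectra_per_compound[2],
              length(noise_peaks) == 2L, block_size >= 1L)
    structure(list(n_compounds = as.integer(n_compounds),
                   spectra_per_compound = as.integer(spectra_per_compound),
                   n_bits = as.integer(n_bits),
                   active_bit_probability = active_bit_probability,
                   peaks_per_active_bit = as.integer(peaks_per_active_bit),
                   noise_peaks = as.integer(noise_peaks),
                   intensity_noise_cv = intensity_noise_cv,
                   bit_dropout = bit_dropout,
                   block_size = as.integer(block_size),
                   grid = grid, seed = as.integer(seed)),
              class = "SynthConfig")
}

#' Characteristic-bin map for fingerprint bits
#'
#' Draws, under the config seed, \code{peaks_per_active_bit} distinct bin
#' centers for each bit (no two bits share a bin, so the mapping is
#' learnable and injective).
#'
#' @param config a \code{\link{synthConfig}}.
#' @return list of length \code{n_bits}; element t holds bit t's
#'   characteristic m/z values.
#' @export
makeBitPeakMap <- function(config) {
    need <- config$n_bits * config$peaks_per_active_bit
    nb <- nBins(config$grid)
    if (nb < need)
        stop(sprintf("grid has %d bins; need %d for %d bits x %d peaks",
                     nb, need, config$n_bits, config$peaks_per_active_bit))
    set.seed(config$seed)
    centers <- binCenters(config$grid)
    chosen <- sample.int(nb, need)
    split(centers[chosen],
          rep(seq_len(config$n_bits), each = config$peaks_per_active_bit))
}

.drawFingerprints <- function(config) {
    p <- config$active_bit_probability
    n <- config$n_compounds
    T <- config$n_bits
    if (config$block_size <= 1L) {
        fp <- matrix(rbinom(n * T, 1L, p), n, T)
    } else {
        n_blocks <- ceiling(T / config$block_size)
        block_of <- rep(seq_len(n_blocks),
                        each = config$block_size)[seq_len(T)]
        fp <- matrix(0L, n, T)
        for (i in seq_len(n)) {
            latent <- rbinom(n_blocks, 1L, p)
            flip <- rbinom(T, 1L, 0.1)
            fp[i, ] <- as.integer(xor(latent[block_of] == 1L, flip == 1L))
        }
    }
    rownames(fp) <- sprintf("CPD_%04d", seq_len(n))
    colnames(fp) <- paste0("bit", seq_len(T))
    fp
}

.synthMeta <- function(record_id, compound_id, mw, ce) {
    data.frame(record_id = record_id, compound_id = compound_id,
               name = compound_id, smiles = NA_character_,
               inchikey = NA_character_, instrument_type = "LC-ESI-QFT",
               ionisation_mode = "positive", precursor_type = "[M+H]+",
               precursor_mz = mw + 1.00728, molecular_weight = mw,
               collision_energy_value = ce, collision_energy_unit = "V",
               stringsAsFactors = FALSE)
}

.synthCore <- function(config, adversarial) {
    map <- makeBitPeakMap(config)     # consumes config$seed
    set.seed(config$seed + 1L)
    fp <- .drawFingerprints(config)
    ## stable base intensity per characteristic peak
    base_int <- lapply(map, function(mzs) runif(length(mzs), 20, 100))
    sdlog <- if (config$intensity_noise_cv > 0)
        sqrt(log(1 + config$intensity_noise_cv^2)) else 0
    grid <- config$grid

    meta_rows <- list()
    peak_list <- list()
    for (ci in seq_len(config$n_compounds)) {
        cid <- rownames(fp)[ci]
        active <- which(fp[ci, ] == 1L)
        char_mz <- unlist(map[active], use.names = FALSE)
        mw <- round(max(c(char_mz, grid@mzMin + 50)) + 21.0, 3)
        n_spec <- sample(seq.int(config$spectra_per_compound[1],
                                 config$spectra_per_compound[2]), 1L)
        ce <- round(runif(n_spec, 10, 60), 1)
        for (s in seq_len(n_spec)) {
            mz <- numeric(0)
            it <- numeric(0)
            if (!adversarial && length(active)) {
                kept <- active[runif(length(active)) >= config$bit_dropout]
                for (b in kept) {
                    mz <- c(mz, map[[b]])
                    noise <- if (sdlog > 0)
                        exp(rnorm(length(map[[b]]), 0, sdlog)) else 1
                    it <- c(it, base_int[[b]] * noise)
                }
            }
            n_noise <- if (adversarial)
                sample(5:30, 1L)
            else
                sample(seq.int(config$noise_peaks[1],
                               config$noise_peaks[2]), 1L)
            ## top up so every record survives the min-peak rule
            n_noise <- max(n_noise, 2L - length(mz))
            if (n_noise > 0) {
                nm <- runif(n_noise, grid@mzMin, min(mw, grid@mzMax))
                mz <- c(mz, nm)
                it <- c(it, runif(n_noise, 1, 30))
            }
            it <- it * 100 / max(it)
            rid <- sprintf("%s_S%02d", cid, s)
            meta_rows[[length(meta_rows) + 1L]] <-
                .synthMeta(rid, cid, mw, ce[s])
            pk <- cbind(mz = mz, intensity = it)
            peak_list[[length(peak_list) + 1L]] <-
                pk[order(pk[, 1L]), , drop = FALSE]
        }
    }
    records <- SpectrumSet(do.call(rbind, meta_rows), peak_list)
    structure(list(records = records, fingerprints = fp,
                   bit_peak_map = map, config = config,
                   adversarial = adversarial),
              class = "SynthDataset")
}

#' Generate a synthetic spectrum-fingerprint dataset
#'
#' Each compound draws a fingerprint; each of its spectra contains the
#' characteristic peaks of its active bits (each bit's peaks dropped with
#' probability \code{bit_dropout}), log-normal intensity noise, and
#' spurious noise peaks below the precursor. Intensities are scaled so
#' every spectrum's maximum is 100. Metadata are populated so that all
#' records pass the default curation rules.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return a \code{SynthDataset} list: \code{records}
#'   (\linkS4class{SpectrumSet}), \code{fingerprints} (compounds by bits),
#'   \code{bit_peak_map}, \code{config}.
#' @export
generateSynth <- function(config = synthConfig()) .synthCore(config, FALSE)

#' Generate an adversarial (pure-noise) dataset
#'
#' Identical metadata and fingerprint marginals, but spectra are drawn
#' independently of the fingerprints: nothing is learnable, so a model
#' trained on this data must score near the random-fingerprint baseline
#' and its non-error rate near 0.5. Serves as the pipeline's negative
#' control.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return a \code{SynthDataset}, with \code{adversarial = TRUE}.
#' @export
generateAdversarial <- function(config = synthConfig()) .synthCore(config, TRUE)

#' @export
print.SynthDataset <- function(x, ...) {
    cat(sprintf("SynthDataset (%s): %d compounds, %d spectra, %d bits\n",
                if (x$adversarial) "adversarial" else "signal",
                nrow(x$fingerprints), nSpectra(x$records),
                ncol(x$fingerprints)))
    invisible(x)
}

#' Fingerprint targets aligned to a set of records
#'
#' @param dataset a \code{SynthDataset}.
#' @param record_ids record ids to align to (defaults to all records).
#' @return binary matrix with one row per record: the fingerprint of the
#'   record's compound.
#' @export
spectrumTargets <- function(dataset, record_ids = NULL) {
    meta <- spectrumMeta(dataset$records)
    if (is.null(record_ids)) record_ids <- meta$record_id
    cid <- meta$compound_id[match(record_ids, meta$record_id)]
    out <- dataset$fingerprints[cid, , drop = FALSE]
    rownames(out) <- record_ids
    out
}
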