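## Shared fixtures, all built in code.

## A small but fully populated record set covering the curation rules.
makeRecordSet <- function(rows, peaks) {
    meta <- do.call(rbind, lapply(rows, function(r) {
        base <- list(record_id = r$id, compound_id = r$id,
                     name = r$id, smiles = NA_character_,
                     inchikey = NA_character_,
                     instrument_type = "LC-ESI-QTOF",
                     ionisation_mode = "positive",
                     precursor_type = "[M+H]+",
                     precursor_mz = 301.10728, molecular_weight = 300.1,
                     collision_energy_value = 35,
                     collision_energy_unit = "V")
        base[names(r$over)] <- r$over
        as.data.frame(base, stringsAsFactors = FALSE)
    }))
    SpectrumSet(meta, peaks)
}

defaultPeaks <- function(n = 6, mz_max = 290) {
    cbind(mz = seq(50, mz_max, length.out = n),
          intensity = seq(10, 100, length.out = n))
}

## Small synthetic dataset for module-level tests: compact grid, few
## compounds, quick to generate and to train on.
tinySynthConfig <- function(seed = 42L, n_compounds = 40L, ...) {
    synthConfig(n_compounds = n_compounds,
                grid = makeGrid(45, 120, 0.1), seed = seed, ...)
}

## A tiny trained ensemble used by the model-level tests. Built once per
## test run and cached.
.tinyEnsembleCache <- new.env(parent = emptyenv())
tinyEnsemble <- function() {
    if (!is.null(.tinyEnsembleCache$obj)) return(.tinyEnsembleCache$obj)
    set.seed(9)
    n <- 60L; p <- 12L; tasks <- 7L
    x <- matrix(runif(n * p), n, p)
    w <- matrix(rnorm(p * tasks), p, tasks)
    y <- (x %*% w > 0) * 1L
    rownames(x) <- rownames(y) <- sprintf("r%02d", seq_len(n))
    hp <- hyperparameters(n_neurons = 8, n_task_specific = 10,
                          learning_rate = 0.01, batch_size = 16,
                          patience = 5, optimizer = "adam",
                          activation = "relu", dropout = 0)
    ens <- trainEnsemble(hp, x[1:40, ], y[1:40, ], x[41:50, ], y[41:50, ],
                         n_replicates = 5, base_seed = 3, max_epochs = 15)
    .tinyEnsembleCache$obj <- list(ensemble = ens, x = x, y = y)
    .tinyEnsembleCache$obj
}
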