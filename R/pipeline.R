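## Pipeline orchestration: each subcommand reads its declared inputs from
## the artifact directory, writes its declared outputs, and drops a JSON
## manifest (inputs, outputs, config hash, seed, versions) next to every
## artifact so runs are auditable and reproducible. Stages never mutate
## their inputs; the pipeline is a DAG of files.

.defaultPipelineConfig <- function() {
    list(paths = list(outdir = "ms2fp_artifacts"),
         synth = list(n_compounds = 300L, seed = 1L, adversarial = FALSE),
         grid = list(mz_min = 45.0, mz_max = 704.5, step = 0.1),
         curation = list(strict = FALSE),
         split = list(fractions = c(0.72, 0.15, 0.13), seed = 1L),
         dimred = list(enabled = FALSE, k = 100L, sparsity = 0),
         model = list(n_neurons = 150L, n_task_specific = 250L,
                      learning_rate = 0.001, activation = "relu",
                      dropout = 0.2, batch_size = 128L, patience = 15L,
                      optimizer = "adam", n_replicates = 5L,
                      max_epochs = 50L, base_seed = 1L),
         tune = list(n_trials = 20L, base_seed = 1L, max_epochs = 40L))
}

.mergeConfig <- function(base, override) {
    for (nm in names(override)) {
        if (is.list(base[[nm]]) && is.list(override[[nm]]))
            base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
        else base[[nm]] <- override[[nm]]
    }
    base
}

#' Load a pipeline configuration
#'
#' @param config a YAML file path, a list of overrides, or NULL for the
#'   defaults. Omitted fields fall back to package defaults.
#' @return the merged configuration list.
#' @export
pipelineConfig <- function(config = NULL) {
    base <- .defaultPipelineConfig()
    if (is.null(config)) return(base)
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    if (!is.list(config)) stop("config must be a YAML file path or a list")
    .mergeConfig(base, config)
}

.configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(yaml::as.yaml(config), tmp)
    unname(tools::md5sum(tmp))
}

.writeManifest <- function(outdir, stage, inputs, outputs, config, seed) {
    manifest <- list(stage = stage, inputs = inputs, outputs = outputs,
                     config_hash = .configHash(config),
                     seed = seed,
                     r_version = R.version.string,
                     package_version =
                         as.character(utils::packageVersion("ms2fp")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest,
                         file.path(outdir, paste0(stage, ".manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE)
}

.need <- function(path, what) {
    if (!file.exists(path))
        stop(sprintf("missing upstream artifact (%s): %s", what, path))
    path
}

#' Run one pipeline stage
#'
#' Subcommands: \code{synth} (generate synthetic library), \code{cure}
#' (curation cascade), \code{vectorize} (binned sparse matrix),
#' \code{split} (compound-grouped partition), \code{reduce} (SPCA scores,
#' fitted on training rows only), \code{train} (replicate ensemble +
#' thresholds), \code{tune} (TPE search, trial log), \code{predict}
#' (binary fingerprints for every spectrum), \code{evaluate} (per-set NER
#' and JT report), \code{match} (candidate ranking for each test
#' spectrum). Every stage writes a manifest beside its outputs.
#'
#' @param subcommand one of the stages above.
#' @param config YAML path, override list or NULL (see
#'   \code{\link{pipelineConfig}}).
#' @return invisibly, a list of the stage's main outputs.
#' @export
runPipeline <- function(subcommand = c("synth", "cure", "vectorize",
                                       "split", "reduce", "train", "tune",
                                       "predict", "evaluate", "match"),
                        config = NULL) {
    subcommand <- match.arg(subcommand)
    cfg <- pipelineConfig(config)
    outdir <- cfg$paths$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(outdir, ...)
    grid <- makeGrid(cfg$grid$mz_min, cfg$grid$mz_max, cfg$grid$step)
    out <- switch(subcommand,
        synth = {
            sc <- synthConfig(n_compounds = cfg$synth$n_compounds,
                              grid = grid, seed = cfg$synth$seed)
            ds <- if (isTRUE(cfg$synth$adversarial))
                generateAdversarial(sc) else generateSynth(sc)
            writeSpectra(ds$records, p("spectra.msp"))
            writeFingerprints(ds$fingerprints, p("fingerprints.tsv"))
            .writeManifest(outdir, "synth", list(),
                           list("spectra.msp", "fingerprints.tsv"),
                           cfg, cfg$synth$seed)
            list(records = ds$records)
        },
        cure = {
            src <- cfg$paths$spectra
            if (is.null(src)) src <- p("spectra.msp")
            .need(src, "spectral library")
            recs <- readSpectra(src, canonicalize = FALSE)
            if (nSpectra(recs) == 0L)
                stop("no records parsed from ", src)
            cured <- cureSpectra(recs, strict = isTRUE(cfg$curation$strict))
            writeSpectra(cured$records, p("cured.msp"))
            for (nm in names(cured$reports))
                writeCurationReport(cured$reports[[nm]],
                                    p(sprintf("curation_%s.tsv", nm)))
            message(sprintf("curation kept %d of %d records",
                            nSpectra(cured$records), nSpectra(recs)))
            .writeManifest(outdir, "cure", list(src), list("cured.msp"),
                           cfg, NA)
            cured
        },
        vectorize = {
            recs <- readSpectra(.need(p("cured.msp"), "cured records"),
                                canonicalize = FALSE)
            sm <- binSpectra(recs, grid)
            writeSparseMatrix(sm, p("matrix.tsv"))
            .writeManifest(outdir, "vectorize", list("cured.msp"),
                           list("matrix.tsv"), cfg, NA)
            list(matrix = sm)
        },
        split = {
            recs <- readSpectra(.need(p("cured.msp"), "cured records"),
                                canonicalize = FALSE)
            sp <- groupSplit(recs, fractions = cfg$split$fractions,
                             seed = cfg$split$seed)
            writeSplit(sp, p("split_records.tsv"), p("split_compounds.tsv"))
            .writeManifest(outdir, "split", list("cured.msp"),
                           list("split_records.tsv", "split_compounds.tsv"),
                           cfg, cfg$split$seed)
            list(split = sp)
        },
        reduce = {
            sm <- readSparseMatrix(.need(p("matrix.tsv"), "binned matrix"))
            splits <- read.delim(.need(p("split_records.tsv"),
                                       "split assignment"))
            train_ids <- splits$record_id[splits$set == "train"]
            v <- if (is(sm, "SpectralMatrix")) sm@values else sm
            model <- fitSpca(v[rownames(v) %in% train_ids, , drop = FALSE],
                             k = cfg$dimred$k,
                             sparsity = cfg$dimred$sparsity)
            sc <- predict(model, v)
            rownames(sc) <- rownames(v)
            scm <- Matrix::Matrix(sc, sparse = TRUE)
            writeSparseMatrix(scm, p("scores.tsv"))
            saveRDS(model, p("spca_model.rds"))
            .writeManifest(outdir, "reduce",
                           list("matrix.tsv", "split_records.tsv"),
                           list("scores.tsv", "spca_model.rds"), cfg, NA)
            list(model = model)
        },
        train = {
            d <- .loadTrainingData(cfg, p)
            hp <- hyperparameters(
                n_neurons = cfg$model$n_neurons,
                n_task_specific = cfg$model$n_task_specific,
                learning_rate = cfg$model$learning_rate,
                activation = cfg$model$activation,
                dropout = cfg$model$dropout,
                batch_size = cfg$model$batch_size,
                patience = cfg$model$patience,
                optimizer = cfg$model$optimizer)
            ens <- trainEnsemble(hp, d$x$train, d$y$train, d$x$val,
                                 d$y$val,
                                 n_replicates = cfg$model$n_replicates,
                                 base_seed = cfg$model$base_seed,
                                 max_epochs = cfg$model$max_epochs)
            saveRDS(ens, p("ensemble.rds"))
            .writeManifest(outdir, "train",
                           list("matrix.tsv", "fingerprints.tsv",
                                "split_records.tsv"),
                           list("ensemble.rds"), cfg, cfg$model$base_seed)
            list(ensemble = ens)
        },
        tune = {
            d <- .loadTrainingData(cfg, p)
            res <- tuneHyperparameters(d$x$train, d$y$train, d$x$val,
                                       d$y$val,
                                       n_trials = cfg$tune$n_trials,
                                       base_seed = cfg$tune$base_seed,
                                       max_epochs = cfg$tune$max_epochs)
            writeTrialLog(res$trials, p("trials.tsv"))
            .writeManifest(outdir, "tune",
                           list("matrix.tsv", "fingerprints.tsv",
                                "split_records.tsv"),
                           list("trials.tsv"), cfg, cfg$tune$base_seed)
            res
        },
        predict = {
            ens <- readRDS(.need(p("ensemble.rds"), "trained ensemble"))
            x <- .featureMatrix(cfg, p)
            pred <- predict(ens, x)
            writeFingerprints(pred, p("predicted_fingerprints.tsv"))
            .writeManifest(outdir, "predict", list("ensemble.rds"),
                           list("predicted_fingerprints.tsv"), cfg, NA)
            list(predictions = pred)
        },
        evaluate = {
            pred <- readFingerprints(.need(p("predicted_fingerprints.tsv"),
                                           "predictions"))
            d <- .loadTrainingData(cfg, p)
            rows <- list()
            for (set in c("train", "val", "test")) {
                ids <- intersect(rownames(pred), rownames(d$y[[set]]))
                rep <- evaluationReport(pred[ids, , drop = FALSE],
                                        d$y[[set]][ids, , drop = FALSE])
                rows[[set]] <- data.frame(set = set, n = length(ids),
                                          NER = rep$ner,
                                          JT = rep$mean_jt)
            }
            tab <- do.call(rbind, rows)
            write.table(tab, p("evaluation.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            .writeManifest(outdir, "evaluate",
                           list("predicted_fingerprints.tsv"),
                           list("evaluation.tsv"), cfg, NA)
            list(report = tab)
        },
        match = {
            pred <- readFingerprints(.need(p("predicted_fingerprints.tsv"),
                                           "predictions"))
            libfile <- cfg$paths$candidate_library
            if (is.null(libfile)) libfile <- p("fingerprints.tsv")
            lib <- readFingerprints(.need(libfile, "candidate library"))
            splits <- read.delim(.need(p("split_records.tsv"),
                                       "split assignment"))
            test_ids <- intersect(rownames(pred),
                                  splits$record_id[splits$set == "test"])
            all_rank <- list()
            for (rid in test_ids) {
                true_id <- splits$compound_id[splits$record_id == rid]
                rk <- rankCandidates(pred[rid, ], lib, true_id = true_id)
                all_rank[[rid]] <- data.frame(query_id = rid,
                                              head(rk, 10L),
                                              true_rank =
                                                  attr(rk, "true_rank"))
            }
            tab <- do.call(rbind, all_rank)
            rownames(tab) <- NULL
            write.table(tab, p("rankings.tsv"), sep = "\t", quote = FALSE,
                        row.names = FALSE)
            .writeManifest(outdir, "match",
                           list("predicted_fingerprints.tsv",
                                if (is.null(cfg$paths$candidate_library))
                                    "fingerprints.tsv"
                                else cfg$paths$candidate_library),
                           list("rankings.tsv"), cfg, NA)
            list(rankings = tab)
        })
    invisible(out)
}

.featureMatrix <- function(cfg, p) {
    src <- if (isTRUE(cfg$dimred$enabled)) p("scores.tsv") else
        p("matrix.tsv")
    sm <- readSparseMatrix(.need(src, "feature matrix"))
    v <- if (is(sm, "SpectralMatrix")) sm@values else sm
    as.matrix(v)
}

.loadTrainingData <- function(cfg, p) {
    x <- .featureMatrix(cfg, p)
    fps <- readFingerprints(.need(p("fingerprints.tsv"), "fingerprints"))
    splits <- read.delim(.need(p("split_records.tsv"), "split assignment"))
    xs <- list(); ys <- list()
    for (set in c("train", "val", "test")) {
        ids <- intersect(rownames(x), splits$record_id[splits$set == set])
        cid <- splits$compound_id[match(ids, splits$record_id)]
        xs[[set]] <- x[ids, , drop = FALSE]
        y <- fps[cid, , drop = FALSE]
        rownames(y) <- ids
        ys[[set]] <- y
    }
    list(x = xs, y = ys)
}
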