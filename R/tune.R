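## Hyperparameter search with a Tree-structured Parzen Estimator and
## regression-based effect analysis. The objective rewards validation
## similarity while penalising the train/validation gap, so configurations
## that overfit score poorly even when their validation similarity is high.

#' Tuning objective
#'
#' \code{F = JT_val * (1 - |JT_train - JT_val|)}: the validation
#' Jaccard-Tanimoto similarity, discounted by the absolute
#' train/validation gap. \code{F} is bounded by \code{JT_val} and lies in
#' [0, 1].
#'
#' @param jt_train,jt_val mean Jaccard-Tanimoto similarities on the
#'   training and validation sets, both in [0, 1].
#' @return the objective value.
#' @export
objectiveF <- function(jt_train, jt_val) {
    if (any(c(jt_train, jt_val) < 0) || any(c(jt_train, jt_val) > 1))
        stop("similarities must lie in [0, 1]")
    jt_val * (1 - abs(jt_train - jt_val))
}

#' Default hyperparameter search space
#'
#' Bounds for the eight tunable settings: hidden width 50-100, task-specific
#' width 250-500, learning rate 1e-4 to 1e-2 (log scale), sigmoid/ReLU
#' activation, dropout 0-0.5, batch size 2000-4000, patience 50-150 epochs,
#' and the Adam/SGD/RMSprop optimizers. For small (synthetic) datasets the
#' batch-size upper bound should be reduced with \code{max_batch}.
#'
#' @param max_batch optional cap applied to the batch-size bounds (use about
#'   a quarter of the training-set size for small data).
#' @return a named list of parameter descriptors for
#'   \code{\link{tpeSearch}}.
#' @export
tuningSpace <- function(max_batch = NULL) {
    bs_low <- 2000L; bs_high <- 4000L
    if (!is.null(max_batch)) {
        bs_high <- max(2L, min(bs_high, as.integer(max_batch)))
        bs_low <- min(bs_low, bs_high)
        if (bs_low >= bs_high) bs_low <- max(2L, bs_high %/% 2L)
    }
    list(
        n_neurons = list(type = "integer", low = 50, high = 100),
        n_task_specific = list(type = "integer", low = 250, high = 500),
        learning_rate = list(type = "numeric", low = 1e-4, high = 1e-2,
                             log = TRUE),
        activation = list(type = "categorical",
                          values = c("sigmoid", "relu")),
        dropout = list(type = "numeric", low = 0, high = 0.5),
        batch_size = list(type = "integer", low = bs_low, high = bs_high),
        patience = list(type = "integer", low = 50, high = 150),
        optimizer = list(type = "categorical",
                         values = c("adam", "sgd", "rmsprop")))
}

.sampleUniform <- function(space) {
    out <- list()
    for (nm in names(space)) {
        d <- space[[nm]]
        out[[nm]] <- switch(d$type,
            categorical = sample(d$values, 1L),
            integer = sample(seq.int(d$low, d$high), 1L),
            numeric = if (isTRUE(d$log))
                exp(runif(1, log(d$low), log(d$high)))
            else runif(1, d$low, d$high))
    }
    out
}

.parzen <- function(vals, low, high, log = FALSE) {
    if (log) { vals <- log(vals); low <- log(low); high <- log(high) }
    rng <- high - low
    bw <- 1.06 * sd(c(vals, low, high)) * (length(vals) + 2)^(-0.2)
    bw <- max(bw, rng / 50)
    list(means = vals, bw = bw, low = low, high = high, log = log)
}

.parzenDensity <- function(kde, x) {
    if (kde$log) x <- log(x)
    rng <- kde$high - kde$low
    ## uniform prior component keeps densities bounded away from zero
    dens <- vapply(x, function(xi)
        mean(stats::dnorm(xi, kde$means, kde$bw)), numeric(1))
    (dens * length(kde$means) + 1 / rng) / (length(kde$means) + 1)
}

.parzenSample <- function(kde, n) {
    mu <- sample(kde$means, n, replace = TRUE)
    x <- rnorm(n, mu, kde$bw)
    x <- pmin(pmax(x, kde$low), kde$high)
    if (kde$log) exp(x) else x
}

.tpePropose <- function(space, trials, gamma, n_candidates) {
    f <- vapply(trials, function(t) ifelse(is.finite(t$F), t$F, -Inf),
                numeric(1))
    ord <- order(f, decreasing = TRUE)
    n_good <- max(1L, ceiling(gamma * sum(is.finite(f))))
    good <- trials[ord[seq_len(n_good)]]
    bad <- trials[ord[-seq_len(n_good)]]
    if (!length(bad)) bad <- good
    out <- list()
    for (nm in names(space)) {
        d <- space[[nm]]
        tmpl <- if (d$type == "categorical") character(1) else numeric(1)
        gv <- vapply(good, function(t) t$hp[[nm]], tmpl)
        bv <- vapply(bad, function(t) t$hp[[nm]], tmpl)
        if (d$type == "categorical") {
            pg <- (table(factor(gv, levels = d$values)) + 1) /
                (length(gv) + length(d$values))
            pb <- (table(factor(bv, levels = d$values)) + 1) /
                (length(bv) + length(d$values))
            cand <- sample(d$values, n_candidates, replace = TRUE,
                           prob = pg)
            score <- as.numeric(pg[cand] / pb[cand])
            out[[nm]] <- cand[which.max(score)]
        } else {
            kg <- .parzen(as.numeric(gv), d$low, d$high, isTRUE(d$log))
            kb <- .parzen(as.numeric(bv), d$low, d$high, isTRUE(d$log))
            cand <- .parzenSample(kg, n_candidates)
            score <- .parzenDensity(kg, cand) / .parzenDensity(kb, cand)
            pick <- cand[which.max(score)]
            out[[nm]] <- if (d$type == "integer")
                as.integer(min(max(round(pick), d$low), d$high)) else pick
        }
    }
    out
}

#' Tree-structured Parzen Estimator search
#'
#' Sequential model-based optimisation: after \code{n_startup} uniform
#' trials, past trials are split into a good fraction (\code{gamma}, by
#' objective value) and the rest; univariate Parzen densities over the good
#' and bad values propose the candidate maximising their density ratio.
#' A crashing trial is recorded as failed and the search continues. The
#' trial sequence is reproducible under \code{base_seed}.
#'
#' @param space parameter descriptors (see \code{\link{tuningSpace}}): each
#'   a list with \code{type} ("numeric", "integer", "categorical"),
#'   bounds \code{low}/\code{high} (optionally \code{log = TRUE}) or
#'   \code{values}.
#' @param eval_fun function of \code{(hp, seed)} returning either a single
#'   numeric objective value or a list with \code{jt_train} and
#'   \code{jt_val} (combined by \code{\link{objectiveF}}).
#' @param n_trials number of trials.
#' @param base_seed RNG seed for the whole search.
#' @param n_startup uniform trials before the Parzen model kicks in.
#' @param gamma good-fraction quantile.
#' @param n_candidates candidates scored per proposal.
#' @param prior_trials optional trial list from an earlier search to resume
#'   from; numbering continues.
#' @return list with \code{best} (the argmax-F trial) and \code{trials}
#'   (all trials: \code{hp}, \code{jt_train}, \code{jt_val}, \code{F},
#'   \code{index}, \code{seed}, \code{failed}).
#' @export
tpeSearch <- function(space, eval_fun, n_trials = 100L, base_seed = 1L,
                      n_startup = 10L, gamma = 0.25, n_candidates = 24L,
                      prior_trials = NULL) {
    set.seed(base_seed)
    trials <- if (is.null(prior_trials)) list() else prior_trials
    offset <- length(trials)
    for (i in seq_len(n_trials)) {
        idx <- offset + i
        done <- Filter(function(t) is.finite(t$F), trials)
        hp <- if (length(done) < n_startup)
            .sampleUniform(space)
        else
            .tpePropose(space, done, gamma, n_candidates)
        trial_seed <- (base_seed + idx * 101L) %% .Machine$integer.max
        res <- tryCatch(eval_fun(hp, trial_seed), error = function(e) e)
        if (inherits(res, "error")) {
            trials[[idx]] <- list(hp = hp, jt_train = NA_real_,
                                  jt_val = NA_real_, F = NA_real_,
                                  index = idx, seed = trial_seed,
                                  failed = TRUE,
                                  message = conditionMessage(res))
            next
        }
        if (is.list(res)) {
            fval <- objectiveF(res$jt_train, res$jt_val)
            trials[[idx]] <- list(hp = hp, jt_train = res$jt_train,
                                  jt_val = res$jt_val, F = fval,
                                  index = idx, seed = trial_seed,
                                  failed = FALSE)
        } else {
            trials[[idx]] <- list(hp = hp, jt_train = NA_real_,
                                  jt_val = NA_real_, F = as.numeric(res),
                                  index = idx, seed = trial_seed,
                                  failed = FALSE)
        }
    }
    fvals <- vapply(trials, function(t) ifelse(is.finite(t$F), t$F, -Inf),
                    numeric(1))
    list(best = trials[[which.max(fvals)]], trials = trials)
}

#' Flatten a trial list to a data.frame
#'
#' @param trials trial list from \code{\link{tpeSearch}}.
#' @return data.frame, one row per trial: hyperparameters, jt_train,
#'   jt_val, F, index, seed, failed.
#' @export
trialsTable <- function(trials) {
    do.call(rbind, lapply(trials, function(t) {
        data.frame(c(t$hp,
                     list(jt_train = t$jt_train, jt_val = t$jt_val,
                          F = t$F, index = t$index, seed = t$seed,
                          failed = t$failed)),
                   stringsAsFactors = FALSE)
    }))
}

#' Write a trial log as a tab-separated file
#'
#' @param trials trial list or data.frame from \code{\link{trialsTable}}.
#' @param path output file.
#' @export
writeTrialLog <- function(trials, path) {
    if (!is.data.frame(trials)) trials <- trialsTable(trials)
    write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Hyperparameter effect analysis
#'
#' Design-of-experiments style screening: numeric hyperparameters are
#' min-max scaled, categorical ones one-hot encoded against a reference
#' level, predictors and response are standardised, and \code{F} is
#' regressed on them by least squares. The standardised coefficients
#' measure each setting's effect on the objective; 95\% confidence
#' intervals come from the classical least-squares standard errors.
#' Aliased (rank-deficient) columns are dropped with a warning.
#'
#' @param trials trial list or data.frame with hyperparameter columns and
#'   \code{F}.
#' @param space the search space the trials were drawn from (defines
#'   numeric bounds and categorical levels).
#' @return data.frame with \code{term}, \code{coefficient}, \code{lower},
#'   \code{upper}, ordered by absolute coefficient.
#' @export
effectAnalysis <- function(trials, space = tuningSpace()) {
    df <- if (is.data.frame(trials)) trials else trialsTable(trials)
    df <- df[is.finite(df$F), , drop = FALSE]
    n_hp <- length(space)
    if (nrow(df) < 2 * n_hp)
        stop("need at least twice as many trials as hyperparameters")
    cols <- list()
    for (nm in names(space)) {
        d <- space[[nm]]
        if (d$type == "categorical") {
            for (lv in d$values[-1])
                cols[[paste0(nm, "_", lv)]] <- as.numeric(df[[nm]] == lv)
        } else {
            v <- as.numeric(df[[nm]])
            if (isTRUE(d$log)) v <- log(v)
            lo <- if (isTRUE(d$log)) log(d$low) else d$low
            hi <- if (isTRUE(d$log)) log(d$high) else d$high
            cols[[nm]] <- (v - lo) / (hi - lo)
        }
    }
    x <- do.call(cbind, cols)
    keep <- apply(x, 2L, function(cc) sd(cc) > 0)
    x <- x[, keep, drop = FALSE]
    xs <- scale(x)
    ## drop aliased columns (perfect collinearity)
    qr_x <- qr(cbind(1, xs))
    if (qr_x$rank < ncol(xs) + 1L) {
        used <- qr_x$pivot[seq_len(qr_x$rank)]
        drop_idx <- setdiff(seq_len(ncol(xs) + 1L), used) - 1L
        warning("dropping aliased columns: ",
                paste(colnames(xs)[drop_idx], collapse = ", "))
        xs <- xs[, -drop_idx, drop = FALSE]
    }
    ys <- as.numeric(scale(df$F))
    if (all(!is.finite(ys))) ys <- rep(0, nrow(df))   # constant response
    fit <- stats::lm(ys ~ xs)
    est <- stats::coef(fit)[-1]
    ci <- stats::confint(fit, level = 0.95)[-1, , drop = FALSE]
    out <- data.frame(term = colnames(xs),
                      coefficient = unname(est),
                      lower = unname(ci[, 1]),
                      upper = unname(ci[, 2]),
                      stringsAsFactors = FALSE)
    out[order(abs(out$coefficient), decreasing = TRUE), , drop = FALSE]
}

#' Tune the multi-task network on prepared data
#'
#' Wires \code{\link{tpeSearch}} to the training pipeline: each trial
#' builds and trains a network with the sampled hyperparameters (a reduced
#' budget of one replicate and a capped epoch count keeps the search
#' tractable), estimates Bayes thresholds, and scores
#' \code{F = JT_val * (1 - |JT_train - JT_val|)}. Retrain the winning
#' configuration with the full 5-replicate protocol afterwards.
#'
#' @param x_train,y_train,x_val,y_val features and binary targets.
#' @param space search space; batch sizes above a quarter of the training
#'   set are clamped.
#' @param n_trials number of TPE trials.
#' @param base_seed RNG seed.
#' @param max_epochs per-trial epoch cap.
#' @return the \code{\link{tpeSearch}} result.
#' @export
tuneHyperparameters <- function(x_train, y_train, x_val, y_val,
                                space = NULL, n_trials = 100L,
                                base_seed = 1L, max_epochs = 60L) {
    if (is.null(space))
        space <- tuningSpace(max_batch = nrow(x_train) %/% 4L)
    eval_fun <- function(hp, seed) {
        hp$batch_size <- min(hp$batch_size, nrow(x_train) %/% 4L + 1L)
        hpo <- do.call(hyperparameters, hp)
        net <- buildNetwork(hpo, n_inputs = ncol(x_train),
                            n_tasks = ncol(y_train), seed = seed)
        net <- trainNetwork(net, x_train, y_train, x_val, y_val,
                            max_epochs = max_epochs)
        th <- bayesThresholds(predict(net, x_train), y_train)
        pt <- applyThresholds(predict(net, x_train), th)
        pv <- applyThresholds(predict(net, x_val), th)
        list(jt_train = mean(jtRows(y_train, pt)),
             jt_val = mean(jtRows(y_val, pv)))
    }
    tpeSearch(space, eval_fun, n_trials = n_trials, base_seed = base_seed)
}
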