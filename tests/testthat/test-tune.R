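test_that("the tuning objective penalises the train/validation gap", {
    expect_equal(objectiveF(0.48, 0.48), 0.48)
    expect_equal(objectiveF(0.6, 0.4), 0.32)
    expect_equal(objectiveF(0.9, 0), 0)
    expect_error(objectiveF(1.2, 0.5), "0, 1")
    ## F <= JT_val and F in [0, 1] over random inputs
    set.seed(23)
    for (i in 1:50) {
        a <- runif(1); b <- runif(1)
        f <- objectiveF(a, b)
        expect_lte(f, b + 1e-15)
        expect_gte(f, 0)
        expect_lte(f, 1)
    }
})

test_that("TPE search optimises a quadratic toy objective", {
    space <- list(x = list(type = "numeric", low = 0, high = 1))
    eval_fun <- function(hp, seed) 1 - (hp$x - 0.3)^2
    res <- tpeSearch(space, eval_fun, n_trials = 50, base_seed = 4)
    ## known optimum F = 1 at x = 0.3; best within 5%
    expect_gt(res$best$F, 0.95)
    expect_equal(length(res$trials), 50L)
    ## single trial degenerate case
    res1 <- tpeSearch(space, eval_fun, n_trials = 1, base_seed = 4)
    expect_equal(res1$best$index, 1L)
    ## determinism: same base seed twice, identical trial sequences
    resA <- tpeSearch(space, eval_fun, n_trials = 20, base_seed = 7)
    resB <- tpeSearch(space, eval_fun, n_trials = 20, base_seed = 7)
    expect_identical(trialsTable(resA$trials), trialsTable(resB$trials))
})

test_that("crashing trials are recorded as failed and the search continues", {
    space <- list(x = list(type = "numeric", low = 0, high = 1))
    eval_fun <- function(hp, seed) {
        if (hp$x > 0.8) stop("synthetic crash")
        hp$x
    }
    res <- tpeSearch(space, eval_fun, n_trials = 30, base_seed = 2)
    tab <- trialsTable(res$trials)
    expect_equal(nrow(tab), 30L)
    expect_true(any(tab$failed))
    expect_true(all(is.na(tab$F[tab$failed])))
    expect_lte(res$best$hp$x, 0.8)
})

test_that("search logs resume with continued numbering and serialize", {
    space <- list(x = list(type = "numeric", low = 0, high = 1))
    eval_fun <- function(hp, seed) hp$x
    first <- tpeSearch(space, eval_fun, n_trials = 12, base_seed = 3)
    resumed <- tpeSearch(space, eval_fun, n_trials = 5, base_seed = 3,
                         prior_trials = first$trials)
    expect_equal(length(resumed$trials), 17L)
    expect_equal(vapply(resumed$trials, `[[`, numeric(1), "index"),
                 as.numeric(1:17))
    f <- withr::local_tempfile()
    writeTrialLog(resumed$trials, f)
    expect_equal(nrow(read.delim(f)), 17L)
})

test_that("effect analysis recovers a planted dominant hyperparameter", {
    space <- tuningSpace()
    set.seed(24)
    n <- 200
    df <- data.frame(
        n_neurons = sample(50:100, n, TRUE),
        n_task_specific = sample(250:500, n, TRUE),
        learning_rate = exp(runif(n, log(1e-4), log(1e-2))),
        activation = sample(c("sigmoid", "relu"), n, TRUE),
        dropout = runif(n, 0, 0.5),
        batch_size = sample(2000:4000, n, TRUE),
        patience = sample(50:150, n, TRUE),
        optimizer = sample(c("adam", "sgd", "rmsprop"), n, TRUE),
        stringsAsFactors = FALSE)
    lr_scaled <- (log(df$learning_rate) - log(1e-4)) / (log(1e-2) - log(1e-4))
    df$F <- 0.5 * lr_scaled + rnorm(n, 0, 0.02)
    eff <- effectAnalysis(df, space)
    expect_equal(eff$term[1], "learning_rate")
    expect_gt(abs(eff$coefficient[1]), 3 * max(abs(eff$coefficient[-1])))
    ## constant response: all coefficients ~ 0 with CIs covering 0
    df0 <- df; df0$F <- 0.4
    eff0 <- effectAnalysis(df0, space)
    expect_true(all(abs(eff0$coefficient) < 1e-8))
    expect_true(all(eff0$lower <= 0 & eff0$upper >= 0))
    ## aliased (duplicated) columns are dropped with a warning
    space2 <- list(a = list(type = "numeric", low = 0, high = 1),
                   b = list(type = "numeric", low = 0, high = 1))
    df2 <- data.frame(a = runif(20))
    df2$b <- df2$a
    df2$F <- df2$a + rnorm(20, 0, 0.01)
    expect_warning(eff2 <- effectAnalysis(df2, space2), "aliased")
    expect_equal(nrow(eff2), 1L)
})

test_that("effects match simple-regression slopes on an orthogonal design", {
    space <- list(u = list(type = "numeric", low = 0, high = 1),
                  v = list(type = "numeric", low = 0, high = 1))
    ## 2^2 factorial replicated: exactly orthogonal columns
    base <- expand.grid(u = c(0, 1), v = c(0, 1))
    df <- base[rep(1:4, 5), ]
    set.seed(25)
    df$F <- 0.3 * df$u - 0.2 * df$v + rnorm(20, 0, 0.01)
    eff <- effectAnalysis(df, space)
    ys <- as.numeric(scale(df$F))
    for (term in c("u", "v")) {
        slope <- unname(coef(lm(ys ~ scale(df[[term]])))[2])
        expect_equal(eff$coefficient[eff$term == term], slope,
                     tolerance = 1e-8)
    }
})
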