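test_that("network construction follows the hyperparameters and seed", {
    hp <- hyperparameters(n_neurons = 100, n_task_specific = 250,
                          activation = "sigmoid", dropout = 0.30)
    net <- buildNetwork(hp, n_inputs = 20, n_tasks = 166, seed = 3)
    expect_equal(dim(net@weights$W1), c(20L, 100L))
    expect_equal(dim(net@weights$W2), c(100L, 250L))
    expect_equal(dim(net@weights$W3), c(250L, 166L))
    ## same seed, same initial weights
    net2 <- buildNetwork(hp, n_inputs = 20, n_tasks = 166, seed = 3)
    expect_identical(net@weights, net2@weights)
    expect_false(identical(
        net@weights,
        buildNetwork(hp, n_inputs = 20, n_tasks = 166, seed = 4)@weights))
    ## invalid settings are rejected
    expect_error(hyperparameters(dropout = 0.9), "dropout")
    expect_error(hyperparameters(learning_rate = -1))
    expect_error(hyperparameters(optimizer = "adagrad"))
})

test_that("training learns separable data, stops early and restores best", {
    set.seed(17)
    n <- 120; p <- 10; tasks <- 4
    x <- matrix(runif(n * p), n, p)
    y <- (x[, 1:tasks] > 0.5) * 1L     # bit copied from one input feature
    tr <- 1:80; va <- 81:120
    hp <- hyperparameters(n_neurons = 16, n_task_specific = 16,
                          learning_rate = 0.05, activation = "sigmoid",
                          dropout = 0, batch_size = 20, patience = 30,
                          optimizer = "adam")
    net <- buildNetwork(hp, p, tasks, seed = 5)
    net <- trainNetwork(net, x[tr, ], y[tr, ], x[va, ], y[va, ],
                        max_epochs = 400)
    h <- net@history
    expect_lt(nrow(h), 400)                     # stopped before the cap
    expect_lt(h$val_loss[which.min(h$val_loss)], h$val_loss[1])
    p_val <- predict(net, x[va, ])
    acc <- mean((p_val > 0.5) == (y[va, ] == 1))
    expect_gt(acc, 0.95)
    ## restored weights achieve the best recorded validation loss
    val_now <- -mean(y[va, ] * log(pmax(p_val, 1e-12)) +
                     (1 - y[va, ]) * log(pmax(1 - p_val, 1e-12)))
    expect_equal(val_now, min(h$val_loss), tolerance = 1e-10)
    ## probabilities stay inside (0, 1)
    expect_true(all(p_val > 0 & p_val < 1))
})

test_that("patience of one halts quickly on pure noise", {
    set.seed(18)
    x <- matrix(runif(200), 40, 5)
    y <- matrix(rbinom(80, 1, 0.5), 40, 2)
    hp <- hyperparameters(n_neurons = 4, n_task_specific = 4,
                          learning_rate = 0.01, dropout = 0,
                          batch_size = 10, patience = 1,
                          optimizer = "sgd", activation = "relu")
    net <- buildNetwork(hp, 5, 2, seed = 1)
    net <- trainNetwork(net, x[1:30, ], y[1:30, ], x[31:40, ], y[31:40, ],
                        max_epochs = 100)
    expect_lt(nrow(net@history), 15)
})

test_that("Bayes thresholds minimise FP + FN against an exhaustive sweep", {
    ## perfectly separated scores: the 0.2/0.8 midpoint, zero errors
    th <- bayesThresholds(matrix(c(0.1, 0.2, 0.8, 0.9), 4, 1),
                          matrix(c(0, 0, 1, 1), 4, 1))
    expect_equal(th, 0.5)
    ## single-class truth gets the neutral threshold
    expect_equal(bayesThresholds(matrix(runif(8), 8, 1),
                                 matrix(0, 8, 1)), 0.5)
    ## random instances: chosen threshold matches a 10,001-point grid sweep
    set.seed(19)
    for (i in 1:20) {
        s <- matrix(runif(50), 50, 1)
        y <- matrix(rbinom(50, 1, 0.4), 50, 1)
        th <- bayesThresholds(s, y)
        err <- sum(y == 0 & s >= th) + sum(y == 1 & s < th)
        grid <- seq(0, 1, length.out = 10001)
        err_grid <- vapply(grid, function(g)
            sum(y == 0 & s >= g) + sum(y == 1 & s < g), numeric(1))
        expect_equal(err, min(err_grid))
    }
})

test_that("majority voting equals the per-bit median across replicates", {
    fix <- tinyEnsemble()
    votes <- lapply(seq_along(fix$ensemble@replicates), function(r)
        applyThresholds(predict(fix$ensemble@replicates[[r]], fix$x),
                        fix$ensemble@thresholds[[r]]))
    stacked <- simplify2array(votes)
    med <- apply(stacked, c(1, 2), median)
    expect_equal(unname(predict(fix$ensemble, fix$x)), unname(med))
    ## an even replicate count cannot form a valid ensemble
    expect_error(new("FingerprintEnsemble",
                     replicates = fix$ensemble@replicates[1:4],
                     thresholds = fix$ensemble@thresholds[1:4],
                     seeds = 1:4),
                 "odd")
})

test_that("replicate stability is the mean per-bit standard deviation", {
    fix <- tinyEnsemble()
    votes <- lapply(seq_along(fix$ensemble@replicates), function(r)
        applyThresholds(predict(fix$ensemble@replicates[[r]], fix$x),
                        fix$ensemble@thresholds[[r]]))
    stacked <- simplify2array(votes)
    oracle <- mean(apply(stacked, 1, function(m) mean(apply(m, 1, sd))))
    expect_equal(replicateStability(fix$ensemble, fix$x), oracle,
                 tolerance = 1e-12)
    ## invariance to replicate order
    perm <- new("FingerprintEnsemble",
                replicates = fix$ensemble@replicates[c(3, 1, 5, 2, 4)],
                thresholds = fix$ensemble@thresholds[c(3, 1, 5, 2, 4)],
                seeds = fix$ensemble@seeds[c(3, 1, 5, 2, 4)])
    expect_equal(replicateStability(perm, fix$x),
                 replicateStability(fix$ensemble, fix$x))
    expect_equal(unname(predict(perm, fix$x)),
                 unname(predict(fix$ensemble, fix$x)))
})
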