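test_that("per-task confusion counts are exact", {
    truth <- matrix(c(1, 1, 0, 0), 4, 1)
    pred <- matrix(c(1, 0, 0, 1), 4, 1)
    cm <- confusionByTask(pred, truth)
    expect_equal(cm$TP, 1); expect_equal(cm$FN, 1)
    expect_equal(cm$TN, 1); expect_equal(cm$FP, 1)
    set.seed(26)
    t2 <- matrix(rbinom(60, 1, 0.4), 20, 3)
    cm2 <- confusionByTask(t2, t2)
    expect_true(all(cm2$FP == 0 & cm2$FN == 0))
    cm3 <- confusionByTask(1 - t2, t2)
    expect_true(all(cm3$TP == 0 & cm3$TN == 0))
    expect_true(all(rowSums(cm2[, c("TP", "TN", "FP", "FN")]) == 20))
    expect_error(confusionByTask(t2, t2[1:10, ]), "shapes")
})

test_that("NER averages sensitivity and specificity over defined tasks", {
    set.seed(27)
    truth <- matrix(rbinom(200, 1, 0.5), 50, 4)
    perfect <- nerScore(confusionByTask(truth, truth))
    expect_equal(perfect$ner, 1.0)
    ## Sn = 1, Sp = 0: predict everything positive
    allpos <- nerScore(confusionByTask(matrix(1, 50, 4), truth))
    expect_equal(allpos$per_task$NER, rep(0.5, 4))
    ## complement symmetry: NER(pred) + NER(1 - pred) == 1 per task
    pred <- matrix(rbinom(200, 1, 0.5), 50, 4)
    a <- nerScore(confusionByTask(pred, truth))$per_task$NER
    b <- nerScore(confusionByTask(1 - pred, truth))$per_task$NER
    expect_equal(a + b, rep(1, 4))
    ## single-class tasks are excluded and reported
    truth1 <- cbind(truth, 0)
    r <- nerScore(confusionByTask(cbind(pred, 1), truth1))
    expect_equal(r$excluded, 5)
    expect_equal(r$ner, mean(r$per_task$NER[1:4]))
    ## NER is invariant to task order
    perm <- sample(4)
    expect_equal(nerScore(confusionByTask(pred[, perm], truth[, perm]))$ner,
                 nerScore(confusionByTask(pred, truth))$ner)
    expect_error(nerScore(confusionByTask(matrix(1, 3, 1),
                                          matrix(1, 3, 1))), "undefined")
})

test_that("candidate ranking is similarity-ordered with deterministic ties", {
    set.seed(28)
    lib <- matrix(rbinom(20 * 166, 1, 0.23), 20, 166,
                  dimnames = list(sprintf("cpd%02d", 1:20), NULL))
    query <- lib[7, ]
    rk <- rankCandidates(query, lib, true_id = "cpd07")
    expect_equal(rk$candidate_id[1], "cpd07")
    expect_equal(rk$jt[1], 1.0)
    expect_equal(attr(rk, "true_rank"), 1L)
    ## all-zero candidates against a nonzero query: ties broken by id
    zlib <- matrix(0L, 5, 166,
                   dimnames = list(c("e", "c", "a", "d", "b"), NULL))
    rz <- rankCandidates(query, zlib)
    expect_true(all(rz$jt == 0))
    expect_equal(rz$candidate_id, sort(rownames(zlib)))
    expect_error(rankCandidates(query, zlib[0, , drop = FALSE]), "empty")
})

test_that("noisy predicted fingerprints rank the true compound above chance", {
    set.seed(29)
    lib <- matrix(rbinom(100 * 166, 1, 0.23), 100, 166,
                  dimnames = list(sprintf("cpd%03d", 1:100), NULL))
    ranks <- vapply(1:40, function(i) {
        noisy <- lib[i, ]
        flip <- sample(166, 12)             # imperfect prediction
        noisy[flip] <- 1 - noisy[flip]
        attr(rankCandidates(noisy, lib, true_id = rownames(lib)[i]),
             "true_rank")
    }, integer(1))
    random_ranks <- vapply(1:40, function(i) {
        rnd <- sample(lib[i, ])             # same bit count, random order
        attr(rankCandidates(rnd, lib, true_id = rownames(lib)[i]),
             "true_rank")
    }, integer(1))
    expect_lt(median(ranks), median(random_ranks))
    expect_lte(median(ranks), 2)
})

test_that("classical MDS reproduces embeddable geometries", {
    ## planted 2-D coordinates: embedding must reproduce all pairwise
    ## distances exactly
    set.seed(30)
    pts <- matrix(rnorm(20), 10, 2)
    d <- as.matrix(dist(pts))
    emb <- mdsEmbed(d, n_dims = 2)
    expect_equal(as.matrix(dist(emb)), d, tolerance = 1e-6,
                 ignore_attr = TRUE)
    ## three pairwise-equidistant fingerprints -> equilateral triangle
    fps <- rbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0),
                 c(0, 0, 0, 0, 1, 1))
    emb3 <- mdsEmbed(fps, n_dims = 2)
    dd <- dist(emb3)
    expect_lt(max(dd) - min(dd), 1e-6)
    ## duplicated fingerprints give coincident points
    fps4 <- rbind(fps, fps[1, ])
    emb4 <- mdsEmbed(fps4, n_dims = 2)
    expect_equal(emb4[4, ], emb4[1, ], tolerance = 1e-9)
    ## deterministic orientation
    expect_identical(mdsEmbed(fps, 2), mdsEmbed(fps, 2))
})

test_that("MDS stress never increases with added dimensions", {
    set.seed(32)
    fps <- matrix(rbinom(12 * 30, 1, 0.4), 12, 30)
    d <- as.matrix(stats::as.dist(1 - jtMatrix(fps)))
    stress <- vapply(1:4, function(k) {
        emb <- suppressWarnings(mdsEmbed(fps, n_dims = k))
        sum((as.matrix(dist(emb)) - d)^2)
    }, numeric(1))
    expect_true(all(diff(stress) <= 1e-9))
})

test_that("active-bit analysis separates accuracy groups", {
    fps <- rbind(low = rep(c(1L, 0L), c(17, 149)),   # ~10% active
                 high = rep(c(1L, 0L), c(50, 116))) # ~30% active
    fps["low", ] <- c(rep(1L, 17), rep(0L, 149))
    cj <- c(low = 0.1, high = 0.9)
    res <- activeBitAnalysis(cj, fps)
    expect_true(res$low$defined && res$high$defined)
    expect_equal(res$low$median, 100 * 17 / 166, tolerance = 1e-6)
    expect_equal(res$high$median, 100 * 50 / 166, tolerance = 1e-6)
    ## empty group flagged
    res2 <- activeBitAnalysis(c(a = 0.9, b = 0.8),
                              matrix(1, 2, 10,
                                     dimnames = list(c("a", "b"), NULL)))
    expect_false(res2$low$defined)
    ## planted effect: compounds with more active bits predicted better
    set.seed(33)
    n <- 60
    frac <- runif(n, 0.05, 0.45)
    fps3 <- t(vapply(frac, function(p) rbinom(166, 1, p), integer(166)))
    rownames(fps3) <- sprintf("c%02d", 1:n)
    jt3 <- pmin(pmax(frac * 2 + rnorm(n, 0, 0.05), 0), 1)
    names(jt3) <- rownames(fps3)
    res3 <- activeBitAnalysis(jt3, fps3)
    expect_gt(res3$high$median, res3$low$median)
})
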