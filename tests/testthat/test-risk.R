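test_that("PCA handles rank-1 data and reconstructs its input", {
    set.seed(1)
    z <- rnorm(50)
    X <- cbind(a = z, b = 2 * z)          # perfectly correlated pair
    p <- pcaFit(scale(X))
    expect_equal(p$explained[1], 1, tolerance = 1e-10)
    # orthogonal reconstruction
    set.seed(2)
    Y <- matrix(rnorm(200), 40, 5)
    q <- pcaFit(Y)
    rec <- q$scores %*% t(q$rotation)
    rec <- sweep(rec, 2L, -q$center)
    expect_lt(max(abs(rec - Y)), 1e-8)
    # sign convention: largest-magnitude loading positive
    for (j in seq_len(ncol(q$rotation)))
        expect_gt(q$rotation[which.max(abs(q$rotation[, j])), j], 0)
    expect_error(pcaFit(Y[1, , drop = FALSE]), "2 samples")
})

test_that("identity-covariance data spreads explained variance evenly", {
    set.seed(3)
    Y <- matrix(rnorm(4000 * 4), 4000, 4)
    p <- pcaFit(Y)
    expect_true(all(abs(p$explained - 0.25) < 0.05))
})

test_that("forest screening selects a driver PC and is never empty", {
    set.seed(4)
    n <- 250
    driver <- rnorm(n)
    y <- rbinom(n, 1, plogis(2.5 * driver))
    pcs <- cbind(driver, matrix(rnorm(n * 9), n, 9))
    for (s in 1:3) {
        sel <- rfScreenPcs(pcs, y, nTrees = 500, seed = s)
        expect_true(1L %in% sel$selected)
        expect_gt(sel$contribution[1], 0.05)
    }
    # 2 PCs: contributions sum to 1, pigeonhole keeps at least one
    sel2 <- rfScreenPcs(pcs[, 1:2], y, nTrees = 300, seed = 1)
    expect_equal(sum(sel2$contribution), 1, tolerance = 1e-12)
    expect_gte(length(sel2$selected), 1L)
    expect_error(rfScreenPcs(pcs, rep(1, n)), "both classes")
})

test_that("PCA/RF iteration converges and is replayable", {
    set.seed(5)
    n <- 200
    z <- rnorm(n)
    X <- sapply(1:8, function(i) z + rnorm(n))
    X <- scale(X)
    y <- rbinom(n, 1, plogis(2 * z))
    it <- iteratePcaRf(X, y, nTrees = 300, seed = 9)
    expect_true(it$converged)
    expect_lte(it$rounds, 10L)
    # recorded stack replays to the same final representation
    rep_ <- progsig:::.replayPcaStack(X, it$stack)
    expect_lt(max(abs(rep_ - it$finalScores)), 1e-10)
    # iteration cap triggers a warning when convergence is impossible
    expect_warning(iteratePcaRf(X, y, maxRounds = 1L, nTrees = 100,
                                cutoff = 0.2, seed = 1),
                   "did not converge")
})

test_that("boosted net separates separable data and resists null data", {
    set.seed(6)
    n <- 200
    x1 <- c(runif(n / 2, -3, -1), runif(n / 2, 1, 3))   # margin of 2
    y <- rep(c(0L, 1L), each = n / 2)
    P <- cbind(x1, rnorm(n))
    fit <- fitBoostedNet(P, y, stages = 100, seed = 3)
    pr <- progsig:::.predictBoosted(fit$intercept, fit$ensemble, P)
    expect_equal(rocAuc(pr, y)$auc, 1.0)
    # null labels: out-of-fold AUC stays near chance (overfitting guard)
    for (s in 1:3) {
        set.seed(100 + s)
        Pn <- matrix(rnorm(300 * 4), 300, 4)
        yn <- rbinom(300, 1, 0.5)
        fn <- fitBoostedNet(Pn, yn, stages = 40, seed = s)
        expect_gte(fn$aucOof, 0.35)
        expect_lte(fn$aucOof, 0.65)
    }
})

test_that("boosting never increases the training log-loss across stages", {
    set.seed(7)
    n <- 150
    z <- rnorm(n)
    P <- cbind(z + rnorm(n, 0, 0.5), rnorm(n))
    y <- rbinom(n, 1, plogis(1.5 * z))
    fit <- withr::with_seed(8, progsig:::.trainBoostedEnsemble(
        P, y, stages = 60, hidden = 3, lr = 0.1))
    Fcur <- rep(fit$intercept, n)
    losses <- numeric(60)
    for (m in seq_along(fit$ensemble)) {
        net <- fit$ensemble[[m]]
        if (net$step != 0)
            Fcur <- Fcur + net$step * progsig:::.tanhNetPredict(net, P)
        losses[m] <- progsig:::.logloss(y, Fcur)
    }
    expect_true(all(diff(losses) <= 1e-6))
})

test_that("risk scores obey the probability-score-group contracts", {
    sc <- smallCohort()
    x <- sc@experiment
    model <- trainRiskModel(x, sc@plantedGenes, seed = 5, stages = 30)
    s <- scoreSamples(model, x)
    expect_true(all(s$score >= -50 & s$score <= 50))
    expect_equal(s$score, 100 * (s$probability - 0.5))
    expect_identical(s$group, ifelse(s$score > 0, "high", "low"))
    # strictly monotone mapping; boundary p = 0.5 -> score 0 -> low risk
    expect_identical(ifelse(100 * (0.5 - 0.5) > 0, "high", "low"), "low")
    # deterministic replay under the same seed
    model2 <- trainRiskModel(x, sc@plantedGenes, seed = 5, stages = 30)
    expect_equal(scoreSamples(model2, x)$score, s$score, tolerance = 1e-12)
})

test_that("model serialization replays scores to 1e-10", {
    sc <- smallCohort()
    x <- sc@experiment
    model <- trainRiskModel(x, sc@plantedGenes, seed = 5, stages = 30)
    s1 <- scoreSamples(model, x)
    f <- withr::local_tempfile(fileext = ".json")
    writeRiskModel(model, f)
    model2 <- readRiskModel(f)
    s2 <- scoreSamples(model2, x)
    expect_lt(max(abs(s1$score - s2$score)), 1e-10)
    expect_equal(model2@trainingAucOof, model@trainingAucOof,
                 tolerance = 1e-12)
})

test_that("missing signature genes: <= 20% imputed at z = 0, more errors", {
    sc <- smallCohort()
    x <- sc@experiment
    model <- trainRiskModel(x, sc@plantedGenes, seed = 5, stages = 20)
    drop1 <- setdiff(rownames(x), sc@plantedGenes[1])
    expect_warning(s <- scoreSamples(model, x[drop1, ]), "imputed")
    expect_identical(nrow(s), ncol(x))
    drop3 <- setdiff(rownames(x), sc@plantedGenes[1:3])
    expect_error(suppressWarnings(scoreSamples(model, x[drop3, ])),
                 "20%")
})
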