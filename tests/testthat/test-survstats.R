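test_that("KM estimator equals the brute-force product limit", {
    set.seed(1)
    for (i in 1:20) {
        n <- sample(10:80, 1)
        t <- round(rexp(n, 0.2), 2)
        e <- rbinom(n, 1, 0.7)
        if (sum(e) == 0) e[1] <- 1L
        km <- kmFit(t, e)
        bf <- kmBrute(t, e)
        at <- km$times %in% bf$times & km$events > 0
        expect_equal(km$survival[at], bf$surv, tolerance = 1e-12)
    }
})

test_that("KM median conventions match the reporting contract", {
    # all events at t = 5: survival drops 1 -> 0 there, median 5
    km <- kmFit(rep(5, 10), rep(1, 10))
    expect_equal(kmMedian(km), 5)
    expect_equal(km$survival[km$times == 5], 0)
    # heavy censoring: curve never reaches 0.5 -> "> max" style
    km2 <- kmFit(c(1, 2, 3, 100), c(1, 0, 0, 0))
    expect_true(is.na(kmMedian(km2)))
    expect_match(formatKmMedian(km2), "^> 100")
    expect_error(kmFit(numeric(0), integer(0)), "empty")
})

test_that("log-rank test: identical groups give chi2 = 0", {
    t <- c(1, 3, 5, 7, 9)
    e <- c(1, 1, 0, 1, 0)
    lr <- logrankTest(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
    expect_equal(lr$chi2, 0, tolerance = 1e-12)
    expect_equal(lr$p, 1, tolerance = 1e-10)
    expect_error(logrankTest(t, rep(0, 5), c(1, 1, 2, 2, 2)), "event")
})

test_that("log-rank single-event case matches the hypergeometric step", {
    # one event (group a, t=1), N=6 at risk, 3 per group:
    # E = 1/2, V = 3*3/6^2 = 1/4, chi2 = (1 - 1/2)^2 / (1/4) = 1
    t <- c(1, 5, 6, 2, 3, 4)
    e <- c(1, 0, 0, 0, 0, 0)
    g <- rep(c("a", "b"), each = 3)
    lr <- logrankTest(t, e, g)
    expect_equal(lr$chi2, 1, tolerance = 1e-10)
})

test_that("log-rank is well powered at HR = 3", {
    hits <- vapply(1:40, function(s) {
        d <- simulateTwoGroupSurvival(200, 3, 0.1, 0, seed = 5000 + s)
        logrankTest(d$dfs_months, d$dfs_event, d$group)$p < 0.01
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("Cox fit recovers a simulated hazard ratio", {
    d <- simulateTwoGroupSurvival(1000, 2, 0.1, 0, seed = 77)
    cx <- coxFit(d$dfs_months, d$dfs_event, d["group"])
    expect_gte(cx$table$hr, 1.8)
    expect_lte(cx$table$hr, 2.2)
    expect_true(cx$table$lo95 < cx$table$hr & cx$table$hr < cx$table$hi95)
    expect_identical(cx$ties, "efron")
})

test_that("Cox p-values are uniform under permuted covariates", {
    d <- simulateTwoGroupSurvival(50, 2, 0.1, 0, seed = 42)
    ps <- vapply(1:100, function(s) {
        set.seed(s)
        g <- sample(d$group)
        coxFit(d$dfs_months, d$dfs_event, data.frame(group = g))$table$p
    }, numeric(1))
    expect_lt(abs(mean(ps) - 0.5), 0.08)
})

test_that("Cox errors name degenerate covariates", {
    d <- simulateTwoGroupSurvival(50, 2, 0.1, 0, seed = 1)
    expect_error(coxFit(d$dfs_months, d$dfs_event,
                        data.frame(flat = rep(1, 100))), "flat")
    # monotone likelihood: covariate perfectly ordered with event times
    t <- 1:40
    e <- rep(1L, 40)
    mono <- data.frame(mono = as.numeric(t <= 20))
    expect_error(coxFit(t, e, mono), "mono")
})

test_that("Cox without ties agrees across Breslow and Efron", {
    d <- simulateTwoGroupSurvival(100, 2, 0.1, 0, seed = 3)
    a <- coxFit(d$dfs_months, d$dfs_event, d["group"], ties = "efron")
    b <- coxFit(d$dfs_months, d$dfs_event, d["group"], ties = "breslow")
    expect_equal(a$table$coef, b$table$coef, tolerance = 1e-8)
})

test_that("Fisher exact and Welch t obey their small-sample contracts", {
    # balanced table is exactly null
    expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
    # one-sided extreme table: 1 / choose(20, 10)
    p1 <- fisherExact2x2(matrix(c(10, 0, 0, 10), 2), "greater")$p
    expect_equal(p1, 1 / choose(20, 10), tolerance = 1e-12)
    expect_warning(z <- fisherExact2x2(matrix(c(0, 0, 3, 4), 2)),
                   "zero margin")
    expect_equal(z$p, 1)
    expect_error(fisherExact2x2(matrix(c(1.5, 1, 1, 1), 2)), "integers")
    # identical degenerate samples: t = 0, two-tailed p = 1
    w <- welchT(c(2, 2, 2), c(2, 2, 2))
    expect_equal(w$t, 0)
    expect_equal(w$p, 1)
    w2 <- welchT(c(5, 6, 7, 8), c(1, 2, 2, 3), alternative = "greater")
    expect_lt(w2$p, 0.01)
    expect_error(welchT(1, c(1, 2)), "at least 2")
})
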