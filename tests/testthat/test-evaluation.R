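test_that("AUC equals the trapezoid under the ROC curve, with ties", {
    trapezoid <- function(rc) {
        x <- rc$fpr; y <- rc$sensitivity
        sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    }
    set.seed(1)
    for (i in 1:25) {
        n <- sample(20:150, 1)
        y <- c(0, 1, rbinom(n - 2, 1, 0.4))
        s <- sample(round(rnorm(n), sample(0:2, 1)))  # induces ties
        rc <- rocAuc(s, y)
        expect_equal(rc$auc, trapezoid(rc), tolerance = 1e-10)
        expect_equal(rc$auc, aucRank(s, y), tolerance = 1e-12)
    }
    # all scores tied: AUC is exactly 1/2
    expect_equal(rocAuc(rep(1, 20), rep(c(0, 1), 10))$auc, 0.5)
    # perfect separation
    expect_equal(rocAuc(1:10, rep(c(0, 1), each = 5))$auc, 1.0)
    expect_error(rocAuc(1:5, rep(1, 5)), "both classes")
})

test_that("null scores give AUC near one half", {
    set.seed(2)
    y <- rbinom(500, 1, 0.5)
    s <- rnorm(500)
    a <- rocAuc(s, y)$auc
    expect_gt(a, 0.43)
    expect_lt(a, 0.57)
})

test_that("DeLong comparison: identity, symmetry, and power", {
    set.seed(3)
    n <- 300
    z <- rnorm(n)
    y <- rbinom(n, 1, plogis(2 * z))
    strong <- z + rnorm(n, 0, 0.3)
    noise <- rnorm(n)
    idem <- compareRocs(strong, strong, y)
    expect_equal(idem$z, 0)
    expect_equal(idem$p, 1)
    cmp <- compareRocs(strong, noise, y)
    expect_lt(cmp$p, 0.001)
    rev_ <- compareRocs(noise, strong, y)
    expect_equal(cmp$p, rev_$p, tolerance = 1e-10)
    expect_equal(cmp$z, -rev_$z, tolerance = 1e-10)
})

test_that("baseline biomarkers: planted driver informative, noise not", {
    sc <- smallCohort()
    x <- sc@experiment
    y <- clinicalData(x)$progressed
    noiseGenes <- setdiff(rownames(x), sc@plantedGenes)[1:5]
    bl <- baselineBiomarkerScores(x, c(sc@plantedGenes[1], noiseGenes[1]),
                                  y, seed = 4)
    aucDriver <- rocAuc(bl$single[[sc@plantedGenes[1]]], y)$auc
    aucNoise <- rocAuc(bl$single[[noiseGenes[1]]], y)$auc
    expect_gt(aucDriver, 0.6)
    expect_gt(aucDriver, aucNoise - 0.05)
    # combined model on pure-noise genes stays near chance out of fold
    bn <- baselineBiomarkerScores(x, noiseGenes, y, seed = 5)
    aucNull <- rocAuc(bn$combined, y)$auc
    expect_gt(aucNull, 0.35)
    expect_lt(aucNull, 0.65)
    expect_warning(baselineBiomarkerScores(x, c("NOPE", noiseGenes[1]), y),
                   "NOPE")
})

test_that("risk-group report computes the full battery on synthetic data", {
    strong <- strongRun()
    rep_ <- strong$run$report
    # high-risk group is enriched for progression
    conf <- rep_$confusion
    expect_lt(rep_$fisherP, 0.01)
    expect_gt(conf["high", "1"] / sum(conf["high", ]),
              conf["low", "1"] / sum(conf["low", ]))
    # survival contrast present with both groups
    expect_named(rep_$km$medians, c("low", "high"))
    expect_true(rep_$km$logrank$p < 0.05)
    # hypoxia contrast: higher risk, higher hypoxia by construction
    expect_lt(rep_$hypoxia$p, 0.05)
    expect_gt(rep_$hypoxia$t, 0)
    # pure function: identical inputs give identical reports
    again <- riskGroupReport(strong$run$scores,
                             clinicalData(strong$cohort@experiment))
    expect_equal(again$fisherP, rep_$fisherP)
    expect_equal(again$km$medians, rep_$km$medians)
})

test_that("report flags contrasts it cannot compute", {
    clin <- data.frame(sample_id = paste0("s", 1:8),
                       progressed = c(1, 1, 1, 1, 0, 0, 0, 0),
                       dfs_months = c(2, 3, 4, 5, 10, 12, 14, 16),
                       dfs_event = rep(1L, 8))
    scores <- data.frame(sample_id = paste0("s", 1:8),
                         probability = rep(0.9, 8),
                         score = rep(40, 8),
                         group = rep("high", 8))   # one risk group empty
    rep_ <- riskGroupReport(scores, clin)
    expect_true(any(grepl("empty|unavailable|fewer",
                          rep_$skipped)))
    expect_null(rep_$fisherP)
})
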