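mkScreen <- function(...) {
    ShrnaScreen(data.frame(...))
}

test_that("gene mean FC is the two-stage average", {
    s <- mkScreen(shrna_id = c("a", "b", "c"), gene = "G1",
                  cell_line = "L1", log2_fc = c(-1, -0.5, 0.3))
    expect_equal(geneMeanFC(s, "G1"), -0.4)
    # cell-line means first, then across cell lines
    s2 <- mkScreen(shrna_id = c("a", "b", "a", "b"), gene = "G1",
                   cell_line = c("L1", "L1", "L2", "L2"),
                   log2_fc = c(-1.5, -0.5, 0, 0))
    expect_equal(geneMeanFC(s2, "G1"), -0.5)
    # absent gene is excluded (NA), never treated as 0
    expect_true(is.na(geneMeanFC(s, "G2")))
})

test_that("per-shRNA depletion test matches the t distribution", {
    p <- shrnaDepletionTest(c(-2, -1, -3))
    tstat <- mean(c(-2, -1, -3)) / (sd(c(-2, -1, -3)) / sqrt(3))
    expect_equal(tstat, -3.4641, tolerance = 1e-4)
    expect_equal(p, stats::pt(tstat, 2))
    expect_equal(p, 0.0371, tolerance = 1e-3)
    expect_gt(shrnaDepletionTest(c(1, 2, 3)), 0.95)
    expect_warning(expect_true(is.na(shrnaDepletionTest(c(0, 0, 0)))),
                   "skipped")
    expect_warning(expect_true(is.na(shrnaDepletionTest(-1))), "skipped")
})

test_that("Fisher combination matches the chi-square closed form", {
    fc <- fisherCombine(c(0.5, 0.5))
    expect_equal(fc$chi2, -2 * 2 * log(0.5))
    expect_equal(fc$df, 4L)
    # df = 4 closed form: exp(-x/2) * (1 + x/2)
    expect_equal(fc$p, exp(-fc$chi2 / 2) * (1 + fc$chi2 / 2),
                 tolerance = 1e-12)
    expect_equal(fc$p, 0.5966, tolerance = 1e-4)
    # k = 1 identity
    expect_equal(fisherCombine(0.123)$p, 0.123, tolerance = 1e-12)
    # boundary
    b <- fisherCombine(c(1, 1, 1))
    expect_equal(b$chi2, 0)
    expect_equal(b$p, 1)
    expect_warning(fisherCombine(c(0, 0.5)), "clamped")
})

test_that("Fisher combination is monotone in each input p-value", {
    set.seed(11)
    for (i in 1:50) {
        p <- runif(sample(2:6, 1))
        j <- sample(length(p), 1)
        p2 <- p
        p2[j] <- p[j] * runif(1)
        expect_lte(fisherCombine(p2)$p, fisherCombine(p)$p + 1e-12)
    }
})

test_that("BH adjustment matches the independent step-up oracle", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(0.3), 0.3)
    expect_equal(bhFdr(rep(0.5, 7)), rep(0.5, 7))
    set.seed(12)
    for (i in 1:200) {
        p <- runif(sample(1:40, 1))^sample(1:3, 1)
        expect_equal(bhFdr(p), bhOracle(p), tolerance = 1e-12)
    }
})

test_that("survival-gene calling implements the mean-FC rule", {
    sc <- smallCohort()
    ess <- callSurvivalGenes(sc@screen, rownames(sc@experiment))
    expect_true(all(ess$mean_fc[ess$is_survival_gene] < 0))
    expect_identical(ess$fisher_df, 2L * ess$n_shrnas)
    # planted genes recalled, FDR confirms
    planted <- ess[ess$gene %in% sc@plantedGenes, ]
    expect_true(all(planted$is_survival_gene))
    expect_true(all(planted$fdr_q < 0.05))
    # strict mode additionally requires the q cutoff
    strict <- callSurvivalGenes(sc@screen, rownames(sc@experiment),
                                strictFdr = 0.05)
    expect_true(all(strict$fdr_q[strict$is_survival_gene] < 0.05))
    expect_error(callSurvivalGenes(sc@screen, character(0)), "empty")
})

test_that("an all-positive screen yields no survival genes", {
    s <- ShrnaScreen(data.frame(
        shrna_id = rep(paste0("sh", 1:6), each = 4),
        gene = rep(paste0("G", 1:3), each = 8),
        cell_line = rep(paste0("L", 1:4), times = 6),
        log2_fc = abs(rnorm(24)) + 0.1))
    ess <- callSurvivalGenes(s, paste0("G", 1:3))
    expect_false(any(ess$is_survival_gene))
    # a candidate absent from the screen is excluded, flagged unmeasured
    ess2 <- callSurvivalGenes(s, c("G1", "G9"))
    expect_false(ess2$measured[ess2$gene == "G9"])
    expect_false(ess2$is_survival_gene[ess2$gene == "G9"])
})

test_that("FDR is controlled under the global null screen", {
    sc <- simulateCohort(simulationConfig(nSamples = 10, nGenes = 400,
                                          nPlanted = 0, nCellLines = 10,
                                          seed = 55))
    ess <- callSurvivalGenes(sc@screen, rownames(sc@experiment))
    alpha <- 0.05
    frac <- mean(ess$fdr_q < alpha, na.rm = TRUE)
    expect_lte(frac, alpha + 3 * sqrt(alpha / nrow(ess)))
})
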