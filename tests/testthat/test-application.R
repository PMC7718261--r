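test_that("validation outcome recoding follows the relapse/death rules", {
    clin <- data.frame(sample_id = c("a", "b", "c", "d"),
                       dfs_event = c(1, 0, NA, 1),
                       os_event = c(1, 1, 0, NA))
    rel <- recodeValidationOutcomes(clin, "relapse")
    expect_identical(unname(rel[c("a", "b")]), c(1L, 0L))
    expect_identical(attr(rel, "excluded"), 1L)
    expect_false("c" %in% names(rel))
    dth <- recodeValidationOutcomes(clin, "death")
    expect_identical(unname(dth[c("b", "c")]), c(1L, 0L))
    expect_identical(attr(dth, "excluded"), 1L)
    expect_error(recodeValidationOutcomes(clin[, 1:2], "death"), "os_event")
})

test_that("stratified split reproduces the 396/132 cohort partition", {
    set.seed(10)
    clin <- data.frame(sample_id = sprintf("P%03d", 1:528),
                       age = rnorm(528, 60, 12),
                       gender = sample(c("male", "female"), 528, TRUE))
    sp <- stratifiedSplit(clin, 0.75, seed = 3)
    expect_length(sp$train, 396L)
    expect_length(sp$validation, 132L)
    expect_length(intersect(sp$train, sp$validation), 0L)
    expect_setequal(c(sp$train, sp$validation), clin$sample_id)
    expect_identical(sp, stratifiedSplit(clin, 0.75, seed = 3))
    expect_false(identical(sp, stratifiedSplit(clin, 0.75, seed = 4)))
})

test_that("splits are balanced within strata", {
    set.seed(11)
    clin <- data.frame(sample_id = sprintf("P%03d", 1:400),
                       age = rnorm(400, 65, 10),
                       gender = sample(c("male", "female"), 400, TRUE))
    pvals <- vapply(1:25, function(s) {
        sp <- stratifiedSplit(clin, 0.5, seed = s)
        inTrain <- clin$sample_id %in% sp$train
        ageBin <- cut(clin$age,
                      c(-Inf, quantile(clin$age, c(0.25, 0.5, 0.75)), Inf))
        stratum <- interaction(ageBin, clin$gender)
        suppressWarnings(stats::chisq.test(table(stratum, inTrain))$p.value)
    }, numeric(1))
    expect_gte(min(pvals), 0.01)
    # balanced strata at fraction 0.5 split into exact halves
    clin2 <- data.frame(sample_id = sprintf("Q%02d", 1:40),
                        gender = rep(c("m", "f"), each = 20))
    sp2 <- stratifiedSplit(clin2, 0.5, strata = "gender", seed = 1)
    expect_length(sp2$train, 20L)
})

test_that("singleton strata go to training with a warning", {
    clin <- data.frame(sample_id = c("a", "b", "c", "d", "e"),
                       gender = c("m", "m", "m", "m", "x"))
    expect_warning(sp <- stratifiedSplit(clin, 0.75, strata = "gender",
                                         seed = 1), "size 1")
    expect_true("e" %in% sp$train)
})

test_that("qPCR delta-Ct panel scores like the expression path", {
    sc <- smallCohort()
    x <- sc@experiment
    model <- trainRiskModel(x, sc@plantedGenes, seed = 5, stages = 30)
    genes <- signatureGenes(model@signature)
    idx <- 1:20
    lx <- log2(exprValues(x)[genes, idx, drop = FALSE] + 1)
    panel <- data.frame(sample_id = colnames(lx), GAPDH = 25,
                        t(30 - lx), check.names = FALSE)
    q <- qpcrToExpression(panel)
    expect_identical(exprScale(q), "zscore")
    sq <- scoreSamples(model, q)
    se <- scoreSamples(model, zscoreByGene(x[genes, idx]))
    expect_gte(stats::cor(sq$score, se$score, method = "spearman"), 0.9)
})

test_that("qPCR edge cases: missing reference, constant delta-Ct", {
    panel <- data.frame(sample_id = c("a", "b", "c"),
                        GAPDH = c(25, NA, 25),
                        G1 = c(25, 24, 25),   # equals reference: dCt = 0
                        G2 = c(20, 21, 19))
    expect_warning(expect_warning(q <- qpcrToExpression(panel),
                                  "missing reference"), "constant")
    expect_identical(ncol(q), 2L)
    expect_true("G1" %in% S4Vectors::metadata(q)$constantGenes)
    expect_error(qpcrToExpression(panel[, -2]), "GAPDH")
})

test_that("pipeline runs are deterministic and abort with a stage name", {
    sc <- smallCohort(seed = 77)
    x <- sc@experiment
    r1 <- runPipeline(x, sc@screen, percentile = 97, seed = 7, stages = 25)
    r2 <- runPipeline(x, sc@screen, percentile = 97, seed = 7, stages = 25)
    expect_equal(r1$scores, r2$scores)
    expect_identical(signatureGenes(r1$signature),
                     signatureGenes(r2$signature))
    expect_identical(r1$manifest$seed, 7)
    # screen where nothing depletes: essentiality stage aborts, named
    rec <- screenRecords(sc@screen)
    rec$log2_fc <- abs(rec$log2_fc) + 0.5
    expect_error(runPipeline(x, ShrnaScreen(rec), percentile = 97, seed = 1),
                 "essentiality_screen")
})
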