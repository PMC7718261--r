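# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# small cohort for fast unit tests
smallCohort <- function(seed = 42L) {
    key <- paste0("small", seed)
    if (is.null(.fixtures[[key]]))
        .fixtures[[key]] <- simulateCohort(simulationConfig(
            nSamples = 120L, nGenes = 300L, nPlanted = 8L,
            nCellLines = 6L, seed = seed))
    .fixtures[[key]]
}

# full-scale strong-signal cohort + pipeline run (study conditions:
# n = 400 samples, 2000 genes, 20 planted, beta = 1.5)
strongRun <- function() {
    if (is.null(.fixtures$strong)) {
        sc <- simulateCohort(simulationConfig(seed = 101L))
        run <- runPipeline(sc@experiment, sc@screen, seed = 101L,
                           label = "strong")
        .fixtures$strong <- list(cohort = sc, run = run)
    }
    .fixtures$strong
}

# matched null cohort (no planted genes, no progression effect)
nullRun <- function() {
    if (is.null(.fixtures$null)) {
        sc <- simulateCohort(simulationConfig(nPlanted = 0L,
                                              progressionEffect = 0,
                                              seed = 202L))
        run <- runPipeline(sc@experiment, sc@screen, seed = 202L,
                           label = "null")
        .fixtures$null <- list(cohort = sc, run = run)
    }
    .fixtures$null
}

# rank-based Mann-Whitney AUC, independent of the package's rocAuc
aucRank <- function(scores, y) {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    r <- rank(scores)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# independent Benjamini-Hochberg step-up oracle
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
        prev <- min(prev, m * p[o[i]] / i)
        q[o[i]] <- prev
    }
    q
}

# brute-force product-limit estimator at event times
kmBrute <- function(t, e) {
    ut <- sort(unique(t[e == 1]))
    s <- 1
    surv <- numeric(length(ut))
    for (i in seq_along(ut)) {
        n <- sum(t >= ut[i])
        d <- sum(t == ut[i] & e == 1)
        s <- s * (1 - d / n)
        surv[i] <- s
    }
    list(times = ut, surv = surv)
}
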