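#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. A single per-sample latent
#' risk factor z ~ N(0,1) simultaneously drives the expression of the
#' planted genes, the progression indicator, and the DFS/OS hazards -- the
#' minimal structure under which genes essential for cancer-cell survival
#' are also progression biomarkers by construction.
#'
#' Defaults describe a TCGA-like bulk cohort: log2 expression with a shared
#' baseline mean of 3 and per-observation noise sd of 2 (inter-tumour
#' heterogeneity typical of variable genes on the log2 RSEM scale), planted
#' genes boosted by 4 log2 units (twice the noise sd, so they dominate the
#' ubiquity ranking) with latent-risk loadings ~ N(1, latentLoadingSd), a
#' log-odds progression effect of 1.5 per latent-risk unit, a 20-cell-line
#' screen with 3 shRNAs per gene (essential mean log2 FC -1, sd 0.3), an
#' exponential DFS model with baseline hazard 0.05/month and log hazard
#' ratio 0.7 per latent-risk unit, and 30\% independent exponential
#' censoring. Overall survival uses half the DFS baseline hazard with the
#' same latent effect.
#'
#' @param nSamples,nGenes cohort dimensions.
#' @param nPlanted number of genes that are simultaneously ubiquitous,
#'   essential and progression-linked.
#' @param baselineLogExpressionMean,baselineLogExpressionSd shared log2
#'   baseline and per-observation noise sd.
#' @param plantedExpressionBoost log2 units added to planted genes.
#' @param progressionEffect log-odds of progression per latent-risk unit.
#' @param latentLoadingSd sd of per-planted-gene loadings around 1.
#' @param nCellLines,shrnasPerGene screen dimensions.
#' @param essentialFcMean,nullFcMean,fcSd shRNA log2 fold-change model.
#' @param baselineHazard exponential DFS baseline hazard (per month).
#' @param hazardLogHr log hazard ratio per latent-risk unit.
#' @param censorRate target fraction of censored DFS/OS times, in [0,1].
#' @param seed integer; fully determines the output.
#' @return A list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nSamples = 400L, nGenes = 2000L, nPlanted = 20L,
                             baselineLogExpressionMean = 3,
                             baselineLogExpressionSd = 2,
                             plantedExpressionBoost = 4,
                             progressionEffect = 1.5,
                             latentLoadingSd = 0.25,
                             nCellLines = 20L, shrnasPerGene = 3L,
                             essentialFcMean = -1, nullFcMean = 0,
                             fcSd = 0.3, baselineHazard = 0.05,
                             hazardLogHr = 0.7, censorRate = 0.3,
                             seed = 1L) {
    cfg <- list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
                nPlanted = as.integer(nPlanted),
                baselineLogExpressionMean = baselineLogExpressionMean,
                baselineLogExpressionSd = baselineLogExpressionSd,
                plantedExpressionBoost = plantedExpressionBoost,
                progressionEffect = progressionEffect,
                latentLoadingSd = latentLoadingSd,
                nCellLines = as.integer(nCellLines),
                shrnasPerGene = as.integer(shrnasPerGene),
                essentialFcMean = essentialFcMean, nullFcMean = nullFcMean,
                fcSd = fcSd, baselineHazard = baselineHazard,
                hazardLogHr = hazardLogHr, censorRate = censorRate,
                seed = as.integer(seed))
    for (nm in c("baselineLogExpressionMean", "progressionEffect",
                 "essentialFcMean", "nullFcMean", "hazardLogHr"))
        .checkFiniteScalar(cfg[[nm]], nm)
    for (nm in c("baselineLogExpressionSd", "plantedExpressionBoost",
                 "latentLoadingSd"))
        .checkFiniteScalar(cfg[[nm]], nm, min = 0)
    .checkFiniteScalar(cfg$fcSd, "fcSd", min = 0, strictMin = TRUE)
    .checkFiniteScalar(cfg$baselineHazard, "baselineHazard", min = 0,
                       strictMin = TRUE)
    .checkFiniteScalar(cfg$censorRate, "censorRate", min = 0, max = 1)
    for (nm in c("nSamples", "nGenes", "nCellLines", "shrnasPerGene"))
        if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
            stop("'", nm, "' must be a positive integer")
    if (is.na(cfg$nPlanted) || cfg$nPlanted < 0L)
        stop("'nPlanted' must be a non-negative integer")
    if (cfg$nPlanted > cfg$nGenes) stop("nPlanted exceeds nGenes")
    if (is.na(cfg$seed)) stop("'seed' must be an integer")
    structure(cfg, class = "SimulationConfig")
}

# exponential censoring time calibrated so about `rate` of events are
# censored, given the marginal event hazard lambdaBar
.censorTimes <- function(n, rate, lambdaBar) {
    if (rate <= 0) return(rep(Inf, n))
    if (rate >= 1) return(rep(0, n))
    stats::rexp(n, rate / (1 - rate) * lambdaBar)
}

#' Generate a synthetic cohort with a planted progression axis
#'
#' Draws a per-sample latent risk z ~ N(0,1); planted gene expression (log2)
#' is baseline + boost + loading*z + noise, non-planted genes baseline +
#' noise, exported as 2^log2 so the raw matrix is RSEM-like non-negative.
#' The progression indicator is Bernoulli(logistic(beta*z)); DFS/OS times
#' are exponential with hazard baseline*exp(logHR*z) (OS at half the DFS
#' baseline), independently exponentially censored at the requested rate;
#' the screen draws shRNA log2 fold changes from N(essentialFcMean, fcSd)
#' for planted genes and N(nullFcMean, fcSd) otherwise, per cell line.
#' Adjuvant treatment (coin-flip assignment) multiplies the DFS hazard by
#' exp(-0.3); treated samples get a responder/resistant call whose
#' resistance odds grow with z; the hypoxia score is 0.5*z + N(0,1).
#'
#' Identical seeds give bit-identical cohorts.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A \linkS4class{SyntheticCohort}.
#' @examples
#' sc <- simulateCohort(simulationConfig(nSamples = 40, nGenes = 100,
#'                                       nPlanted = 5, nCellLines = 4))
#' sc
#' @export
simulateCohort <- function(config) {
    if (!inherits(config, "SimulationConfig"))
        config <- do.call(simulationConfig, as.list(config))
    c_ <- config
    .withSeed(c_$seed, {
        genes <- sprintf("G%05d", seq_len(c_$nGenes))
        samples <- sprintf("S%04d", seq_len(c_$nSamples))
        planted <- sort(sample(genes, c_$nPlanted))
        z <- stats::rnorm(c_$nSamples)
        names(z) <- samples

        L <- matrix(stats::rnorm(c_$nGenes * c_$nSamples,
                                 mean = c_$baselineLogExpressionMean,
                                 sd = c_$baselineLogExpressionSd),
                    c_$nGenes, c_$nSamples, dimnames = list(genes, samples))
        if (c_$nPlanted > 0L) {
            loadings <- 1 + stats::rnorm(c_$nPlanted, 0, c_$latentLoadingSd)
            L[planted, ] <- L[planted, , drop = FALSE] +
                c_$plantedExpressionBoost + outer(loadings, z)
        }
        expr <- 2^L

        progressed <- stats::rbinom(c_$nSamples, 1L,
                                    stats::plogis(c_$progressionEffect * z))
        treated <- stats::rbinom(c_$nSamples, 1L, 0.5)
        dfsRate <- c_$baselineHazard *
            exp(c_$hazardLogHr * z - 0.3 * treated)
        tDfs <- stats::rexp(c_$nSamples, dfsRate)
        lambdaBar <- c_$baselineHazard * exp(c_$hazardLogHr^2 / 2)
        cDfs <- .censorTimes(c_$nSamples, c_$censorRate, lambdaBar)
        osRate <- c_$baselineHazard / 2 * exp(c_$hazardLogHr * z)
        tOs <- stats::rexp(c_$nSamples, osRate)
        cOs <- .censorTimes(c_$nSamples, c_$censorRate, lambdaBar / 2)

        resistant <- stats::rbinom(c_$nSamples, 1L, stats::plogis(0.8 * z))
        clinical <- data.frame(
            sample_id = samples,
            progressed = progressed,
            dfs_months = pmin(tDfs, cDfs),
            dfs_event = as.integer(tDfs <= cDfs),
            os_months = pmin(tOs, cOs),
            os_event = as.integer(tOs <= cOs),
            age = round(stats::rnorm(c_$nSamples, 65, 10), 1),
            gender = sample(c("male", "female"), c_$nSamples, replace = TRUE),
            stage = ifelse(stats::rbinom(c_$nSamples, 1L,
                                         stats::plogis(0.5 * z)) == 1L,
                           "late", "early"),
            smoking = sample(c("never", "former", "current"), c_$nSamples,
                             replace = TRUE),
            treated = treated,
            response = ifelse(treated == 1L,
                              ifelse(resistant == 1L, "resistant",
                                     "responder"), NA_character_),
            hypoxia_score = 0.5 * z + stats::rnorm(c_$nSamples),
            stringsAsFactors = FALSE)

        cellLines <- sprintf("CL%02d", seq_len(c_$nCellLines))
        shrna <- paste0(rep(genes, each = c_$shrnasPerGene), "_sh",
                        rep(seq_len(c_$shrnasPerGene), times = c_$nGenes))
        shrnaGene <- rep(genes, each = c_$shrnasPerGene)
        nSh <- length(shrna)
        fcMean <- ifelse(shrnaGene %in% planted, c_$essentialFcMean,
                         c_$nullFcMean)
        records <- data.frame(
            shrna_id = rep(shrna, times = c_$nCellLines),
            gene = rep(shrnaGene, times = c_$nCellLines),
            cell_line = rep(cellLines, each = nSh),
            log2_fc = stats::rnorm(nSh * c_$nCellLines,
                                   mean = rep(fcMean, times = c_$nCellLines),
                                   sd = c_$fcSd),
            stringsAsFactors = FALSE)

        methods::new("SyntheticCohort",
                     experiment = PgsExperiment(expr, clinical = clinical,
                                                scale = "raw"),
                     screen = ShrnaScreen(records),
                     plantedGenes = planted,
                     latentRisk = z,
                     config = unclass(c_))
    })
}

#' Simulate a two-group exponential survival cohort
#'
#' Oracle input for the survival statistics: group 1 has hazard
#' baseline * hazardRatio, group 0 has the baseline hazard; optional
#' independent exponential censoring at the requested rate.
#'
#' @param nPerGroup samples per group.
#' @param hazardRatio hazard ratio of group 1 vs group 0 (> 0).
#' @param baselineHazard baseline exponential hazard (> 0).
#' @param censorRate target censoring fraction in [0,1).
#' @param seed integer seed.
#' @return data.frame (sample_id, group, dfs_months, dfs_event).
#' @export
simulateTwoGroupSurvival <- function(nPerGroup, hazardRatio,
                                     baselineHazard, censorRate = 0,
                                     seed = 1L) {
    .checkFiniteScalar(hazardRatio, "hazardRatio", min = 0, strictMin = TRUE)
    .checkFiniteScalar(baselineHazard, "baselineHazard", min = 0,
                       strictMin = TRUE)
    .checkFiniteScalar(censorRate, "censorRate", min = 0, max = 1)
    nPerGroup <- as.integer(nPerGroup)
    if (is.na(nPerGroup) || nPerGroup < 1L)
        stop("'nPerGroup' must be a positive integer")
    .withSeed(seed, {
        n <- 2L * nPerGroup
        group <- rep(c(0L, 1L), each = nPerGroup)
        rate <- baselineHazard * hazardRatio^group
        t <- stats::rexp(n, rate)
        cens <- .censorTimes(n, censorRate,
                             baselineHazard * (1 + hazardRatio) / 2)
        data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                   group = group,
                   dfs_months = pmin(t, cens),
                   dfs_event = as.integer(t <= cens),
                   stringsAsFactors = FALSE)
    })
}
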