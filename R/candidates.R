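#' Rank genes by ubiquity of expression
#'
#' The primary candidate pool starts from the most ubiquitously expressed
#' genes. Ubiquity is operationalized as the per-gene 5th percentile of
#' log2 expression across samples -- a robust minimum that is high only when
#' the gene is highly expressed in essentially all samples. Per-gene mean
#' expression is available as an alternative statistic. Ties are broken
#' lexicographically by gene symbol.
#'
#' @param x a \linkS4class{PgsExperiment} on log scale (raw input is
#'   log2(x+1)-transformed), with at least 2 samples.
#' @param statistic \code{"quantile"} (default) or \code{"mean"}.
#' @param prob quantile level for the quantile statistic (default 0.05).
#' @return Named numeric vector of the statistic, sorted in rank order
#'   (descending statistic, ties by gene symbol).
#' @export
ubiquityRank <- function(x, statistic = c("quantile", "mean"), prob = 0.05) {
    statistic <- match.arg(statistic)
    if (exprScale(x) == "raw") x <- logTransform(x)
    if (exprScale(x) != "log")
        stop("ubiquityRank expects raw or log scale expression")
    if (ncol(x) < 2L) stop("need at least 2 samples")
    v <- exprValues(x)
    stat <- switch(statistic,
                   quantile = apply(v, 1L, stats::quantile, probs = prob,
                                    names = FALSE),
                   mean = rowMeans(v))
    names(stat) <- rownames(v)
    stat[order(-stat, names(stat))]
}

#' Select the top percentile of a ranked statistic
#'
#' Returns the genes at or above the given percentile of the statistic's
#' distribution: \code{ceiling(n * (1 - percentile/100))} genes after the
#' deterministic tie handling of \code{\link{ubiquityRank}}. At the 99th
#' percentile of a 20,000-gene universe this is the 200-gene pool.
#'
#' @param statistic named numeric vector (any order; re-ranked internally).
#' @param percentile percentile cutoff in (0, 100), default 99.
#' @return Character vector of selected genes in rank order.
#' @export
selectTopPercentile <- function(statistic, percentile = 99) {
    if (!is.numeric(percentile) || length(percentile) != 1L ||
        !is.finite(percentile) || percentile <= 0 || percentile >= 100)
        stop("'percentile' must lie strictly between 0 and 100")
    if (is.null(names(statistic))) stop("'statistic' must be named by gene")
    ranked <- statistic[order(-statistic, names(statistic))]
    # round before ceiling: n*(1-p/100) can carry float error (20000*0.01
    # is 200.00000000000003, which must select 200 genes, not 201)
    k <- ceiling(round(length(ranked) * (1 - percentile / 100), 9))
    names(ranked)[seq_len(k)]
}

#' Refine the candidate pool size by downstream BIC
#'
#' For each candidate pool size, the full downstream path is run
#' (essentiality filtering of the pool, then backward stepwise assembly of
#' the signature) and the BIC of the final stepwise logistic model
#' (-2 logL + k log n, k counting the intercept) is recorded. The pool at
#' the BIC-minimizing size is returned, ties going to the smaller size.
#'
#' @param x a \linkS4class{PgsExperiment} (raw or log scale).
#' @param labels binary progression indicator per sample (NA allowed;
#'   NA-labelled samples are excluded from the stepwise fit).
#' @param screen an \linkS4class{ShrnaScreen}.
#' @param candidateSizes pool sizes to evaluate (default 200, 150, 100, 50).
#' @param statistic,prob passed to \code{\link{ubiquityRank}}.
#' @param pThreshold stepwise removal threshold (default 0.25).
#' @return A \linkS4class{CandidatePool} with the full \code{bicTrace}.
#' @export
refinePoolByBic <- function(x, labels, screen,
                            candidateSizes = c(200L, 150L, 100L, 50L),
                            statistic = "quantile", prob = 0.05,
                            pThreshold = 0.25) {
    if (!length(candidateSizes)) stop("'candidateSizes' must be non-empty")
    candidateSizes <- as.integer(candidateSizes)
    if (any(candidateSizes > nrow(x)))
        stop("candidate size exceeds the gene universe (", nrow(x), ")")
    rank <- ubiquityRank(x, statistic = statistic, prob = prob)
    z <- zscoreByGene(x)
    bic <- vapply(candidateSizes, function(k) {
        pool <- names(rank)[seq_len(k)]
        ess <- callSurvivalGenes(screen, pool)
        sg <- ess$gene[ess$is_survival_gene]
        if (!length(sg)) return(.interceptOnlyBic(labels))
        sig <- backwardStepwise(z, labels, sg, pThreshold = pThreshold)
        sig@modelBIC
    }, numeric(1))
    trace <- data.frame(pool_size = candidateSizes, bic = bic)
    best <- candidateSizes[order(bic, candidateSizes)][1L]
    methods::new("CandidatePool",
                 genes = names(rank)[seq_len(best)],
                 ubiquityStatistic = rank,
                 poolSize = best,
                 bicTrace = trace)
}

.interceptOnlyBic <- function(labels) {
    y <- labels[!is.na(labels)]
    y <- .checkBinary(y)
    fit <- stats::glm(y ~ 1, family = stats::binomial())
    stats::BIC(fit)
}
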