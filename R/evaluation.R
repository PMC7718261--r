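#' ROC curve and AUC
#'
#' The AUC is computed as the tie-corrected Mann-Whitney concordance
#' (midranks), which equals the trapezoidal area under the ROC curve with
#' ties traversed diagonally.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary labels, both classes present.
#' @return list of class \code{RocCurve}: thresholds, sensitivity, fpr,
#'   auc, nPos, nNeg.
#' @export
rocAuc <- function(scores, labels) {
    y <- .checkBinary(labels)
    if (length(scores) != length(y))
        stop("scores and labels lengths differ")
    if (any(is.na(scores))) stop("scores contain NA")
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    r <- rank(scores)                      # midranks handle ties
    auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

    thr <- sort(unique(scores), decreasing = TRUE)
    tp <- vapply(thr, function(t) sum(scores >= t & y == 1L), numeric(1))
    fp <- vapply(thr, function(t) sum(scores >= t & y == 0L), numeric(1))
    structure(list(thresholds = c(Inf, thr),
                   sensitivity = c(0, tp / n1),
                   fpr = c(0, fp / n0),
                   auc = auc, nPos = n1, nNeg = n0),
              class = "RocCurve")
}

#' Compare two correlated ROC curves (DeLong paired test)
#'
#' Both score vectors must be computed on the same samples. Degenerate
#' variance (e.g. identical scores) gives z = 0, p = 1 with a warning.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels binary labels.
#' @return list(z, p, aucA, aucB, deltaAuc, method).
#' @export
compareRocs <- function(scoresA, scoresB, labels) {
    y <- .checkBinary(labels)
    if (length(scoresA) != length(y) || length(scoresB) != length(y))
        stop("scores and labels lengths differ")
    aucA <- rocAuc(scoresA, y)$auc
    aucB <- rocAuc(scoresB, y)$auc
    if (isTRUE(all.equal(scoresA, scoresB)))
        return(list(z = 0, p = 1, aucA = aucA, aucB = aucB,
                    deltaAuc = 0, method = "DeLong"))
    rA <- pROC::roc(y, scoresA, quiet = TRUE, direction = "<")
    rB <- pROC::roc(y, scoresB, quiet = TRUE, direction = "<")
    tst <- tryCatch(pROC::roc.test(rA, rB, method = "delong",
                                   paired = TRUE),
                    error = function(e) NULL)
    if (is.null(tst) || !is.finite(tst$p.value)) {
        warning("degenerate variance in DeLong comparison; p = 1")
        return(list(z = 0, p = 1, aucA = aucA, aucB = aucB,
                    deltaAuc = aucA - aucB, method = "DeLong"))
    }
    list(z = unname(tst$statistic), p = tst$p.value,
         aucA = aucA, aucB = aucB, deltaAuc = aucA - aucB,
         method = "DeLong")
}

#' Baseline biomarker scores
#'
#' Single-gene baseline scores are the z-scored expression of each
#' biomarker gene; the combined baseline is the out-of-fold fitted
#' probability of a logistic regression on all available biomarker genes
#' ("assessed together"). Missing genes are skipped with a warning.
#'
#' @param x a \linkS4class{PgsExperiment}.
#' @param biomarkerGenes character vector of baseline biomarker genes.
#' @param labels binary progression labels.
#' @param folds CV folds for the combined model (default 10).
#' @param seed fold-assignment seed.
#' @return list(single = named list of score vectors, combined = out-of-fold
#'   probability vector (NULL if no genes present), genesUsed,
#'   genesMissing).
#' @export
baselineBiomarkerScores <- function(x, biomarkerGenes, labels, folds = 10L,
                                    seed = 1L) {
    y <- .checkBinary(labels)
    present <- intersect(biomarkerGenes, rownames(x))
    missing <- setdiff(biomarkerGenes, present)
    for (g in missing)
        warning("biomarker gene '", g, "' missing; skipped")
    if (!length(present))
        return(list(single = list(), combined = NULL,
                    genesUsed = character(0), genesMissing = missing))
    z <- zscoreByGene(x[present, ])
    Z <- t(exprValues(z))
    single <- stats::setNames(lapply(present, function(g) Z[, g]), present)

    foldAssign <- .stratifiedFolds(y, folds, seed)
    oof <- rep(NA_real_, length(y))
    df <- as.data.frame(Z)
    names(df) <- paste0("g", seq_len(ncol(Z)))
    for (k in seq_len(folds)) {
        tr <- foldAssign != k
        fit <- suppressWarnings(
            stats::glm(y[tr] ~ ., data = df[tr, , drop = FALSE],
                       family = stats::binomial()))
        oof[!tr] <- stats::predict(fit, newdata = df[!tr, , drop = FALSE],
                                   type = "response")
    }
    list(single = single, combined = oof, genesUsed = present,
         genesMissing = missing)
}

#' Risk-group evaluation report
#'
#' The assessment battery applied to a scored cohort: the risk-group x
#' progression confusion matrix with Fisher's exact p; Kaplan-Meier DFS
#' curves, medians and the log-rank test by risk group; within-group
#' treated-vs-untreated one-tailed Welch t-tests on DFS time (treatment
#' benefit); the risk-group x response Fisher's exact test; and the
#' two-tailed Welch t-test of hypoxia score between risk groups. Any
#' contrast whose arm is empty (or too small) is skipped and flagged rather
#' than computed.
#'
#' @param scores data.frame from \code{\link{scoreSamples}}.
#' @param clinical clinical data.frame with \code{sample_id}.
#' @return list of class \code{EvaluationReport}: confusion, fisherP, km
#'   (per-group curves, medians, logrank), treatment, response, hypoxia,
#'   skipped.
#' @export
riskGroupReport <- function(scores, clinical) {
    d <- merge(scores, clinical, by = "sample_id")
    if (!nrow(d)) stop("no overlapping samples between scores and clinical")
    d$group <- factor(d$group, levels = c("low", "high"))
    skipped <- character(0)
    rep_ <- list()

    # confusion matrix: risk group x progression
    if ("progressed" %in% names(d) && !all(is.na(d$progressed))) {
        dc <- d[!is.na(d$progressed), ]
        conf <- table(group = dc$group, progressed = dc$progressed)
        rep_$confusion <- conf
        if (all(dim(conf) == 2L) && all(rowSums(conf) > 0)) {
            rep_$fisherP <- fisherExact2x2(conf)$p
        } else {
            skipped <- c(skipped, "confusion_fisher: a risk group is empty")
        }
    } else skipped <- c(skipped, "confusion: no progression labels")

    # KM / log-rank by risk group on DFS
    if (all(c("dfs_months", "dfs_event") %in% names(d))) {
        ds <- d[!is.na(d$dfs_months) & !is.na(d$dfs_event), ]
        groups <- levels(droplevels(ds$group))
        if (length(groups) == 2L && sum(ds$dfs_event) >= 1L) {
            km <- lapply(split(ds, ds$group), function(g)
                kmFit(g$dfs_months, g$dfs_event))
            rep_$km <- list(
                curves = km,
                medians = vapply(km, kmMedian, numeric(1)),
                mediansFormatted = vapply(km, formatKmMedian, character(1)),
                logrank = logrankTest(ds$dfs_months, ds$dfs_event,
                                      ds$group))
        } else skipped <- c(skipped, "km: fewer than two risk groups or no events")
    } else skipped <- c(skipped, "km: no DFS columns")

    # treatment benefit: within each risk group, treated vs untreated DFS
    if (all(c("treated", "dfs_months") %in% names(d))) {
        rep_$treatment <- lapply(split(d, d$group), function(g) {
            trt <- g$dfs_months[g$treated %in% 1 & !is.na(g$dfs_months)]
            unt <- g$dfs_months[g$treated %in% 0 & !is.na(g$dfs_months)]
            if (length(trt) < 2L || length(unt) < 2L) {
                skipped <<- c(skipped, paste0(
                    "treatment[", g$group[1L], "]: arm with n < 2"))
                return(NULL)
            }
            # one-tailed: does treatment lengthen DFS within the group?
            c(welchT(trt, unt, alternative = "greater"),
              list(nTreated = length(trt), nUntreated = length(unt)))
        })
    } else skipped <- c(skipped, "treatment: columns unavailable")

    # risk group x treatment response
    if ("response" %in% names(d) && !all(is.na(d$response))) {
        dr <- d[!is.na(d$response), ]
        tabR <- table(group = droplevels(dr$group), response = dr$response)
        rep_$responseTable <- tabR
        if (all(dim(tabR) == 2L) && all(rowSums(tabR) > 0)) {
            rep_$responseFisherP <- fisherExact2x2(tabR)$p
        } else skipped <- c(skipped, "response: a group or category is empty")
    } else skipped <- c(skipped, "response: column unavailable")

    # hypoxia score: high vs low risk, two-tailed
    if ("hypoxia_score" %in% names(d) && !all(is.na(d$hypoxia_score))) {
        hi <- d$hypoxia_score[d$group == "high" & !is.na(d$hypoxia_score)]
        lo <- d$hypoxia_score[d$group == "low" & !is.na(d$hypoxia_score)]
        if (length(hi) >= 2L && length(lo) >= 2L) {
            rep_$hypoxia <- welchT(hi, lo, alternative = "two.sided")
        } else skipped <- c(skipped, "hypoxia: a group has n < 2")
    } else skipped <- c(skipped, "hypoxia: column unavailable")

    rep_$skipped <- skipped
    class(rep_) <- "EvaluationReport"
    rep_
}

#' @export
print.EvaluationReport <- function(x, ...) {
    cat("EvaluationReport\n")
    if (!is.null(x$confusion)) {
        cat("  confusion (group x progressed):\n")
        print(x$confusion)
        if (!is.null(x$fisherP))
            cat("  Fisher exact p:", format(x$fisherP, digits = 3), "\n")
    }
    if (!is.null(x$km)) {
        cat("  KM median DFS:",
            paste(names(x$km$mediansFormatted), x$km$mediansFormatted,
                  sep = " = ", collapse = ", "),
            "| log-rank p:", format(x$km$logrank$p, digits = 3), "\n")
    }
    if (!is.null(x$hypoxia))
        cat("  hypoxia Welch t p:", format(x$hypoxia$p, digits = 3), "\n")
    if (length(x$skipped))
        cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
    invisible(x)
}
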