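#' @importFrom survival Surv survfit survdiff coxph coxph.control
NULL

#' Kaplan-Meier product-limit estimator
#'
#' At tied times, events are handled before censorings (the standard
#' product-limit convention).
#'
#' @param times non-negative event/censoring times.
#' @param events binary event indicators (1 = event, 0 = censored).
#' @return list of class \code{KmCurve}: times, survival, atRisk, events,
#'   median (NA when the curve never reaches 0.5), maxTime.
#' @export
kmFit <- function(times, events) {
    if (!length(times)) stop("empty survival input")
    if (any(times < 0, na.rm = TRUE)) stop("times must be non-negative")
    events <- as.integer(events)
    if (!all(events %in% c(0L, 1L))) stop("events must be 0/1")
    fit <- survival::survfit(survival::Surv(times, events) ~ 1)
    surv <- fit$surv
    idx <- which(surv <= 0.5)
    med <- if (length(idx)) fit$time[min(idx)] else NA_real_
    structure(list(times = fit$time, survival = surv,
                   atRisk = fit$n.risk, events = fit$n.event,
                   median = med, maxTime = max(times)),
              class = "KmCurve")
}

#' Median survival time of a KM curve
#'
#' The smallest time at which the survival estimate drops to 0.5 or below.
#' When the curve never reaches 0.5 the median is undefined and is reported
#' in "> max follow-up" style by \code{\link{formatKmMedian}}.
#'
#' @param curve a \code{KmCurve}.
#' @return Numeric median, or \code{NA} when undefined.
#' @export
kmMedian <- function(curve) curve$median

#' Format a KM median for reporting
#' @param curve a \code{KmCurve}.
#' @param digits significant digits.
#' @return e.g. \code{"6.9"} or \code{"> 250"} when the median is undefined.
#' @export
formatKmMedian <- function(curve, digits = 3) {
    if (is.na(curve$median))
        paste(">", format(curve$maxTime, digits = digits))
    else format(curve$median, digits = digits)
}

#' Mantel-Cox log-rank test
#'
#' @param times,events as in \code{\link{kmFit}}.
#' @param group group membership (2 or more groups).
#' @return list(chi2, df, p).
#' @export
logrankTest <- function(times, events, group) {
    events <- as.integer(events)
    group <- as.factor(group)
    if (nlevels(group) < 2L) stop("need at least 2 groups")
    if (sum(events) < 1L) stop("log-rank test needs at least one event")
    sd <- survival::survdiff(survival::Surv(times, events) ~ group)
    df <- length(sd$n) - 1L
    list(chi2 = unname(sd$chisq), df = df,
         p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit with Efron tie handling (Breslow by option).
#' Wald confidence intervals exp(beta +/- 1.96 se). Monotone likelihood
#' (infinite coefficient) or non-convergence is an error naming the
#' covariate.
#'
#' @param times,events as in \code{\link{kmFit}}.
#' @param covariates data.frame or matrix of covariates (no constant
#'   columns).
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return list of class \code{CoxResult}: table (term, coef, hr, lo95,
#'   hi95, se, z, p), logLik, scoreTest (chi2, df, p), ties.
#' @export
coxFit <- function(times, events, covariates, ties = c("efron", "breslow")) {
    ties <- match.arg(ties)
    cov <- as.data.frame(covariates)
    if (!ncol(cov)) stop("no covariates")
    const <- names(cov)[vapply(cov, function(v)
        length(unique(v[!is.na(v)])) < 2L, logical(1))]
    if (length(const))
        stop("constant covariate(s): ", paste(const, collapse = ", "))
    if (sum(events) < 1L) stop("need at least one event")
    dat <- cbind(data.frame(.t = times, .e = as.integer(events)), cov)
    fit <- survival::coxph(survival::Surv(.t, .e) ~ ., data = dat,
                           ties = ties,
                           control = survival::coxph.control(
                               iter.max = 100L, eps = 1e-9))
    if (fit$iter >= 100L)
        stop("Cox fit did not converge in 100 iterations")
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    bad <- names(beta)[!is.finite(beta) | abs(beta) > 15 | se > 100]
    if (length(bad))
        stop("monotone likelihood / unstable coefficient for covariate(s): ",
             paste(bad, collapse = ", "))
    sc <- fit$score
    tab <- data.frame(term = names(beta), coef = unname(beta),
                      hr = exp(unname(beta)),
                      lo95 = exp(unname(beta) - 1.96 * se),
                      hi95 = exp(unname(beta) + 1.96 * se),
                      se = unname(se), z = unname(beta / se),
                      p = 2 * stats::pnorm(-abs(unname(beta / se))),
                      stringsAsFactors = FALSE)
    structure(list(table = tab,
                   logLik = fit$loglik[2L],
                   scoreTest = list(chi2 = unname(sc),
                                    df = length(beta),
                                    p = stats::pchisq(sc, length(beta),
                                                      lower.tail = FALSE)),
                   ties = ties),
              class = "CoxResult")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided by default (summing hypergeometric probabilities at or below
#' the observed table's); one-sided modes available. A zero margin makes
#' the table uninformative: p = 1 with a warning.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @param alternative \code{"two.sided"}, \code{"less"} or \code{"greater"}.
#' @return list(p, alternative, table).
#' @export
fisherExact2x2 <- function(tab, alternative = c("two.sided", "less",
                                                "greater")) {
    alternative <- match.arg(alternative)
    tab <- as.matrix(tab)
    if (!all(dim(tab) == 2L)) stop("table must be 2x2")
    if (any(tab < 0) || any(tab != round(tab)))
        stop("table must contain non-negative integers")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warning("zero margin in 2x2 table; p = 1")
        return(list(p = 1, alternative = alternative, table = tab))
    }
    list(p = stats::fisher.test(tab, alternative = alternative)$p.value,
         alternative = alternative, table = tab)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom. Two
#' degenerate identical samples give t = 0 and the null p-value directly.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @param alternative \code{"two.sided"}, \code{"less"} or \code{"greater"}
#'   (one-tailed tests per the treatment-response protocol).
#' @return list(t, df, p).
#' @export
welchT <- function(a, b, alternative = c("two.sided", "less", "greater")) {
    alternative <- match.arg(alternative)
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
        stop("each sample needs at least 2 values")
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
        p <- if (alternative == "two.sided") 1 else 0.5
        return(list(t = 0, df = NA_real_, p = p))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE, alternative = alternative)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}
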