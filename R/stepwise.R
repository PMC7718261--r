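# ridge-stabilized logistic fit used when glm hits separation: IRLS with a
# small L2 penalty on the slopes (never the intercept)
.logisticRidge <- function(X, y, lambda = 1e-4, maxIter = 100L) {
    X1 <- cbind(`(Intercept)` = 1, X)
    p <- ncol(X1)
    pen <- diag(c(0, rep(lambda, p - 1L)), p)
    beta <- rep(0, p)
    for (it in seq_len(maxIter)) {
        eta <- drop(X1 %*% beta)
        mu <- stats::plogis(eta)
        w <- pmax(mu * (1 - mu), 1e-10)
        H <- crossprod(X1 * w, X1) + pen
        g <- crossprod(X1, y - mu) - pen %*% beta
        step <- solve(H, g)
        beta <- beta + drop(step)
        if (max(abs(step)) < 1e-10) break
    }
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    cov <- solve(crossprod(X1 * w, X1) + pen)
    se <- sqrt(diag(cov))
    ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
    names(beta) <- names(se) <- colnames(X1)
    list(coef = beta, se = se, logLik = ll,
         bic = -2 * ll + p * log(length(y)), ridge = TRUE)
}

# fit logistic regression of y on the given columns of X; returns per-column
# Wald (or LR) p-values, logLik and BIC; falls back to ridge on separation
.logisticWald <- function(X, y, pType = "wald") {
    if (ncol(X) == 0L) {
        fit <- stats::glm(y ~ 1, family = stats::binomial())
        return(list(p = numeric(0), logLik = as.numeric(stats::logLik(fit)),
                    bic = stats::BIC(fit), ridge = FALSE))
    }
    safe <- paste0("g", seq_len(ncol(X)))
    df <- as.data.frame(X)
    names(df) <- safe
    df$.y <- y
    sep <- FALSE
    fit <- withCallingHandlers(
        stats::glm(.y ~ ., data = df, family = stats::binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                      conditionMessage(w))) {
                sep <<- TRUE
                invokeRestart("muffleWarning")
            }
        })
    cf0 <- stats::coef(fit)
    se0 <- sqrt(diag(stats::vcov(fit)))
    # separation can pass glm's convergence check silently, leaving huge
    # coefficients/SEs on z-scored covariates
    if (any(is.finite(cf0) & abs(cf0) > 10) || any(se0 > 30)) sep <- TRUE
    if (sep || any(is.na(stats::coef(fit)))) {
        warning("separation or collinearity in logistic fit; ",
                "using ridge-stabilized fallback (lambda = 1e-4)")
        Xm <- as.matrix(X)
        r <- .logisticRidge(Xm, y)
        # Wald SEs degenerate under separation (covariance ~ 1/lambda);
        # penalized likelihood-ratio p-values stay informative
        p <- vapply(seq_len(ncol(Xm)), function(j) {
            r0 <- if (ncol(Xm) > 1L) .logisticRidge(Xm[, -j, drop = FALSE], y)
                  else list(logLik = sum(stats::dbinom(y, 1, mean(y),
                                                       log = TRUE)))
            stats::pchisq(2 * (r$logLik - r0$logLik), 1,
                          lower.tail = FALSE)
        }, numeric(1))
        names(p) <- colnames(X)
        return(list(p = p, logLik = r$logLik, bic = r$bic, ridge = TRUE))
    }
    cf <- summary(fit)$coefficients
    if (pType == "lr") {
        p <- vapply(seq_len(ncol(X)), function(j) {
            red <- stats::glm(.y ~ ., data = df[, c(safe[-j], ".y"),
                                                drop = FALSE],
                              family = stats::binomial())
            stats::pchisq(2 * (as.numeric(stats::logLik(fit)) -
                               as.numeric(stats::logLik(red))),
                          1, lower.tail = FALSE)
        }, numeric(1))
    } else {
        p <- cf[match(safe, rownames(cf)), "Pr(>|z|)"]
    }
    names(p) <- colnames(X)
    list(p = p, logLik = as.numeric(stats::logLik(fit)),
         bic = stats::BIC(fit), ridge = FALSE)
}

#' Assemble a signature by backward stepwise logistic regression
#'
#' Fits a logistic regression of the binary progression indicator on the
#' z-scored expression of all starting genes, then repeatedly removes the
#' covariate with the largest Wald p-value while that p-value is at or above
#' the threshold, refitting after every single removal. Ties are broken
#' deterministically (larger p first, then lexicographic gene symbol). The
#' run stops when every remaining gene has p below the threshold or only the
#' intercept remains. Perfect separation triggers a ridge-stabilized
#' fallback fit (penalty 1e-4 on slopes) with a warning.
#'
#' @param x a \linkS4class{PgsExperiment}; z-scored internally if needed.
#' @param labels binary progression indicator, either a vector aligned with
#'   (or named by) the samples; NA-labelled samples are dropped.
#' @param startGenes genes to start from (rows of \code{x}).
#' @param pThreshold removal threshold (default 0.25, chosen to retain
#'   weakly contributing / interacting genes).
#' @param maxIter cap on removals (default unlimited).
#' @param pType \code{"wald"} (default) or \code{"lr"} for likelihood-ratio
#'   p-values.
#' @param label cohort label stored on the signature.
#' @return A \linkS4class{Signature}; genes ordered by increasing final
#'   p-value, with the elimination trace and the final model's BIC.
#' @export
backwardStepwise <- function(x, labels, startGenes, pThreshold = 0.25,
                             maxIter = Inf, pType = c("wald", "lr"),
                             label = "") {
    pType <- match.arg(pType)
    if (!length(startGenes)) stop("'startGenes' is empty")
    miss <- setdiff(startGenes, rownames(x))
    if (length(miss))
        stop("start gene(s) absent from matrix: ",
             paste(utils::head(miss, 5L), collapse = ", "))
    if (exprScale(x) != "zscore") x <- zscoreByGene(x)
    if (!is.null(names(labels))) labels <- labels[colnames(x)]
    if (length(labels) != ncol(x))
        stop("'labels' length must match the number of samples")
    keep <- !is.na(labels)
    y <- .checkBinary(labels[keep])
    X <- t(exprValues(x)[startGenes, keep, drop = FALSE])

    genes <- sort(startGenes)
    trace <- data.frame(step = integer(0), gene = character(0),
                        p_at_removal = numeric(0))
    step <- 0L
    repeat {
        fit <- .logisticWald(X[, genes, drop = FALSE], y, pType = pType)
        if (!length(genes) || all(fit$p < pThreshold) || step >= maxIter)
            break
        # remove the worst gene: largest p, ties by gene symbol
        ord <- order(-fit$p, names(fit$p))
        worst <- names(fit$p)[ord[1L]]
        step <- step + 1L
        trace <- rbind(trace, data.frame(step = step, gene = worst,
                                         p_at_removal = fit$p[[worst]]))
        genes <- setdiff(genes, worst)
    }
    p <- fit$p
    if (length(p)) {
        ord <- order(p, names(p))
        genes <- names(p)[ord]
        p <- p[ord]
    } else {
        genes <- character(0)
        p <- stats::setNames(numeric(0), character(0))
    }
    methods::new("Signature", label = label, genes = genes,
                 stepwiseP = p, modelBIC = fit$bic, trace = trace)
}
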