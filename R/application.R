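#' Recode validation-cohort outcomes to progression labels
#'
#' Cross-study compatibility rules: in relapse mode, relapsed patients
#' (\code{dfs_event} = 1) are "progressed" and non-relapsed "disease-free";
#' in death mode, deceased patients (\code{os_event} = 1) are "progressed"
#' and living patients "disease-free". Samples missing the required outcome
#' are excluded, with the excluded count attached.
#'
#' @param clinical clinical data.frame with \code{sample_id}.
#' @param mode \code{"relapse"} or \code{"death"}.
#' @return Named binary vector of progression labels for retained samples;
#'   attributes \code{mode} and \code{excluded} (count).
#' @export
recodeValidationOutcomes <- function(clinical, mode = c("relapse",
                                                        "death")) {
    mode <- match.arg(mode)
    col <- switch(mode, relapse = "dfs_event", death = "os_event")
    if (!col %in% names(clinical))
        stop("mode '", mode, "' requires clinical column '", col, "'")
    v <- clinical[[col]]
    keep <- !is.na(v)
    if (any(!keep))
        message(sum(!keep), " sample(s) excluded: missing ", col)
    labels <- as.integer(v[keep])
    names(labels) <- clinical$sample_id[keep]
    attr(labels, "mode") <- mode
    attr(labels, "excluded") <- sum(!keep)
    labels
}

#' Stratified random train/validation split
#'
#' Samples are binned into strata (numeric stratification variables are cut
#' at their quartiles; categorical ones used as-is; default age quartile x
#' gender) and, within each stratum, the requested fraction is drawn into
#' the training set. Per-stratum training counts follow largest-remainder
#' apportionment of \code{round(n * fraction)}, so each stratum is within
#' one sample of its proportional share and the total is exact: 528 samples
#' at fraction 0.75 give a 396/132 split. Strata of size 1 go to training
#' with a warning. The seed fully determines the split.
#'
#' @param clinical clinical data.frame with \code{sample_id}.
#' @param fraction training fraction in (0, 1).
#' @param strata column names to stratify on (default age, gender).
#' @param seed integer seed.
#' @return list(train, validation) of sample ids.
#' @export
stratifiedSplit <- function(clinical, fraction = 0.75,
                            strata = c("age", "gender"), seed = 1L) {
    .checkFiniteScalar(fraction, "fraction", min = 0, max = 1,
                       strictMin = TRUE)
    if (fraction >= 1) stop("'fraction' must lie strictly between 0 and 1")
    miss <- setdiff(strata, names(clinical))
    if (length(miss))
        stop("stratification column(s) missing: ",
             paste(miss, collapse = ", "))
    ids <- clinical$sample_id
    if (anyDuplicated(ids)) stop("duplicate sample ids")
    bins <- lapply(strata, function(s) {
        v <- clinical[[s]]
        if (is.numeric(v)) {
            q <- unique(stats::quantile(v, probs = c(0.25, 0.5, 0.75),
                                        na.rm = TRUE))
            as.character(cut(v, breaks = c(-Inf, q, Inf),
                             labels = FALSE))
        } else as.character(v)
    })
    stratum <- do.call(paste, c(bins, sep = "|"))
    stratum[is.na(stratum)] <- "NA"

    counts <- table(stratum)
    singletons <- names(counts)[counts == 1L]
    if (length(singletons))
        warning(length(singletons),
                " stratum/strata of size 1 assigned to training")
    multi <- names(counts)[counts > 1L]
    totalTarget <- round(length(ids) * fraction)
    targetMulti <- totalTarget - length(singletons)
    raw <- counts[multi] * fraction
    base <- pmin(floor(raw), counts[multi] - 0)  # may take a full stratum
    remainder <- targetMulti - sum(base)
    if (remainder > 0) {
        frac <- raw - floor(raw)
        ord <- order(-frac, multi)
        bump <- multi[ord][seq_len(min(remainder, length(multi)))]
        base[bump] <- base[bump] + 1L
    } else if (remainder < 0) {
        frac <- raw - floor(raw)
        ord <- order(frac, multi)
        drop_ <- multi[ord][seq_len(min(-remainder, length(multi)))]
        base[drop_] <- pmax(base[drop_] - 1L, 0L)
    }

    train <- character(0)
    .withSeed(seed, {
        for (s in sort(names(counts))) {
            sid <- ids[stratum == s]
            k <- if (s %in% singletons) 1L else unname(base[s])
            k <- min(k, length(sid))
            pick <- if (k >= length(sid)) sid
                else sid[sample.int(length(sid), k)]
            train <- c(train, pick)
        }
    })
    train <- sort(train)
    list(train = train, validation = sort(setdiff(ids, train)))
}

#' Convert a qPCR Ct panel to z-scored expression
#'
#' Delta-Ct is the reference gene's Ct minus the target gene's Ct
#' (so higher delta-Ct = higher expression, proportional to log2 relative
#' abundance), z-scored per gene across the panel's samples. Samples
#' missing the reference Ct are dropped with a warning; constant delta-Ct
#' rows are flagged. The result is scored by \code{\link{scoreSamples}}
#' unchanged (already on the z-score scale).
#'
#' @param panel data.frame with \code{sample_id} and one Ct column per gene
#'   (including the reference gene).
#' @param referenceGene reference (housekeeping) gene column, default GAPDH.
#' @return A \linkS4class{PgsExperiment} on zscore scale.
#' @export
qpcrToExpression <- function(panel, referenceGene = "GAPDH") {
    panel <- as.data.frame(panel)
    if (!"sample_id" %in% names(panel))
        stop("panel lacks a sample_id column")
    if (!referenceGene %in% names(panel))
        stop("reference gene '", referenceGene, "' not in panel")
    refCt <- panel[[referenceGene]]
    drop_ <- is.na(refCt)
    if (any(drop_)) {
        warning(sum(drop_), " sample(s) dropped: missing reference Ct")
        panel <- panel[!drop_, , drop = FALSE]
        refCt <- refCt[!drop_]
    }
    if (nrow(panel) < 2L)
        stop("z-scoring a qPCR panel needs at least 2 samples")
    genes <- setdiff(names(panel), c("sample_id", referenceGene))
    if (!length(genes)) stop("no target genes in panel")
    dct <- vapply(genes, function(g) refCt - panel[[g]],
                  numeric(nrow(panel)))
    m <- t(dct)
    dimnames(m) <- list(genes, panel$sample_id)
    # delta-Ct is already a log2-scale quantity
    x <- PgsExperiment(m, scale = "log")
    zscoreByGene(x)
}

#' Run the full discovery pipeline on one cohort
#'
#' Candidate selection (ubiquity ranking at the given percentile, or BIC
#' refinement over several pool sizes), survival-gene calling from the
#' screen, backward stepwise signature assembly, risk-model training with
#' tenfold CV, scoring of the full cohort, and the evaluation battery.
#' Every stage's parameters and outputs are recorded in a run manifest. A
#' stage failure aborts with the stage name. If the stepwise model retains
#' no gene, the risk stage falls back to the unfiltered survival-gene set
#' (flagged in the manifest) since scoring needs at least one gene.
#'
#' @param x a \linkS4class{PgsExperiment} with clinical data (including
#'   \code{progressed}) in its colData.
#' @param screen an \linkS4class{ShrnaScreen}.
#' @param percentile ubiquity percentile cutoff (default 99).
#' @param bicSizes optional candidate sizes for BIC refinement (NULL skips
#'   refinement and uses the percentile pool).
#' @param pThreshold stepwise removal threshold (default 0.25).
#' @param strictFdr optional FDR level for survival-gene calling.
#' @param seed pipeline seed.
#' @param label cohort label.
#' @param ... further arguments to \code{\link{trainRiskModel}}.
#' @return list of class \code{PgsRun}: pool, essentiality, signature,
#'   model, scores, report, manifest.
#' @export
runPipeline <- function(x, screen, percentile = 99, bicSizes = NULL,
                        pThreshold = 0.25, strictFdr = NULL, seed = 1L,
                        label = "", ...) {
    manifest <- list(label = label, seed = seed, percentile = percentile,
                     bicSizes = bicSizes, pThreshold = pThreshold,
                     strictFdr = strictFdr,
                     nGenes = nrow(x), nSamples = ncol(x),
                     packageVersion = as.character(
                         utils::packageVersion("progsig")))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    labels <- clinicalData(x)$progressed
    names(labels) <- colnames(x)

    pool <- stage("candidate_selection", {
        if (is.null(bicSizes)) {
            rank <- ubiquityRank(x)
            genes <- selectTopPercentile(rank, percentile)
            methods::new("CandidatePool", genes = genes,
                         ubiquityStatistic = rank,
                         poolSize = length(genes),
                         bicTrace = data.frame())
        } else {
            refinePoolByBic(x, labels, screen, candidateSizes = bicSizes,
                            pThreshold = pThreshold)
        }
    })
    manifest$poolSize <- pool@poolSize

    ess <- stage("essentiality_screen",
                 callSurvivalGenes(screen, pool@genes,
                                   strictFdr = strictFdr))
    survGenes <- ess$gene[ess$is_survival_gene]
    manifest$nSurvivalGenes <- length(survGenes)
    if (!length(survGenes))
        stop("pipeline stage 'essentiality_screen' failed: ",
             "no survival genes (mean FC < 0) in the candidate pool",
             call. = FALSE)

    sig <- stage("signature_assembly",
                 backwardStepwise(x, labels, survGenes,
                                  pThreshold = pThreshold, label = label))
    manifest$signatureSize <- length(sig@genes)
    manifest$signatureFallback <- FALSE
    modelSig <- sig
    if (!length(sig@genes)) {
        # scoring needs >= 1 gene; fall back to the unfiltered survival set
        manifest$signatureFallback <- TRUE
        modelSig <- methods::new("Signature", label = label,
                                 genes = sort(survGenes),
                                 stepwiseP = stats::setNames(
                                     rep(NA_real_, length(survGenes)),
                                     sort(survGenes)),
                                 modelBIC = sig@modelBIC,
                                 trace = sig@trace)
    }

    model <- stage("risk_model",
                   trainRiskModel(x, modelSig, labels = labels, seed = seed,
                                  ...))
    scores <- stage("scoring", scoreSamples(model, x))
    report <- stage("evaluation", {
        rep_ <- riskGroupReport(scores, clinicalData(x))
        keep <- !is.na(labels)
        oof <- model@oof
        oofY <- labels[oof$sample_id]
        rep_$aucOof <- rocAuc(oof$probability, oofY)$auc
        rep_$aucResubstitution <- rocAuc(
            scores$probability[match(names(labels)[keep],
                                     scores$sample_id)],
            labels[keep])$auc
        rep_
    })
    manifest$aucOof <- report$aucOof
    structure(list(pool = pool, essentiality = ess, signature = sig,
                   model = model, scores = scores, report = report,
                   manifest = manifest),
              class = "PgsRun")
}

#' @export
print.PgsRun <- function(x, ...) {
    cat("PgsRun '", x$manifest$label, "'\n", sep = "")
    cat("  pool:", x$manifest$poolSize, "genes | survival genes:",
        x$manifest$nSurvivalGenes, "| signature:",
        x$manifest$signatureSize, "genes",
        if (x$manifest$signatureFallback) "(fallback to survival genes)",
        "\n")
    cat("  out-of-fold AUC:", format(x$manifest$aucOof, digits = 4), "\n")
    invisible(x)
}
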