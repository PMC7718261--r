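#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Cohort expression container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a genes x
#' samples expression matrix (assay \code{"exprs"}), per-sample clinical
#' annotation in \code{colData}, and a normalization state tag in
#' \code{metadata(x)$scale}: \code{"raw"} (RSEM-like non-negative values),
#' \code{"log"} (log2 scale) or \code{"zscore"} (per-gene standardized).
#' After z-scoring, \code{metadata(x)$geneNorm} records the per-gene
#' (mean, sd) used, sufficient to apply the identical transform to new
#' samples.
#'
#' @export
setClass("PgsExperiment", contains = "SummarizedExperiment")

setValidity("PgsExperiment", function(object) {
    msg <- character()
    g <- rownames(object)
    s <- colnames(object)
    if (is.null(g) || anyDuplicated(g))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(s) || anyDuplicated(s))
        msg <- c(msg, "sample ids must be present and unique")
    sc <- metadata(object)$scale
    if (is.null(sc) || !sc %in% c("raw", "log", "zscore"))
        msg <- c(msg, "metadata(x)$scale must be one of raw/log/zscore")
    if (identical(sc, "zscore") && ncol(object) >= 2L && nrow(object) > 0L &&
        !isTRUE(metadata(object)$replayedNorm)) {
        v <- assay(object)
        m <- rowMeans(v)
        sd1 <- apply(v, 1L, stats::sd)
        const <- metadata(object)$constantGenes
        chk <- !(rownames(object) %in% const)
        if (any(abs(m[chk]) > 1e-8))
            msg <- c(msg, "zscore scale but some gene means differ from 0")
        if (any(abs(sd1[chk] - 1) > 1e-8))
            msg <- c(msg, "zscore scale but some gene sds differ from 1")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PgsExperiment
#'
#' @param expression numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param clinical optional \code{data.frame} of per-sample clinical fields
#'   with a \code{sample_id} column (or rownames) matching the matrix columns.
#' @param scale normalization state of \code{expression}.
#' @return A \linkS4class{PgsExperiment}.
#' @examples
#' m <- matrix(rpois(6, 50), 3, 2,
#'             dimnames = list(c("TP53", "EGFR", "MET"), c("s1", "s2")))
#' PgsExperiment(m)
#' @export
PgsExperiment <- function(expression, clinical = NULL,
                          scale = c("raw", "log", "zscore")) {
    scale <- match.arg(scale)
    if (!is.matrix(expression) || !is.numeric(expression))
        stop("'expression' must be a numeric matrix")
    rownames(expression) <- trimws(rownames(expression))
    if (is.null(clinical)) {
        cd <- DataFrame(row.names = colnames(expression))
    } else {
        clinical <- as.data.frame(clinical)
        if ("sample_id" %in% names(clinical)) {
            rownames(clinical) <- clinical$sample_id
        }
        miss <- setdiff(colnames(expression), rownames(clinical))
        if (length(miss))
            stop("clinical table lacks samples: ",
                 paste(utils::head(miss, 5L), collapse = ", "))
        cd <- DataFrame(clinical[colnames(expression), , drop = FALSE])
    }
    se <- SummarizedExperiment(assays = list(exprs = expression), colData = cd,
                               metadata = list(scale = scale))
    methods::new("PgsExperiment", se)
}

#' @describeIn PgsExperiment normalization state ("raw", "log" or "zscore")
#' @param x a \code{PgsExperiment}
#' @export
exprScale <- function(x) metadata(x)$scale

#' @describeIn PgsExperiment the expression matrix
#' @export
exprValues <- function(x) assay(x, "exprs")

#' @describeIn PgsExperiment clinical annotation as a base data.frame with a
#'   \code{sample_id} column
#' @export
clinicalData <- function(x) {
    df <- as.data.frame(colData(x))
    df$sample_id <- colnames(x)
    df[, c("sample_id", setdiff(names(df), "sample_id")), drop = FALSE]
}

#' @describeIn PgsExperiment per-gene (mean, sd) recorded at z-scoring time,
#'   or NULL for raw/log data
#' @export
geneNorm <- function(x) metadata(x)$geneNorm

setMethod("show", "PgsExperiment", function(object) {
    cat("PgsExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  scale:", exprScale(object), "\n")
    cv <- setdiff(names(colData(object)), "sample_id")
    if (length(cv))
        cat("  clinical:", paste(utils::head(cv, 8L), collapse = ", "),
            if (length(cv) > 8L) "..." else "", "\n")
})

#' shRNA depletion screen
#'
#' Records of shRNA-level log2 fold changes of depletion across cell lines.
#' Each shRNA targets exactly one gene and each (shrna_id, cell_line) pair is
#' measured at most once; negative fold change means cells carrying the
#' knockdown were lost during selection.
#'
#' @slot records data.frame with columns \code{shrna_id}, \code{gene},
#'   \code{cell_line}, \code{log2_fc}.
#' @export
setClass("ShrnaScreen", representation(records = "data.frame"))

setValidity("ShrnaScreen", function(object) {
    r <- object@records
    need <- c("shrna_id", "gene", "cell_line", "log2_fc")
    if (!all(need %in% names(r)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (!is.numeric(r$log2_fc))
        return("log2_fc must be numeric")
    key <- paste(r$shrna_id, r$cell_line, sep = "\r")
    if (anyDuplicated(key))
        return("duplicated (shrna_id, cell_line) measurement")
    map <- unique(r[, c("shrna_id", "gene")])
    dup <- map$shrna_id[duplicated(map$shrna_id)]
    if (length(dup))
        return(paste0("shRNA mapped to more than one gene: ",
                      paste(unique(dup), collapse = ", ")))
    TRUE
})

#' Construct an ShrnaScreen
#'
#' @param records data.frame with columns \code{shrna_id}, \code{gene},
#'   \code{cell_line}, \code{log2_fc}.
#' @return An \linkS4class{ShrnaScreen}.
#' @export
ShrnaScreen <- function(records) {
    records <- as.data.frame(records)
    for (col in c("shrna_id", "gene", "cell_line"))
        if (col %in% names(records))
            records[[col]] <- trimws(as.character(records[[col]]))
    methods::new("ShrnaScreen", records = records)
}

#' @describeIn ShrnaScreen the underlying records data.frame
#' @param x an \code{ShrnaScreen}
#' @export
screenRecords <- function(x) x@records

#' @describeIn ShrnaScreen genes with at least one measurement
#' @export
screenGenes <- function(x) sort(unique(x@records$gene))

setMethod("show", "ShrnaScreen", function(object) {
    r <- object@records
    cat("ShrnaScreen:", nrow(r), "measurements |",
        length(unique(r$shrna_id)), "shRNAs |",
        length(unique(r$gene)), "genes |",
        length(unique(r$cell_line)), "cell lines\n")
})

#' Progression gene signature
#'
#' Ordered gene list retained by backward stepwise logistic regression of the
#' binary progression indicator on z-scored expression, with the per-gene
#' Wald p-values of the final model, its BIC, and the full elimination trace.
#'
#' @slot label cohort or cancer-type label.
#' @slot genes retained genes, ordered by increasing final p-value.
#' @slot stepwiseP named numeric, final-model p-value per retained gene.
#' @slot modelBIC BIC of the final stepwise logistic model.
#' @slot trace data.frame (step, gene, p_at_removal) of eliminated genes.
#' @export
setClass("Signature",
         representation(label = "character", genes = "character",
                        stepwiseP = "numeric", modelBIC = "numeric",
                        trace = "data.frame"))

setValidity("Signature", function(object) {
    if (length(object@genes) != length(object@stepwiseP))
        return("genes and stepwiseP lengths differ")
    if (length(object@genes) &&
        !identical(object@genes, names(object@stepwiseP)))
        return("stepwiseP must be named by genes, in order")
    TRUE
})

#' @describeIn Signature the retained genes
#' @param x a \code{Signature}
#' @export
signatureGenes <- function(x) x@genes

setMethod("show", "Signature", function(object) {
    cat("Signature", if (nzchar(object@label)) paste0("'", object@label, "'"),
        ":", length(object@genes), "genes; model BIC",
        format(object@modelBIC, digits = 6), "\n")
    if (length(object@genes))
        cat("  ", paste(utils::head(object@genes, 10L), collapse = ", "),
            if (length(object@genes) > 10L) "..." else "", "\n")
})

#' Fitted risk-scoring pipeline
#'
#' Everything needed to replay the scoring path on new samples: the training
#' per-gene normalization, the iterated PCA loadings with the PC subsets the
#' random forest retained at each round, and the boosted ensemble of
#' 3-tanh-unit networks mapping final PCs to a progression probability.
#'
#' @slot signature the \linkS4class{Signature} scored by the model.
#' @slot geneNorm data.frame (gene, mean, sd) from the training cohort.
#' @slot pcaStack list per iteration: rotation matrix, center, selected PCs.
#' @slot forestSpec list(nTrees, cutoff, importance, seed).
#' @slot ensemble list of weak learners (tanh-hidden-layer weights + step).
#' @slot intercept initial log-odds F0 of the boosted model.
#' @slot learningRate boosting learning rate.
#' @slot cvSpec list(folds, seed) of the cross-validation design.
#' @slot oof data.frame (sample_id, probability) of out-of-fold predictions.
#' @slot trainingAucOof honest (out-of-fold) training AUC.
#' @export
setClass("RiskModel",
         representation(signature = "Signature", geneNorm = "data.frame",
                        pcaStack = "list", forestSpec = "list",
                        ensemble = "list", intercept = "numeric",
                        learningRate = "numeric", cvSpec = "list",
                        oof = "data.frame", trainingAucOof = "numeric"))

setMethod("show", "RiskModel", function(object) {
    dims <- vapply(object@pcaStack,
                   function(s) length(s$selected), integer(1))
    cat("RiskModel on", length(object@signature@genes), "signature genes\n")
    cat("  PCA/RF rounds:", length(object@pcaStack),
        "| retained dims:", paste(dims, collapse = " -> "), "\n")
    cat("  boosted ensemble:", length(object@ensemble),
        "tanh nets | learning rate", object@learningRate, "\n")
    cat("  out-of-fold training AUC:",
        format(object@trainingAucOof, digits = 4), "\n")
})

#' Synthetic cohort bundle
#'
#' Output of \code{\link{simulateCohort}}: an expression + clinical
#' experiment, a matching shRNA screen, the identities of the planted genes
#' and the per-sample latent risk factor that drives expression, progression
#' and survival simultaneously.
#'
#' @slot experiment \linkS4class{PgsExperiment} (raw scale, clinical in colData).
#' @slot screen \linkS4class{ShrnaScreen}.
#' @slot plantedGenes gene ids carrying the planted signal.
#' @slot latentRisk named per-sample latent risk factor.
#' @slot config the generating configuration.
#' @export
setClass("SyntheticCohort",
         representation(experiment = "PgsExperiment", screen = "ShrnaScreen",
                        plantedGenes = "character", latentRisk = "numeric",
                        config = "list"))

setValidity("SyntheticCohort", function(object) {
    msg <- character()
    if (!all(object@plantedGenes %in% rownames(object@experiment)))
        msg <- c(msg, "plantedGenes must be a subset of expression gene ids")
    if (!identical(names(object@latentRisk), colnames(object@experiment)))
        msg <- c(msg, "latentRisk names must equal sample ids")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort:", nrow(object@experiment), "genes x",
        ncol(object@experiment), "samples;",
        length(object@plantedGenes), "planted genes\n")
})

#' Candidate gene pool
#'
#' The primary candidate pool: genes ranked by the ubiquity statistic, cut at
#' a percentile, optionally refined by BIC over several pool sizes.
#'
#' @slot genes pool genes in descending ubiquity order.
#' @slot ubiquityStatistic full per-gene statistic (all genes, ranked).
#' @slot poolSize number of genes in the pool.
#' @slot bicTrace data.frame (pool_size, bic) when BIC refinement was run.
#' @export
setClass("CandidatePool",
         representation(genes = "character", ubiquityStatistic = "numeric",
                        poolSize = "integer", bicTrace = "data.frame"))

setMethod("show", "CandidatePool", function(object) {
    cat("CandidatePool:", object@poolSize, "genes")
    if (nrow(object@bicTrace))
        cat(" (BIC-refined over sizes ",
            paste(object@bicTrace$pool_size, collapse = ", "), ")", sep = "")
    cat("\n")
})
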