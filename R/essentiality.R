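#' Gene-level mean shRNA log2 fold change
#'
#' Two-stage average matching the screen's preprocessing: mean over the
#' shRNAs targeting the gene within each cell line, then mean over cell
#' lines.
#'
#' @param screen an \linkS4class{ShrnaScreen}.
#' @param gene gene symbol.
#' @return Mean log2 FC, or \code{NA} if the gene is absent from the screen
#'   (absent genes are excluded from the analysis, never treated as 0).
#' @export
geneMeanFC <- function(screen, gene) {
    r <- screenRecords(screen)
    r <- r[r$gene == gene, , drop = FALSE]
    if (!nrow(r)) return(NA_real_)
    perLine <- tapply(r$log2_fc, r$cell_line, mean)
    mean(perLine)
}

#' One-tailed one-sample depletion t-test for a single shRNA
#'
#' Tests H0: mean log2 FC = 0 against H1: mean < 0 across the cell lines
#' measuring the shRNA.
#'
#' @param fcs numeric log2 fold changes of one shRNA across cell lines.
#' @return Lower-tail p-value, or \code{NA} (with a warning) when fewer than
#'   2 finite values or zero variance make the test undefined.
#' @export
shrnaDepletionTest <- function(fcs) {
    fcs <- fcs[is.finite(fcs)]
    if (length(fcs) < 2L || stats::sd(fcs) == 0) {
        warning("depletion test undefined (n < 2 or zero variance); skipped")
        return(NA_real_)
    }
    stats::t.test(fcs, mu = 0, alternative = "less")$p.value
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values via chi-square = -2 * sum(log p) on 2k
#' degrees of freedom. A single p-value combines to itself; p = 0 is clamped
#' to the smallest positive double with a warning.
#'
#' @param pvalues numeric p-values in (0, 1].
#' @return list(chi2, df, p).
#' @export
fisherCombine <- function(pvalues) {
    pvalues <- pvalues[!is.na(pvalues)]
    if (!length(pvalues)) stop("no p-values to combine")
    if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
    if (any(pvalues == 0)) {
        warning("p-value of 0 clamped to the smallest positive double")
        pvalues[pvalues == 0] <- .Machine$double.xmin
    }
    chi2 <- -2 * sum(log(pvalues))
    df <- 2L * length(pvalues)
    list(chi2 = chi2, df = df,
         p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values controlling the false discovery rate.
#'
#' @param pvalues numeric p-values.
#' @return q-values in the input order.
#' @export
bhFdr <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' Call survival genes from an shRNA depletion screen
#'
#' For each candidate gene: the two-stage mean log2 FC; a one-tailed
#' one-sample t-test per shRNA across cell lines (shRNAs measured in < 2
#' cell lines contribute to the mean but are skipped in the combination);
#' Fisher's combined probability over the gene's shRNA tests; and BH-FDR
#' across the candidate genes. The selection rule is mean FC < 0 among
#' measured genes -- the Fisher/FDR columns are reported as confirmation of
#' significance, not as the filter; passing \code{strictFdr} additionally
#' requires q below that level. Genes absent from the screen are flagged
#' \code{measured = FALSE} and excluded.
#'
#' @param screen an \linkS4class{ShrnaScreen}.
#' @param candidateGenes non-empty character vector of genes to evaluate.
#' @param cellLines optional subset of cell lines to use.
#' @param strictFdr optional q-value level to require for the call.
#' @return data.frame (gene, measured, mean_fc, n_shrnas, fisher_chi2,
#'   fisher_df, combined_p, fdr_q, is_survival_gene).
#' @export
callSurvivalGenes <- function(screen, candidateGenes, cellLines = NULL,
                              strictFdr = NULL) {
    if (!length(candidateGenes)) stop("empty candidate gene list")
    r <- screenRecords(screen)
    if (!is.null(cellLines)) r <- r[r$cell_line %in% cellLines, , drop = FALSE]
    r <- r[r$gene %in% candidateGenes, , drop = FALSE]

    res <- lapply(candidateGenes, function(g) {
        rg <- r[r$gene == g, , drop = FALSE]
        if (!nrow(rg))
            return(data.frame(gene = g, measured = FALSE, mean_fc = NA_real_,
                              n_shrnas = 0L, fisher_chi2 = NA_real_,
                              fisher_df = NA_integer_, combined_p = NA_real_))
        perLine <- tapply(rg$log2_fc, rg$cell_line, mean)
        meanFc <- mean(perLine)
        ps <- vapply(split(rg$log2_fc, rg$shrna_id), function(fcs) {
            fcs <- fcs[is.finite(fcs)]
            if (length(fcs) < 2L || stats::sd(fcs) == 0) return(NA_real_)
            stats::t.test(fcs, mu = 0, alternative = "less")$p.value
        }, numeric(1))
        ps <- ps[!is.na(ps)]
        if (length(ps)) {
            fc <- fisherCombine(ps)
            data.frame(gene = g, measured = TRUE, mean_fc = meanFc,
                       n_shrnas = length(ps), fisher_chi2 = fc$chi2,
                       fisher_df = fc$df, combined_p = fc$p)
        } else {
            data.frame(gene = g, measured = TRUE, mean_fc = meanFc,
                       n_shrnas = 0L, fisher_chi2 = NA_real_,
                       fisher_df = NA_integer_, combined_p = NA_real_)
        }
    })
    out <- do.call(rbind, res)
    out$fdr_q <- NA_real_
    ok <- !is.na(out$combined_p)
    out$fdr_q[ok] <- bhFdr(out$combined_p[ok])
    out$is_survival_gene <- out$measured & !is.na(out$mean_fc) &
        out$mean_fc < 0
    if (!is.null(strictFdr))
        out$is_survival_gene <- out$is_survival_gene & !is.na(out$fdr_q) &
            out$fdr_q < strictFdr
    attr(out, "fdrMethod") <- "BH"
    attr(out, "selectionRule") <- if (is.null(strictFdr)) "mean_fc < 0"
        else sprintf("mean_fc < 0 & q < %g", strictFdr)
    rownames(out) <- NULL
    out
}
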