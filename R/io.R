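#' Read a genes x samples expression TSV
#'
#' Expects a tab-separated file with a header row of sample ids, gene symbols
#' in the first column, and numeric values elsewhere. Gene symbols are
#' trimmed of whitespace and matched case-sensitively downstream.
#'
#' @param path file path.
#' @param scale normalization state to record on the result (default raw).
#' @return A \linkS4class{PgsExperiment}.
#' @seealso \code{\link{writeExpression}}
#' @export
readExpression <- function(path, scale = c("raw", "log", "zscore")) {
    scale <- match.arg(scale)
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    if (length(unique(nf)) != 1L) {
        bad <- which(nf != nf[1L])[1L]
        stop("ragged expression file '", path, "': line ", bad, " has ",
             nf[bad], " fields, expected ", nf[1L])
    }
    df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    genes <- trimws(df[[1L]])
    dup <- unique(genes[duplicated(genes)])
    if (length(dup))
        stop("duplicate gene symbol(s) in '", path, "': ",
             paste(dup, collapse = ", "))
    vals <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    bad <- which(is.na(num) & !(vals %in% c("", "NA")), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-numeric cell in '", path, "' at line ", bad[1L, 1L] + 1L,
             " (gene ", genes[bad[1L, 1L]], "): '",
             vals[bad[1L, 1L], bad[1L, 2L]], "'")
    dimnames(num) <- list(genes, colnames(vals))
    PgsExperiment(num, scale = scale)
}

#' Write a genes x samples expression TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces them exactly.
#'
#' @param x a \linkS4class{PgsExperiment} or a numeric matrix with dimnames.
#' @param path output path.
#' @export
writeExpression <- function(x, path) {
    m <- if (methods::is(x, "PgsExperiment")) exprValues(x) else x
    chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    chr[is.na(m)] <- "NA"
    out <- cbind(gene = rownames(m), chr)
    colnames(out) <- c("gene", colnames(m))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

# canonical clinical columns and their parsers
.clinicalNumeric <- c("progressed", "dfs_months", "dfs_event", "os_months",
                      "os_event", "age", "treated", "hypoxia_score")
.clinicalCharacter <- c("gender", "stage", "smoking", "response")

#' Read a per-sample clinical table
#'
#' Tab-separated with a \code{sample_id} column; recognized columns
#' (\code{progressed}, \code{dfs_months}, \code{dfs_event}, \code{os_months},
#' \code{os_event}, \code{age}, \code{gender}, \code{stage}, \code{smoking},
#' \code{treated}, \code{response}, \code{hypoxia_score}) are validated;
#' unknown columns are preserved untouched. Empty cells are missing values,
#' never zero.
#'
#' @param path file path.
#' @return data.frame keyed by \code{sample_id}.
#' @export
readClinical <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
    if (!"sample_id" %in% names(df))
        stop("clinical file '", path, "' lacks a sample_id column")
    df$sample_id <- trimws(as.character(df$sample_id))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in '", path, "'")
    for (col in intersect(.clinicalNumeric, names(df))) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        if (any(is.na(v) & !is.na(df[[col]])))
            stop("non-numeric value in clinical column '", col, "'")
        df[[col]] <- v
    }
    for (col in intersect(c("progressed", "dfs_event", "os_event", "treated"),
                          names(df))) {
        v <- df[[col]]
        if (any(!v[!is.na(v)] %in% c(0, 1)))
            stop("clinical column '", col, "' must be 0/1")
    }
    for (col in intersect(c("dfs_months", "os_months"), names(df))) {
        v <- df[[col]]
        if (any(v[!is.na(v)] < 0))
            stop("clinical column '", col, "' has negative times")
    }
    rownames(df) <- df$sample_id
    df
}

#' Write a clinical table as TSV
#' @param clinical data.frame with a \code{sample_id} column.
#' @param path output path.
#' @export
writeClinical <- function(clinical, path) {
    utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    invisible(path)
}

#' Read an shRNA screen CSV
#'
#' Comma-separated with columns \code{shrna_id}, \code{gene},
#' \code{cell_line}, \code{log2_fc}. An shRNA listed under two genes is an
#' integrity error.
#'
#' @param path file path.
#' @return An \linkS4class{ShrnaScreen}.
#' @export
readScreen <- function(path) {
    df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
    need <- c("shrna_id", "gene", "cell_line", "log2_fc")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("screen file '", path, "' lacks column(s): ",
             paste(miss, collapse = ", "))
    df$log2_fc <- suppressWarnings(as.numeric(df$log2_fc))
    if (any(is.na(df$log2_fc)))
        stop("missing or non-numeric log2_fc in '", path, "'")
    ShrnaScreen(df[, need])
}

#' Write an shRNA screen as CSV
#' @param screen an \linkS4class{ShrnaScreen}.
#' @param path output path.
#' @export
writeScreen <- function(screen, path) {
    utils::write.csv(screenRecords(screen), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' Log2-transform raw expression
#'
#' Raw RSEM-like values are mapped to \code{log2(x + 1)}; log-scale input is
#' returned unchanged.
#'
#' @param x a \linkS4class{PgsExperiment} on raw or log scale.
#' @return A \code{PgsExperiment} on log scale.
#' @export
logTransform <- function(x) {
    sc <- exprScale(x)
    if (sc == "log") return(x)
    if (sc != "raw") stop("logTransform expects raw or log scale")
    out <- x
    assay(out, "exprs") <- log2(exprValues(x) + 1)
    metadata(out)$scale <- "log"
    out
}

#' Per-gene z-score normalization
#'
#' Raw input is first \code{log2(x + 1)}-transformed; each gene row is then
#' centered and scaled using the sample standard deviation (n - 1). Constant
#' genes map to all-zero rows and are flagged in
#' \code{metadata(x)$constantGenes} with a warning. The per-gene (mean, sd)
#' is stored in \code{metadata(x)$geneNorm} so the identical transform can be
#' replayed on new samples via \code{\link{applyGeneNorm}}.
#'
#' Idempotent: z-scoring an already z-scored matrix is the identity (up to
#' numerical tolerance).
#'
#' @param x a \linkS4class{PgsExperiment}.
#' @return A \code{PgsExperiment} with scale \code{"zscore"}.
#' @export
zscoreByGene <- function(x) {
    if (nrow(x) == 0L || ncol(x) == 0L) stop("empty expression matrix")
    if (exprScale(x) == "raw") x <- logTransform(x)
    v <- exprValues(x)
    m <- rowMeans(v)
    s <- apply(v, 1L, stats::sd)
    const <- rownames(v)[s == 0 | !is.finite(s)]
    if (length(const))
        warning("constant gene row(s) mapped to zeros: ",
                paste(utils::head(const, 5L), collapse = ", "),
                if (length(const) > 5L) " ..." else "")
    z <- (v - m) / ifelse(s > 0, s, 1)
    z[s == 0 | !is.finite(s), ] <- 0
    out <- x
    assay(out, "exprs") <- z
    metadata(out)$scale <- "zscore"
    metadata(out)$constantGenes <- const
    metadata(out)$geneNorm <- data.frame(gene = rownames(v), mean = m, sd = s,
                                         row.names = rownames(v))
    methods::validObject(out)
    out
}

#' Replay a stored per-gene normalization on new samples
#'
#' Applies the (mean, sd) recorded by \code{\link{zscoreByGene}} on a
#' training cohort to another matrix from the same platform (raw input is
#' log2(x+1)-transformed first). Genes with stored sd = 0 map to zeros.
#'
#' @param x a \linkS4class{PgsExperiment} (raw or log scale).
#' @param norm data.frame (gene, mean, sd) as stored by
#'   \code{\link{zscoreByGene}}.
#' @return A \code{PgsExperiment} with scale \code{"zscore"}, restricted to
#'   the genes present in \code{norm}.
#' @export
applyGeneNorm <- function(x, norm) {
    if (exprScale(x) == "raw") x <- logTransform(x)
    genes <- intersect(norm$gene, rownames(x))
    if (!length(genes)) stop("no overlap between norm genes and matrix genes")
    v <- exprValues(x)[genes, , drop = FALSE]
    n <- norm[match(genes, norm$gene), ]
    z <- (v - n$mean) / ifelse(n$sd > 0, n$sd, 1)
    z[n$sd == 0, ] <- 0
    cd <- as.data.frame(colData(x))
    out <- PgsExperiment(z, clinical = if (ncol(cd)) cd else NULL,
                         scale = "log")
    # replayed z-scores need not have mean 0 / sd 1 in the new cohort
    metadata(out)$replayedNorm <- TRUE
    metadata(out)$scale <- "zscore"
    metadata(out)$geneNorm <- n
    out
}
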