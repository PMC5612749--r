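#' Read a gene x sample expression table
#'
#' Reads a tab-delimited table (first column: gene identifier; remaining
#' columns: one per sample, RSEM-style nonnegative normalized values) and
#' returns a `RangedSummarizedExperiment` whose rows are restricted to genes
#' present in the annotation and sorted in 5'->3' chromosomal order.
#' Expression values are used untransformed by default; set
#' `log2transform = TRUE` for `log2(x + 1)`.
#'
#' @param path tab-delimited file path.
#' @param annotation ranked `GRanges` from [orderGenes()] /
#'   [readGeneAnnotation()].
#' @param log2transform apply `log2(x + 1)` to the values.
#' @return `RangedSummarizedExperiment` with assay `"expression"`.
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#' @importFrom data.table fread
#' @export
readExpressionTable <- function(path, annotation, log2transform = FALSE) {
    tab <- data.table::fread(path, sep = "\t", header = TRUE,
                             data.table = FALSE)
    if (ncol(tab) < 2L)
        stop("expression table needs a gene_id column plus >= 1 sample")
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
        stop("duplicated gene_id in expression table: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    vals <- tab[, -1L, drop = FALSE]
    for (j in seq_along(vals)) {
        if (!is.numeric(vals[[j]])) {
            bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                         !is.na(vals[[j]]))[1L]
            stop("non-numeric expression value at row '", ids[bad %||% 1L],
                 "', column '", names(vals)[j], "'")
        }
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
    if (any(!is.finite(m)))
        stop("expression values must be finite")
    if (any(m < 0))
        stop("expression values must be nonnegative")
    if (log2transform) m <- log2(m + 1)
    codExperiment(m, annotation)
}

#' Assemble an expression experiment from a matrix and an annotation
#'
#' Restricts the matrix to annotated genes (warning reports how many rows
#' were dropped), orders rows 5'->3' per chromosome and attaches the gene
#' ranges.
#'
#' @param values numeric matrix, rownames = gene identifiers.
#' @param annotation ranked `GRanges` with `gene_id` (re-ranked if needed).
#' @return `RangedSummarizedExperiment` with assay `"expression"`.
#' @export
codExperiment <- function(values, annotation) {
    if (is.null(rownames(values)))
        stop("expression matrix must have gene identifiers as rownames")
    if (is.null(mcols(annotation)$rank))
        annotation <- orderGenes(annotation)
    keep <- rownames(values) %in% mcols(annotation)$gene_id
    if (any(!keep))
        warning(sum(!keep), " gene(s) absent from the annotation dropped")
    values <- values[keep, , drop = FALSE]
    ann <- annotation[match(rownames(values), mcols(annotation)$gene_id)]
    o <- order(as.character(seqnames(ann)), mcols(ann)$rank)
    SummarizedExperiment(assays = list(expression = values[o, , drop = FALSE]),
                         rowRanges = ann[o])
}
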