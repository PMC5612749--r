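#' Build per-chromosome coexpression matrices
#'
#' For each chromosome, computes the Pearson correlation coefficient between
#' the expression profiles of every pair of genes across all samples, with
#' genes in 5'->3' chromosomal order. Genes with zero variance across
#' samples are flagged invalid: their ranks are preserved (so domain
#' coordinates never shift) but their entries are `NA` and they are excluded
#' from every average.
#'
#' @param expr `RangedSummarizedExperiment` from [readExpressionTable()] /
#'   [codExperiment()], or a plain numeric matrix (then `annotation` is
#'   required).
#' @param annotation ranked `GRanges`; only needed when `expr` is a matrix.
#' @param chromosomes restrict to these chromosomes (default: all present).
#' @return named list of [CoexpressionMatrix-class], one per chromosome.
#' @export
buildCoexpressionMatrix <- function(expr, annotation = NULL,
                                    chromosomes = NULL) {
    if (is.matrix(expr)) {
        if (is.null(annotation))
            stop("annotation is required when expr is a bare matrix")
        expr <- codExperiment(expr, annotation)
    }
    values <- assay(expr, "expression")
    if (ncol(values) < 3L)
        stop("at least 3 samples are required to estimate correlations")
    ann <- rowRanges(expr)
    chr <- as.character(seqnames(ann))
    keep <- unique(chr)
    if (!is.null(chromosomes)) keep <- intersect(keep, chromosomes)
    out <- lapply(keep, function(cc) {
        idx <- which(chr == cc)
        idx <- idx[order(mcols(ann)$rank[idx])]
        m <- values[idx, , drop = FALSE]
        .coexpression_from_values(m, cc)
    })
    names(out) <- keep
    out
}

#' Construct a CoexpressionMatrix from a correlation matrix
#'
#' Wraps an already-computed symmetric correlation matrix (e.g. a designed
#' toy example) in the container consumed by the COD caller. Genes whose
#' row is all `NA` are flagged invalid.
#'
#' @param corr symmetric matrix of Pearson coefficients, `NA` allowed.
#' @param chromosome chromosome name.
#' @param geneIds gene identifiers (default `g1..gn`).
#' @return a [CoexpressionMatrix-class].
#' @export
coexpressionMatrix <- function(corr, chromosome = "chrS", geneIds = NULL) {
    corr <- as.matrix(corr)
    n <- nrow(corr)
    ids <- geneIds %||% rownames(corr) %||% paste0("g", seq_len(n))
    valid <- rowSums(is.finite(corr)) > 0
    new("CoexpressionMatrix", chrom = chromosome, corr = unname(corr),
        geneIds = ids, valid = valid)
}

# Correlation matrix from a genes x samples block, rank order preserved.
.coexpression_from_values <- function(m, chromosome) {
    n <- nrow(m)
    sds <- apply(m, 1L, stats::sd)
    valid <- is.finite(sds) & sds > 0
    corr <- matrix(NA_real_, n, n,
                   dimnames = list(rownames(m), rownames(m)))
    if (sum(valid) >= 2L)
        corr[valid, valid] <- stats::cor(t(m[valid, , drop = FALSE]))
    diag(corr)[valid] <- 1
    new("CoexpressionMatrix", chrom = chromosome, corr = corr,
        geneIds = rownames(m) %||% as.character(seq_len(n)), valid = valid)
}

#' Average pairwise coexpression over gene sets
#'
#' With one set, averages the correlation over all unordered within-set gene
#' pairs (self-pairs excluded); with two sets, over all cross pairs. Only
#' defined entries enter the mean; if every relevant entry is undefined the
#' average is `NA` with a warning, never silently 0.
#'
#' @param C a [CoexpressionMatrix-class].
#' @param setA integer vector of gene ranks.
#' @param setB optional second set of ranks.
#' @return list with `average` (mean coefficient) and `nPairs` (defined
#'   pairs used).
#' @export
averagePairwiseCoexpression <- function(C, setA, setB = NULL) {
    corr <- corrMatrix(C)
    if (!length(setA)) stop("setA must be non-empty")
    if (is.null(setB)) {
        if (length(setA) < 2L)
            return(list(average = NA_real_, nPairs = 0L))
        block <- corr[setA, setA, drop = FALSE]
        vals <- block[upper.tri(block)]
    } else {
        if (!length(setB)) stop("setB must be non-empty")
        block <- corr[setA, setB, drop = FALSE]
        self <- outer(setA, setB, "==")
        vals <- block[!self]
    }
    defined <- vals[is.finite(vals)]
    if (!length(defined)) {
        warning("all requested coexpression entries are undefined")
        return(list(average = NA_real_, nPairs = 0L))
    }
    list(average = mean(defined), nPairs = length(defined))
}
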