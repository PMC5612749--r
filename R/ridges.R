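#' Call RIDGEs (Regions of Increased Gene Expression)
#'
#' Implements the moving-median rule: per gene, the mean expression across
#' samples is summarized; for each gene `i` the median of a moving window
#' of `window` genes (`(window - 1) / 2` up- and downstream, truncated at
#' chromosome ends) is computed; maximal runs of at least `minRun`
#' consecutive genes whose moving median is strictly greater than `factor`
#' times the genome-wide median expression are emitted as RIDGEs. The
#' genomic median is computed over all genes genome-wide, not per
#' chromosome.
#'
#' @param expr `RangedSummarizedExperiment` of expression.
#' @param window moving-window size in genes (default 39: 19 up + 19 down).
#' @param factor multiplier on the genomic median (default 2).
#' @param minRun minimum consecutive qualifying genes (default 10).
#' @return named list of [DomainSet-class] objects of kind `"RIDGE"`, one
#'   per chromosome with at least one RIDGE (chromosomes with fewer genes
#'   than `minRun` never qualify).
#' @export
callRidges <- function(expr, window = 39L, factor = 2, minRun = 10L) {
    window <- as.integer(window)
    half <- (window - 1L) %/% 2L
    values <- assay(expr, "expression")
    geneMean <- rowMeans(values)
    genomicMedian <- stats::median(geneMean)
    ann <- rowRanges(expr)
    chr <- as.character(seqnames(ann))
    out <- list()
    for (cc in unique(chr)) {
        idx <- which(chr == cc)
        idx <- idx[order(mcols(ann)$rank[idx])]
        mm <- moving_median(geneMean[idx], half)
        qual <- mm > factor * genomicMedian
        runs <- true_runs(qual)
        runs <- runs[runs$length >= minRun, , drop = FALSE]
        if (!nrow(runs)) next
        a <- ann[idx]
        gr <- GRanges(cc, IRanges(start(a)[runs$first], end(a)[runs$last]))
        mcols(gr)$firstRank <- mcols(a)$rank[runs$first]
        mcols(gr)$lastRank <- mcols(a)$rank[runs$last]
        mcols(gr)$nGenes <- runs$length
        mcols(gr)$geneIds <- CharacterList(lapply(seq_len(nrow(runs)),
            function(k) mcols(a)$gene_id[runs$first[k]:runs$last[k]]))
        mcols(gr)$meanExpression <- vapply(seq_len(nrow(runs)), function(k)
            mean(geneMean[idx][runs$first[k]:runs$last[k]]), numeric(1L))
        out[[cc]] <- domainSet(gr, kind = "RIDGE")
    }
    out
}

# Median over a window of +-half genes, truncated at the ends.
moving_median <- function(x, half) {
    n <- length(x)
    vapply(seq_len(n), function(i)
        stats::median(x[max(1L, i - half):min(n, i + half)]), numeric(1L))
}
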