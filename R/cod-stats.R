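#' Intra- and inter-COD coexpression summary
#'
#' Computes, for one chromosome: the average intra-domain coexpression of
#' every COD; one record per unordered COD pair with its average inter-COD
#' coexpression, midpoint distance and significance classification
#' (`positive` when the average is >= `sigThreshold`, `negative` when
#' <= -`sigThreshold`, else `neutral`; 0.2 is the published cutoff for a
#' strongly significant pair); and the three pairwise-coefficient
#' populations — intra-COD, inter-COD and rest (pairs with at least one
#' gene outside any COD) — for distribution comparisons.
#'
#' @param cods [DomainSet-class] of kind COD with rank metadata.
#' @param C matching [CoexpressionMatrix-class].
#' @param sigThreshold absolute classification cutoff (default 0.2).
#' @param distance `"midpoint"` (default) or `"edge"` — how inter-COD
#'   distance is measured, in bp.
#' @return list with `intra` (data.frame: domain, n_genes,
#'   avg_intra_coexpression), `pairs` (data.frame: cod_a, cod_b,
#'   avg_inter_coexpression, distance, classification) and `populations`
#'   (list of numeric vectors `intra`, `inter`, `rest`).
#' @export
codCoexpressionSummary <- function(cods, C, sigThreshold = 0.2,
                                   distance = c("midpoint", "edge")) {
    distance <- match.arg(distance)
    gr <- domainRanges(cods)
    nd <- length(gr)
    fr <- mcols(gr)$firstRank; lr <- mcols(gr)$lastRank
    if (nd && (is.null(fr) || is.null(lr)))
        stop("cods must carry firstRank/lastRank metadata")
    intra <- data.frame(
        domain = seq_len(nd),
        n_genes = if (nd) lr - fr + 1L else integer(),
        avg_intra_coexpression = vapply(seq_len(nd), function(k)
            averagePairwiseCoexpression(C, fr[k]:lr[k])$average, numeric(1L)))
    pairs <- .cod_pair_stats(gr, C, sigThreshold, distance)
    list(intra = intra, pairs = pairs,
         populations = .pair_populations(gr, C))
}

.cod_pair_stats <- function(gr, C, sigThreshold, distance) {
    nd <- length(gr)
    out <- data.frame(cod_a = integer(), cod_b = integer(),
                      avg_inter_coexpression = numeric(),
                      distance = numeric(), classification = character())
    if (nd < 2L) return(out)
    fr <- mcols(gr)$firstRank; lr <- mcols(gr)$lastRank
    mid <- (start(gr) + end(gr)) / 2
    idx <- utils::combn(nd, 2L)
    for (k in seq_len(ncol(idx))) {
        a <- idx[1L, k]; b <- idx[2L, k]
        avg <- averagePairwiseCoexpression(C, fr[a]:lr[a], fr[b]:lr[b])$average
        d <- if (distance == "midpoint") abs(mid[a] - mid[b])
             else max(0, max(start(gr)[a], start(gr)[b]) -
                         min(end(gr)[a], end(gr)[b]))
        cls <- if (is.na(avg)) NA_character_
               else if (avg >= sigThreshold) "positive"
               else if (avg <= -sigThreshold) "negative" else "neutral"
        out[k, c("cod_a", "cod_b")] <- c(a, b)
        out$avg_inter_coexpression[k] <- avg
        out$distance[k] <- d
        out$classification[k] <- cls
    }
    out
}

# Partition all upper-triangle coefficients into intra / inter / rest.
.pair_populations <- function(gr, C, membership = NULL) {
    corr <- corrMatrix(C)
    if (is.null(membership))
        membership <- .rank_membership(gr, nrow(corr))
    .population_split(corr, membership)
}

# Split the upper triangle of a symmetric pair-value matrix by domain
# membership: both genes in the same domain (intra), in two different
# domains (inter), or at least one gene outside every domain (rest).
.population_split <- function(mat, membership) {
    n <- nrow(mat)
    memI <- matrix(membership, n, n)
    memJ <- t(memI)
    up <- upper.tri(mat)
    both <- !is.na(memI) & !is.na(memJ)
    intra <- mat[up & both & memI == memJ]
    inter <- mat[up & both & memI != memJ]
    rest <- mat[up & !both]
    list(intra = intra[is.finite(intra)], inter = inter[is.finite(inter)],
         rest = rest[is.finite(rest)])
}

#' Distance dependence of inter-COD coexpression
#'
#' Orders COD pairs by genomic distance and splits them into `nBins`
#' equal-count groups (counts differ by at most one; ties resolved by
#' stable sort order), reporting per-group mean distance and mean inter-COD
#' coexpression.
#'
#' @param pairs data.frame from [codCoexpressionSummary()]'s `pairs`
#'   element (needs columns `distance` and `avg_inter_coexpression`).
#' @param nBins number of groups (default 50); reduced to the pair count
#'   when fewer pairs are available.
#' @return data.frame with `bin`, `n_pairs`, `mean_distance`,
#'   `mean_coexpression`.
#' @export
distanceBinnedCoexpression <- function(pairs, nBins = 50L) {
    n <- nrow(pairs)
    if (!n)
        return(data.frame(bin = integer(), n_pairs = integer(),
                          mean_distance = numeric(),
                          mean_coexpression = numeric()))
    nBins <- min(as.integer(nBins), n)
    o <- order(pairs$distance)  # stable
    bin <- ceiling(seq_len(n) * nBins / n)
    data.frame(
        bin = seq_len(nBins),
        n_pairs = as.integer(table(bin)),
        mean_distance = as.numeric(
            tapply(pairs$distance[o], bin, mean)),
        mean_coexpression = as.numeric(
            tapply(pairs$avg_inter_coexpression[o], bin, mean)))
}

#' Randomize domains by coordinate inversion
#'
#' Maps every domain `[s, e)` to `[L - e, L - s)` on a chromosome of length
#' `L` — flipping the chromosome 5'->3' to 3'->5'. Domain sizes, the
#' multiset of inter-domain gaps, the genomic context and gene proximity
#' are preserved exactly while the gene composition of each domain changes;
#' applying the operation twice returns the original coordinates. Gene
#' composition is reassigned as the genes whose midpoints fall inside the
#' inverted interval (when an annotation is supplied).
#'
#' @param domains a [DomainSet-class].
#' @param chromLength chromosome length in bp; defaults to the largest gene
#'   end in `annotation`, else the largest domain end. Any `L` at least
#'   that large gives an isometric inversion.
#' @param annotation optional ranked `GRanges` used to reassign genes.
#' @return a [DomainSet-class] of kind `"random"`.
#' @export
invertDomains <- function(domains, chromLength = NULL, annotation = NULL) {
    gr <- domainRanges(domains)
    L <- chromLength %||% (if (!is.null(annotation)) max(end(annotation))
                           else max(end(gr)))
    if (L < max(end(gr))) stop("chromLength smaller than the largest domain end")
    inv <- GRanges(as.character(seqnames(gr)),
                   IRanges(L - end(gr) + 1L, L - start(gr) + 1L))
    inv <- .reassign_genes(inv, annotation)
    domainSet(inv, kind = "random")
}

#' Randomize domains by border shifting
#'
#' Moves every domain border by `shift` bp upstream or downstream. Domain
#' sizes are preserved except where a shifted domain is clipped at a
#' chromosome end; domains pushed entirely off the chromosome are dropped
#' with a warning.
#'
#' @param domains a [DomainSet-class].
#' @param shift shift magnitude in bp (default 100,000).
#' @param direction `"downstream"` (+) or `"upstream"` (-).
#' @param chromLength chromosome length for clipping (default: largest
#'   domain or gene end).
#' @param annotation optional ranked `GRanges` used to reassign genes.
#' @return a [DomainSet-class] of kind `"random"`.
#' @export
shiftDomains <- function(domains, shift = 1e5,
                         direction = c("downstream", "upstream"),
                         chromLength = NULL, annotation = NULL) {
    direction <- match.arg(direction)
    gr <- domainRanges(domains)
    L <- chromLength %||% (if (!is.null(annotation)) max(end(annotation))
                           else max(end(gr)))
    delta <- if (direction == "downstream") shift else -shift
    s <- start(gr) + delta; e <- end(gr) + delta
    keep <- e >= 1 & s <= L
    if (any(!keep))
        warning(sum(!keep), " domain(s) shifted entirely off the chromosome",
                " were dropped")
    s <- pmax(s[keep], 1); e <- pmin(e[keep], L)
    out <- GRanges(as.character(seqnames(gr))[keep], IRanges(s, e))
    out <- .reassign_genes(out, annotation)
    domainSet(out, kind = "random")
}

.reassign_genes <- function(gr, annotation) {
    if (is.null(annotation)) return(gr)
    ann <- annotation[.strip_chr(seqnames(annotation)) %in%
                      .strip_chr(seqnames(gr))]
    mid <- .mid0(ann)
    o <- order(start(gr), end(gr))
    gr <- gr[o]
    ids <- vector("list", length(gr))
    fr <- lr <- rep(NA_integer_, length(gr))
    for (k in seq_along(gr)) {
        inside <- which(mid >= start(gr)[k] - 1 & mid < end(gr)[k])
        ids[[k]] <- mcols(ann)$gene_id[inside]
        if (length(inside)) {
            fr[k] <- min(mcols(ann)$rank[inside])
            lr[k] <- max(mcols(ann)$rank[inside])
        }
    }
    mcols(gr)$firstRank <- fr
    mcols(gr)$lastRank <- lr
    mcols(gr)$nGenes <- lengths(ids)
    mcols(gr)$geneIds <- CharacterList(ids)
    gr
}

#' Compare labeled coefficient distributions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test for every pair of
#' groups, Bonferroni-adjusted (`p_adjusted = min(1, p * nTests)`). Small
#' untied samples use the exact U distribution; larger ones the normal
#' approximation with tie correction (the `stats::wilcox.test` switch).
#' Identical constant groups give `p = 1`.
#'
#' @param groups named list of numeric vectors.
#' @param nTests Bonferroni multiplier (default: the number of pairwise
#'   comparisons performed).
#' @return data.frame with `group_a`, `group_b`, `statistic`, `p_value`,
#'   `p_adjusted`.
#' @export
compareDistributions <- function(groups, nTests = NULL) {
    stopifnot(is.list(groups), length(groups) >= 2L,
              !is.null(names(groups)))
    idx <- utils::combn(length(groups), 2L)
    nTests <- nTests %||% ncol(idx)
    rows <- lapply(seq_len(ncol(idx)), function(k) {
        a <- idx[1L, k]; b <- idx[2L, k]
        x <- groups[[a]]; y <- groups[[b]]
        if (stats::sd(c(x, y)) == 0) {
            stat <- length(x) * length(y) / 2; p <- 1
        } else {
            wt <- suppressWarnings(stats::wilcox.test(x, y))
            stat <- unname(wt$statistic); p <- wt$p.value
        }
        data.frame(group_a = names(groups)[a], group_b = names(groups)[b],
                   statistic = stat, p_value = p,
                   p_adjusted = min(1, p * nTests))
    })
    do.call(rbind, rows)
}
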