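#' Match domains by length coincidence
#'
#' A domain of set `a` matches when some single domain of set `b` overlaps
#' at least `minLengthFrac` of its length (published cutoff: 80%,
#' inclusive). The relation is not symmetric; call the function both ways
#' for Venn-style summaries.
#'
#' @param a,b [DomainSet-class] objects on the same chromosome.
#' @param minLengthFrac minimum overlap as a fraction of the `a` domain
#'   length (default 0.80).
#' @return list with `matched` (logical per `a` domain), `nMatched`,
#'   `nTotal`, and `pairs` (data.frame `a_idx`, `b_idx`, `overlap_frac` of
#'   the best-overlapping `b` domain per matched `a`).
#' @importFrom GenomicRanges findOverlaps pintersect
#' @importFrom S4Vectors queryHits subjectHits
#' @export
matchDomainsByLength <- function(a, b, minLengthFrac = 0.80) {
    ga <- domainRanges(a); gb <- domainRanges(b)
    matched <- logical(length(ga))
    pairs <- data.frame(a_idx = integer(), b_idx = integer(),
                        overlap_frac = numeric())
    if (length(ga) && length(gb)) {
        hits <- findOverlaps(ga, gb)
        if (length(hits)) {
            ov <- width(pintersect(ga[queryHits(hits)], gb[subjectHits(hits)]))
            frac <- ov / width(ga)[queryHits(hits)]
            ok <- frac >= minLengthFrac
            matched[unique(queryHits(hits)[ok])] <- TRUE
            if (any(ok)) {
                df <- data.frame(a_idx = queryHits(hits)[ok],
                                 b_idx = subjectHits(hits)[ok],
                                 overlap_frac = frac[ok])
                best <- tapply(seq_len(nrow(df)), df$a_idx, function(ii)
                    ii[which.max(df$overlap_frac[ii])])
                pairs <- df[as.integer(best), , drop = FALSE]
                rownames(pairs) <- NULL
            }
        }
    }
    list(matched = matched, nMatched = sum(matched), nTotal = length(ga),
         pairs = pairs)
}

#' Match domain boundaries
#'
#' Every boundary (both end coordinates) of every `a` domain is compared
#' with every boundary of `b`, irrespective of 5'/3' position; a boundary
#' matches when some `b` boundary lies within a tolerance of
#' `boundaryTolFrac` of that `a` domain's size (discrepancy strictly less
#' than the tolerance). Each boundary is matched independently — a single
#' `b` boundary may satisfy several `a` boundaries. With `unit = "bp"` the
#' size is the domain length in bp (COD-versus-TAD comparisons); with
#' `unit = "genes"` it is the domain's gene count and discrepancies are
#' measured in gene ranks (normal-versus-cancer COD comparisons).
#'
#' @param a,b [DomainSet-class] objects.
#' @param boundaryTolFrac tolerance fraction (default 0.10).
#' @param unit `"bp"` or `"genes"`.
#' @return list with `matched` (logical, 2 entries per `a` domain:
#'   start then end), `nMatched`, `nTotal`.
#' @export
matchBoundaries <- function(a, b, boundaryTolFrac = 0.10,
                            unit = c("bp", "genes")) {
    unit <- match.arg(unit)
    ga <- domainRanges(a); gb <- domainRanges(b)
    if (unit == "bp") {
        aBound <- as.numeric(rbind(start(ga), end(ga)))
        bBound <- as.numeric(rbind(start(gb), end(gb)))
        tol <- rep(boundaryTolFrac * width(ga), each = 2L)
    } else {
        fa <- mcols(ga)$firstRank; la <- mcols(ga)$lastRank
        fb <- mcols(gb)$firstRank; lb <- mcols(gb)$lastRank
        if (is.null(fa) || is.null(fb))
            stop("gene-unit boundary matching needs rank metadata")
        aBound <- as.numeric(rbind(fa, la))
        bBound <- as.numeric(rbind(fb, lb))
        tol <- rep(boundaryTolFrac * (la - fa + 1L), each = 2L)
    }
    matched <- vapply(seq_along(aBound), function(k)
        length(bBound) > 0 && any(abs(bBound - aBound[k]) < tol[k]),
        logical(1L))
    list(matched = matched, nMatched = sum(matched),
         nTotal = length(aBound))
}

#' Match domains by gene composition
#'
#' A domain of `a` matches when some domain of `b` contains at least
#' `geneFrac` of its genes (published cutoff: 80%, inclusive).
#'
#' @param a,b [DomainSet-class] objects carrying gene lists.
#' @param geneFrac minimum shared fraction of the `a` domain's genes.
#' @return list with `matched` (logical per `a` domain), `nMatched`,
#'   `nTotal`.
#' @export
matchDomainsByGenes <- function(a, b, geneFrac = 0.80) {
    genesA <- domainGenes(a); genesB <- domainGenes(b)
    matched <- vapply(genesA, function(g) {
        if (!length(g)) return(FALSE)
        any(vapply(genesB, function(h)
            length(intersect(g, h)) >= geneFrac * length(g), logical(1L)))
    }, logical(1L))
    list(matched = matched, nMatched = sum(matched), nTotal = length(genesA))
}

# Midpoint of a range under the 0-based half-open convention.
.mid0 <- function(gr) (start(gr) - 1 + end(gr)) / 2

#' Assign genes to domains by midpoint
#'
#' A gene belongs to a domain iff its midpoint (under the 0-based half-open
#' convention) falls inside the domain interval; a midpoint exactly at the
#' (half-open) domain end is outside. Domains must be non-overlapping, so
#' each gene maps to at most one domain.
#'
#' @param annotation ranked `GRanges` of genes on the domain chromosome.
#' @param domains a [DomainSet-class].
#' @return integer vector, one entry per gene: the domain index, or `NA`
#'   for genes outside every domain.
#' @export
assignGenesToDomains <- function(annotation, domains) {
    gr <- domainRanges(domains)
    if (length(gr) > 1L &&
        any(start(gr)[-1L] <= end(gr)[-length(gr)]))
        stop("domains must be non-overlapping for gene assignment")
    mid <- .mid0(annotation)
    s0 <- start(gr) - 1; e0 <- end(gr)
    out <- rep(NA_integer_, length(annotation))
    for (k in seq_along(gr))
        out[mid >= s0[k] & mid < e0[k]] <- k
    out
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail probability of observing at least `hits` category members in
#' a draw of `setSize` genes from a universe of `universe` genes containing
#' `categorySize` category members (sampling without replacement) — the
#' enrichment test used for housekeeping-gene and RIDGE-gene overlaps.
#'
#' @param hits observed genes in both the set and the category.
#' @param setSize size of the drawn gene set.
#' @param categorySize number of category genes in the universe.
#' @param universe universe size.
#' @return the upper-tail p-value, `P(X >= hits)`.
#' @export
geneSetOverlapTest <- function(hits, setSize, categorySize, universe) {
    if (hits < 0 || setSize < 0 || categorySize < 0 || universe < 1)
        stop("counts must be nonnegative (universe >= 1)")
    if (hits > min(setSize, categorySize) ||
        setSize > universe || categorySize > universe)
        stop("inconsistent counts: hits must be <= min(setSize, categorySize)",
             " and both sizes <= universe")
    stats::phyper(hits - 1, categorySize, universe - categorySize, setSize,
                  lower.tail = FALSE)
}

#' Chi-square test of boundary-coincidence proportions
#'
#' Pearson chi-square test (no continuity correction by default) on the
#' 2x2 table of matched/unmatched boundary counts for real versus
#' randomized domains.
#'
#' @param realMatched,realTotal matched and total boundaries, real domains.
#' @param randomMatched,randomTotal same for randomized domains.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `p_value` and the 2x2 `table`. A table
#'   with a zero margin gives `NA` with a warning.
#' @export
boundaryCoincidenceChi2 <- function(realMatched, realTotal, randomMatched,
                                    randomTotal, correct = FALSE) {
    counts <- c(realMatched, realTotal - realMatched,
                randomMatched, randomTotal - randomMatched)
    if (any(counts < 0)) stop("negative cell count")
    tab <- matrix(counts, nrow = 2L, byrow = TRUE,
                  dimnames = list(c("real", "random"),
                                  c("matched", "unmatched")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warning("zero margin: chi-square statistic undefined")
        return(list(statistic = NA_real_, p_value = NA_real_, table = tab))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(statistic = unname(ct$statistic), p_value = ct$p.value, table = tab)
}

#' Intra- versus inter-domain coexpression with a randomization null
#'
#' Assigns genes to domains by midpoint, extracts the three
#' pairwise-coefficient populations (same domain, different domains, rest),
#' repeats the intra extraction on randomized domains (coordinate inversion
#' by default), and reports Bonferroni-corrected Mann-Whitney comparisons.
#'
#' @param domains a [DomainSet-class] (e.g. imported TADs).
#' @param C matching [CoexpressionMatrix-class].
#' @param annotation ranked `GRanges` of the matrix genes.
#' @param null a function `(domains, annotation)` returning randomized
#'   domains; default wraps [invertDomains()].
#' @param nTests Bonferroni multiplier forwarded to
#'   [compareDistributions()].
#' @return list with `populations` (`intra`, `inter`, `rest`,
#'   `random_intra`) and `tests` (data.frame of pairwise comparisons), or
#'   `NULL` with a message when the domain set is empty.
#' @export
intraVsInterDomainCoexpression <- function(domains, C, annotation,
        null = function(d, ann) invertDomains(d, annotation = ann),
        nTests = NULL) {
    gr <- domainRanges(domains)
    if (!length(gr)) {
        message("empty domain set: nothing to compare")
        return(NULL)
    }
    ann <- annotation[order(mcols(annotation)$rank)]
    membership <- assignGenesToDomains(ann, domains)
    pops <- .pair_populations(gr, C, membership = membership)
    rnd <- null(domains, ann)
    membershipR <- assignGenesToDomains(ann, rnd)
    popsR <- .pair_populations(domainRanges(rnd), C,
                               membership = membershipR)
    groups <- list(intra = pops$intra, inter = pops$inter, rest = pops$rest,
                   random_intra = popsR$intra)
    groups <- groups[lengths(groups) > 0]
    list(populations = groups,
         tests = compareDistributions(groups, nTests = nTests))
}
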