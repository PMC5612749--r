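#' Configuration for the COD caller
#'
#' See [CodCallConfig-class] for the meaning and published default of every
#' parameter. `strictBoundaryLength = TRUE` requires a below-threshold run
#' to reach `minBoundaryRun` genes before it may delimit a domain; the
#' default also admits shorter (>= `qualifyingRun`) significant runs as
#' delimiters, while only runs of at least `minBoundaryRun` genes are
#' reported as boundary regions.
#'
#' @param w binsignal window in genes.
#' @param threshold binsignal cutoff.
#' @param alpha boundary-test significance level.
#' @param minCodGenes minimum genes per COD.
#' @param maxInternalDip consecutive below-threshold genes tolerated inside
#'   a COD.
#' @param minBoundaryRun minimum length of a reported boundary region.
#' @param qualifyingRun minimum length of a delimiting run.
#' @param anchor `"any"`, `"min"` or `"midpoint"`; where in a
#'   below-threshold run the t-test decides significance.
#' @param tWindow binsignal values per side in the boundary t-test.
#' @param strictBoundaryLength shorthand setting
#'   `qualifyingRun = minBoundaryRun`.
#' @return a validated [CodCallConfig-class] object.
#' @export
codCallConfig <- function(w = 4, threshold = 0.15, alpha = 0.05,
                          minCodGenes = 4, maxInternalDip = 1,
                          minBoundaryRun = 4, qualifyingRun = 2,
                          anchor = c("any", "min", "midpoint"),
                          tWindow = 4, strictBoundaryLength = FALSE) {
    anchor <- match.arg(anchor)
    if (strictBoundaryLength) qualifyingRun <- minBoundaryRun
    new("CodCallConfig", w = as.integer(w), threshold = threshold,
        alpha = alpha, minCodGenes = as.integer(minCodGenes),
        maxInternalDip = as.integer(maxInternalDip),
        minBoundaryRun = as.integer(minBoundaryRun),
        qualifyingRun = as.integer(qualifyingRun), anchor = anchor,
        tWindow = as.integer(tWindow))
}

#' Call coexpression domains on one chromosome
#'
#' Implements the windowed boundary-statistic caller: (1) the binsignal
#' track is computed and every junction classified as above or below the
#' threshold; (2) above-threshold runs are segmented along the rank axis,
#' tolerating up to `maxInternalDip` consecutive below-threshold genes
#' inside a run; (3) below-threshold runs are tested for boundary
#' significance with the Student t-test (see [boundaryTest()] and the
#' `anchor` rule); (4) an above-threshold run delimited on both sides by a
#' significant boundary or a chromosome end, spanning at least
#' `minCodGenes` genes, is emitted as a COD together with its average
#' intra-COD coexpression and both boundary p-values.
#'
#' A COD spanning genes `a..b` corresponds to the above-threshold junctions
#' `a..b-1`; domain coordinates run from the first nucleotide of the first
#' member gene to the last nucleotide of the last one.
#'
#' @param C a [CoexpressionMatrix-class].
#' @param annotation optional ranked `GRanges` for the same chromosome,
#'   used to attach genomic coordinates. Without it, rank indices stand in
#'   for coordinates.
#' @param config a [CodCallConfig-class] from [codCallConfig()].
#' @return list with elements `cods` (a [DomainSet-class] of kind COD),
#'   `boundaries` (data.frame of reported boundary regions: `first_rank`,
#'   `last_rank`, `run_length`, `p_value`, `significant`) and `track` (the
#'   [BinSignalTrack-class]).
#' @export
callCods <- function(C, annotation = NULL, config = codCallConfig()) {
    n <- length(geneIds(C))
    empty <- .empty_cod_result(C, annotation)
    if (n < 2L * config@w + 1L) {
        warning("chromosome ", chrom(C), " has fewer than 2w+1 genes; ",
                "no CODs called")
        return(empty)
    }
    track <- computeBinsignal(C, w = config@w, threshold = config@threshold)
    s <- binsignal(track)
    links <- seq_len(n - 1L)
    above <- !is.na(s[links]) & s[links] >= config@threshold
    runs <- true_runs(above)
    runs <- .merge_dips(runs, config@maxInternalDip)
    below <- .complement_runs(runs, n - 1L)
    if (nrow(below)) {
        below$p_value <- vapply(seq_len(nrow(below)), function(k)
            .boundary_p(track, below$first[k], below$last[k], config),
            numeric(1L))
        below$significant <- is.finite(below$p_value) &
            below$p_value < config@alpha &
            below$length >= config@qualifyingRun
    } else {
        below$p_value <- numeric(); below$significant <- logical()
    }
    keep <- logical(nrow(runs))
    pL <- pR <- rep(NA_real_, nrow(runs))
    for (k in seq_len(nrow(runs))) {
        a <- runs$first[k]; b <- runs$last[k]
        leftOk <- a == 1L
        if (!leftOk) {
            j <- which(below$last == a - 1L)
            leftOk <- length(j) && below$significant[j]
            pL[k] <- if (length(j)) below$p_value[j] else NA_real_
        }
        rightOk <- b == n - 1L
        if (!rightOk) {
            j <- which(below$first == b + 1L)
            rightOk <- length(j) && below$significant[j]
            pR[k] <- if (length(j)) below$p_value[j] else NA_real_
        }
        keep[k] <- leftOk && rightOk && (b + 1L - a + 1L) >= config@minCodGenes
    }
    boundaries <- below[below$length >= config@minBoundaryRun, , drop = FALSE]
    names(boundaries)[names(boundaries) == "first"] <- "first_rank"
    names(boundaries)[names(boundaries) == "last"] <- "last_rank"
    names(boundaries)[names(boundaries) == "length"] <- "run_length"
    rownames(boundaries) <- NULL
    if (!any(keep)) {
        empty$boundaries <- boundaries
        empty$track <- track
        return(empty)
    }
    firstRank <- runs$first[keep]
    lastRank <- runs$last[keep] + 1L  # junction b covers genes b and b+1
    gr <- .cod_ranges(C, annotation, firstRank, lastRank)
    mcols(gr)$firstRank <- firstRank
    mcols(gr)$lastRank <- lastRank
    mcols(gr)$nGenes <- lastRank - firstRank + 1L
    mcols(gr)$geneIds <- CharacterList(lapply(seq_along(firstRank), function(k)
        geneIds(C)[firstRank[k]:lastRank[k]]))
    mcols(gr)$avgIntraCoexpression <- vapply(seq_along(firstRank), function(k)
        averagePairwiseCoexpression(C, firstRank[k]:lastRank[k])$average,
        numeric(1L))
    mcols(gr)$pLeft <- pL[keep]
    mcols(gr)$pRight <- pR[keep]
    list(cods = domainSet(gr, kind = "COD", checkOverlap = FALSE),
         boundaries = boundaries, track = track)
}

.empty_cod_result <- function(C, annotation) {
    gr <- GRanges(seqnames = character(), IRanges())
    mcols(gr)$firstRank <- integer(); mcols(gr)$lastRank <- integer()
    mcols(gr)$nGenes <- integer(); mcols(gr)$geneIds <- CharacterList()
    mcols(gr)$avgIntraCoexpression <- numeric()
    mcols(gr)$pLeft <- numeric(); mcols(gr)$pRight <- numeric()
    list(cods = new("DomainSet", ranges = gr, kind = "COD"),
         boundaries = data.frame(first_rank = integer(),
                                 last_rank = integer(),
                                 run_length = integer(),
                                 p_value = numeric(),
                                 significant = logical()),
         track = NULL)
}

# Merge above-threshold runs separated by at most maxDip below junctions.
.merge_dips <- function(runs, maxDip) {
    if (nrow(runs) < 2L || maxDip < 1L) return(runs)
    out <- runs[1L, , drop = FALSE]
    for (k in 2L:nrow(runs)) {
        gap <- runs$first[k] - out$last[nrow(out)] - 1L
        if (gap <= maxDip) {
            out$last[nrow(out)] <- runs$last[k]
        } else {
            out <- rbind(out, runs[k, , drop = FALSE])
        }
    }
    out$length <- out$last - out$first + 1L
    out
}

.complement_runs <- function(runs, n) {
    flag <- rep(TRUE, n)
    for (k in seq_len(nrow(runs))) flag[runs$first[k]:runs$last[k]] <- FALSE
    true_runs(flag)
}

# Boundary p-value of a below-threshold run under the configured anchor.
.boundary_p <- function(track, first, last, config) {
    anchors <- switch(config@anchor,
        # the extra anchor one gene before the run mirrors, for the run's
        # 5' edge, the clean domain-versus-boundary window split that the
        # run's last gene provides at its 3' edge (U includes gene i, D
        # does not, so the two edges are otherwise asymmetric)
        any = max(first - 1L, 1L):last,
        min = {
            s <- binsignal(track)[first:last]
            if (all(is.na(s))) as.integer((first + last) / 2)
            else first + which.min(s) - 1L
        },
        midpoint = as.integer((first + last) / 2))
    p <- vapply(anchors, function(i) boundaryTest(track, i, config@tWindow),
                numeric(1L))
    p <- p[is.finite(p)]
    if (!length(p)) NA_real_ else min(p)
}

.cod_ranges <- function(C, annotation, firstRank, lastRank) {
    if (is.null(annotation)) {
        return(GRanges(chrom(C), IRanges(firstRank, lastRank)))
    }
    ann <- annotation[.strip_chr(seqnames(annotation)) == .strip_chr(chrom(C))]
    ann <- ann[order(mcols(ann)$rank)]
    if (length(ann) != length(geneIds(C)))
        stop("annotation does not cover the coexpression matrix genes")
    GRanges(as.character(seqnames(ann))[1L],
            IRanges(start(ann)[firstRank], end(ann)[lastRank]))
}

#' Sweep the binsignal window size
#'
#' Re-runs the COD caller for each window in `wValues` and tabulates the
#' number of domains, their mean size in genes, and the mean intra-domain
#' coexpression — the robustness table used to justify the default `w = 4`
#' (the window maximizing average intra-COD coexpression; windows 3-6 give
#' very similar results).
#'
#' @param C a [CoexpressionMatrix-class].
#' @param wValues integer vector of window sizes.
#' @param annotation optional ranked `GRanges` (as in [callCods()]).
#' @param config base [CodCallConfig-class]; its `w` is overridden.
#' @return data.frame with columns `w`, `n_cods`, `mean_cod_genes`,
#'   `mean_intra_coexpression`.
#' @export
windowSweep <- function(C, wValues, annotation = NULL,
                        config = codCallConfig()) {
    rows <- lapply(as.integer(wValues), function(w) {
        cfg <- initialize(config, w = w)
        res <- callCods(C, annotation, cfg)
        gr <- domainRanges(res$cods)
        data.frame(w = w, n_cods = length(gr),
                   mean_cod_genes = mean_defined(mcols(gr)$nGenes),
                   mean_intra_coexpression =
                       mean_defined(mcols(gr)$avgIntraCoexpression))
    })
    if (!length(rows))
        return(data.frame(w = integer(), n_cods = integer(),
                          mean_cod_genes = numeric(),
                          mean_intra_coexpression = numeric()))
    do.call(rbind, rows)
}
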