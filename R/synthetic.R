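#' Specify a synthetic chromosome
#'
#' Low-level constructor for [SyntheticSpec-class]. The generator plants
#' blocks of mutually correlated genes (the ground-truth coexpression
#' domains) among uncorrelated background genes, optionally couples
#' designated block pairs through a shared latent factor, and can emit a
#' companion Hi-C map whose compartments follow the coupled block groups.
#'
#' @param nGenes genes on the chromosome.
#' @param nSamples samples in the cohort (default 100, a typical
#'   normal-tissue cohort size).
#' @param blocks data.frame with `firstRank`, `lastRank`, `rhoIntra`
#'   (1-based inclusive ranks; disjoint).
#' @param coupledPairs data.frame with `blockA`, `blockB`, `rhoInter`.
#' @param geneSpacing distance between gene starts, bp (default 100 kb,
#'   matching the Hi-C anchor size so each gene has its own anchor).
#' @param geneLength gene length, bp.
#' @param chrom chromosome name.
#' @param exprMean,exprSd affine placement on the nonnegative RSEM-like
#'   scale (does not affect correlations).
#' @param hicResolution,hicDecay,hicBoost,hicDepth Hi-C parameters: bin
#'   size, power-law decay exponent, same-compartment enrichment factor,
#'   expected off-compartment count at distance 1.
#' @param seed integer seed; identical seeds give identical output.
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nGenes, nSamples = 100L,
                          blocks = data.frame(firstRank = integer(),
                                              lastRank = integer(),
                                              rhoIntra = numeric()),
                          coupledPairs = data.frame(blockA = integer(),
                                                    blockB = integer(),
                                                    rhoInter = numeric()),
                          geneSpacing = 1e5, geneLength = 2e4,
                          chrom = "chrS", exprMean = 100, exprSd = 10,
                          hicResolution = 1e5, hicDecay = 1, hicBoost = 2,
                          hicDepth = 100, seed = 1L) {
    new("SyntheticSpec", nGenes = as.integer(nGenes),
        nSamples = as.integer(nSamples), geneSpacing = geneSpacing,
        geneLength = geneLength, chrom = chrom,
        blocks = blocks, coupledPairs = coupledPairs,
        exprMean = exprMean, exprSd = exprSd,
        hicResolution = hicResolution, hicDecay = hicDecay,
        hicBoost = hicBoost, hicDepth = hicDepth, seed = as.integer(seed))
}

#' Standard planted-block design
#'
#' The study design used throughout the package's own validation:
#' `nBlocks` blocks of `blockGenes` genes at within-block correlation
#' `rhoIntra`, separated by `gapGenes` background genes and flanked by
#' `flankGenes` background genes at each end, across `nSamples` samples.
#'
#' @param nBlocks,blockGenes,gapGenes,flankGenes layout in genes.
#'   `gapGenes` may be a vector of `nBlocks - 1` gap sizes and
#'   `flankGenes` a length-2 vector (5', 3'); an irregular layout is the
#'   realistic choice when demonstrating the coordinate-inversion null,
#'   since a palindromic layout makes inversion a symmetry of the truth.
#' @param rhoIntra target within-block correlation.
#' @param coupledPairs optional coupling data.frame (see
#'   [syntheticSpec()]).
#' @param nSamples cohort size.
#' @param seed integer seed.
#' @param ... passed to [syntheticSpec()].
#' @return a [SyntheticSpec-class].
#' @export
plantedBlockSpec <- function(nBlocks = 5L, blockGenes = 10L, gapGenes = 6L,
                             flankGenes = 6L, rhoIntra = 0.6,
                             coupledPairs = data.frame(blockA = integer(),
                                                       blockB = integer(),
                                                       rhoInter = numeric()),
                             nSamples = 100L, seed = 1L, ...) {
    gaps <- rep_len(gapGenes, max(nBlocks - 1L, 0L))
    flanks <- rep_len(flankGenes, 2L)
    first <- flanks[1L] + 1L +
        c(0L, cumsum(blockGenes + gaps))[seq_len(nBlocks)]
    blocks <- data.frame(firstRank = first,
                         lastRank = first + blockGenes - 1L,
                         rhoIntra = rhoIntra)
    nGenes <- sum(flanks) + nBlocks * blockGenes + sum(gaps)
    syntheticSpec(nGenes = nGenes, nSamples = nSamples, blocks = blocks,
                  coupledPairs = coupledPairs, seed = seed, ...)
}

#' Generate a synthetic expression cohort with planted domains
#'
#' Latent-factor model: each block has a per-sample factor; coupled block
#' pairs share an additional factor scaled to induce the requested
#' cross-block correlation; every gene is its block loading times the
#' factors plus independent noise, placed on a nonnegative RSEM-like scale
#' by an affine shift (which leaves all correlations exact). Expected
#' pairwise correlations: `rhoIntra` within a block, `rhoInter` across
#' coupled blocks, 0 elsewhere.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `expr` (`RangedSummarizedExperiment`), `annotation`
#'   (ranked `GRanges`), `truth` (a [DomainSet-class] of the planted
#'   blocks) and `spec`.
#' @export
generateExpression <- function(spec) {
    validObject(spec)
    b <- spec@blocks; cp <- spec@coupledPairs
    shared <- numeric(max(nrow(b), 1L))
    if (nrow(b)) {
        shared <- vapply(seq_len(nrow(b)), function(k)
            sum(cp$rhoInter[cp$blockA == k | cp$blockB == k]), numeric(1L))
        if (any(shared > b$rhoIntra + 1e-12))
            stop("infeasible correlation targets: shared-factor variance ",
                 "exceeds rhoIntra for at least one block")
    }
    n <- spec@nGenes; m <- spec@nSamples
    z <- with_rng(spec@seed, {
        noise <- matrix(stats::rnorm(n * m), n, m)
        z <- noise  # background genes: pure noise
        if (nrow(b)) {
            factors <- matrix(stats::rnorm(nrow(b) * m), nrow(b), m)
            sharedF <- if (nrow(cp))
                matrix(stats::rnorm(nrow(cp) * m), nrow(cp), m)
            else matrix(numeric(), 0L, m)
            for (k in seq_len(nrow(b))) {
                idx <- b$firstRank[k]:b$lastRank[k]
                own <- b$rhoIntra[k] - shared[k]
                sig <- sqrt(own) * factors[k, ]
                for (p in seq_len(nrow(cp)))
                    if (cp$blockA[p] == k || cp$blockB[p] == k)
                        sig <- sig + sqrt(cp$rhoInter[p]) * sharedF[p, ]
                z[idx, ] <- matrix(sig, length(idx), m, byrow = TRUE) +
                    sqrt(1 - b$rhoIntra[k]) * noise[idx, ]
            }
        }
        z
    })
    values <- spec@exprMean + spec@exprSd * z
    ids <- sprintf("g%04d", seq_len(n))
    rownames(values) <- ids
    colnames(values) <- sprintf("s%04d", seq_len(m))
    starts <- (seq_len(n) - 1L) * spec@geneSpacing + 1
    ann <- geneAnnotation(ids, spec@chrom, starts,
                          starts + spec@geneLength - 1)
    ann <- orderGenes(ann)
    expr <- codExperiment(values, ann)
    truth <- .truth_domains(spec, ann)
    list(expr = expr, annotation = ann, truth = truth, spec = spec)
}

.truth_domains <- function(spec, ann) {
    b <- spec@blocks
    if (!nrow(b)) {
        gr <- GRanges(seqnames = character(), IRanges())
        mcols(gr)$firstRank <- integer(); mcols(gr)$lastRank <- integer()
        mcols(gr)$nGenes <- integer(); mcols(gr)$geneIds <- CharacterList()
        return(new("DomainSet", ranges = gr, kind = "COD"))
    }
    o <- order(b$firstRank)
    b <- b[o, , drop = FALSE]
    gr <- GRanges(spec@chrom,
                  IRanges(start(ann)[b$firstRank], end(ann)[b$lastRank]))
    mcols(gr)$firstRank <- as.integer(b$firstRank)
    mcols(gr)$lastRank <- as.integer(b$lastRank)
    mcols(gr)$nGenes <- as.integer(b$lastRank - b$firstRank + 1L)
    mcols(gr)$geneIds <- CharacterList(lapply(seq_len(nrow(b)), function(k)
        mcols(ann)$gene_id[b$firstRank[k]:b$lastRank[k]]))
    domainSet(gr, kind = "COD")
}

#' Generate a synthetic Hi-C contact map
#'
#' Expected contacts follow a power law in bin distance,
#' `lambda(i, j) = depth * |i - j|^(-decay)`, multiplied by `boost` when
#' both bins belong to the same compartment; compartments are the
#' connected groups of blocks linked by `coupledPairs` (with
#' `coupling = "cod_coupled"`), so the contact structure aligns with the
#' planted coexpression structure. Counts are independent Poisson draws,
#' mirrored to a symmetric matrix.
#'
#' @param spec a [SyntheticSpec-class].
#' @param coupling `"cod_coupled"` (compartments from coupled block
#'   groups) or `"none"` (pure distance decay).
#' @return list with `hic` (a raw-count [HiCMatrix-class]),
#'   `compartments` (integer label per bin, `NA` for unassigned bins) and
#'   `spec`.
#' @export
generateHic <- function(spec, coupling = c("cod_coupled", "none")) {
    validObject(spec)
    coupling <- match.arg(coupling)
    chromLength <- spec@nGenes * spec@geneSpacing
    nBins <- as.integer(ceiling(chromLength / spec@hicResolution))
    comp <- rep(NA_integer_, nBins)
    if (coupling == "cod_coupled" && nrow(spec@blocks)) {
        group <- .block_groups(nrow(spec@blocks), spec@coupledPairs)
        starts <- (seq_len(spec@nGenes) - 1L) * spec@geneSpacing + 1
        mids <- starts - 1 + spec@geneLength / 2
        geneBin <- floor(mids / spec@hicResolution) + 1L
        for (k in seq_len(nrow(spec@blocks))) {
            idx <- spec@blocks$firstRank[k]:spec@blocks$lastRank[k]
            comp[unique(geneBin[idx])] <- group[k]
        }
    }
    d <- abs(row(diag(nBins)) - col(diag(nBins)))
    lambda <- spec@hicDepth * pmax(d, 0.5)^(-spec@hicDecay)
    same <- outer(comp, comp, function(a, b)
        !is.na(a) & !is.na(b) & a == b)
    lambda <- lambda * ifelse(same, spec@hicBoost, 1)
    counts <- with_rng((spec@seed + 1000003L) %% .Machine$integer.max, {
        upper <- which(upper.tri(lambda, diag = TRUE))
        cnt <- matrix(0, nBins, nBins)
        cnt[upper] <- stats::rpois(length(upper), lambda[upper])
        cnt[lower.tri(cnt)] <- t(cnt)[lower.tri(cnt)]
        cnt
    })
    list(hic = hicMatrix(counts, chrom = spec@chrom,
                         resolution = spec@hicResolution),
         compartments = comp, spec = spec)
}

# Connected components of the block-coupling graph (union-find).
.block_groups <- function(nBlocks, coupledPairs) {
    parent <- seq_len(nBlocks)
    find <- function(i) {
        i <- as.integer(i)
        while (parent[i] != i) i <- parent[i]
        i
    }
    for (p in seq_len(nrow(coupledPairs))) {
        a <- find(coupledPairs$blockA[p]); b <- find(coupledPairs$blockB[p])
        if (a != b) parent[b] <- a
    }
    roots <- vapply(seq_len(nBlocks), find, integer(1L))
    match(roots, unique(roots))
}

#' Evaluate domain recovery against the planted truth
#'
#' A truth block counts as recovered when a called COD shares at least 80%
#' of its genes (gene-coincidence matching); precision is the converse
#' fraction of called CODs matching some truth block. Boundary precision,
#' recall and F1 compare called against true domain edges in rank units at
#' a tolerance of `tolGenes` (starts against starts, ends against ends).
#'
#' @param called [DomainSet-class] of called domains.
#' @param truth [DomainSet-class] of planted blocks.
#' @param tolGenes boundary tolerance in genes (default 1).
#' @param geneFrac gene-coincidence fraction for domain matching.
#' @return list with `precision`, `recall`, `boundaryPrecision`,
#'   `boundaryRecall`, `boundaryF1`, `boundaryErrors` (signed rank offsets
#'   of matched domain edges), `nCalled`, `nTruth`. With no calls,
#'   `precision` is `NA` (flagged) and recall 0.
#' @export
evaluateRecovery <- function(called, truth, tolGenes = 1L,
                             geneFrac = 0.80) {
    nCalled <- nDomains(called); nTruth <- nDomains(truth)
    if (nCalled == 0L) {
        return(list(precision = NA_real_, recall = 0,
                    boundaryPrecision = NA_real_, boundaryRecall = 0,
                    boundaryF1 = 0, boundaryErrors = integer(),
                    nCalled = 0L, nTruth = nTruth))
    }
    recall <- matchDomainsByGenes(truth, called, geneFrac)$nMatched / nTruth
    precision <- matchDomainsByGenes(called, truth, geneFrac)$nMatched /
        nCalled
    cg <- domainRanges(called); tg <- domainRanges(truth)
    calledEdges <- list(start = mcols(cg)$firstRank,
                        end = mcols(cg)$lastRank)
    truthEdges <- list(start = mcols(tg)$firstRank,
                       end = mcols(tg)$lastRank)
    matchedCalled <- matchedTruth <- 0L
    for (side in c("start", "end")) {
        ce <- calledEdges[[side]]; te <- truthEdges[[side]]
        matchedCalled <- matchedCalled +
            sum(vapply(ce, function(e) any(abs(te - e) <= tolGenes),
                       logical(1L)))
        matchedTruth <- matchedTruth +
            sum(vapply(te, function(e) any(abs(ce - e) <= tolGenes),
                       logical(1L)))
    }
    bPrec <- matchedCalled / (2L * nCalled)
    bRec <- matchedTruth / (2L * nTruth)
    bF1 <- if (bPrec + bRec == 0) 0 else 2 * bPrec * bRec / (bPrec + bRec)
    pairs <- matchDomainsByGenes(called, truth, geneFrac)
    errors <- integer()
    for (k in which(pairs$matched)) {
        overlapGenes <- vapply(domainGenes(truth), function(g)
            length(intersect(g, domainGenes(called)[[k]])), integer(1L))
        j <- which.max(overlapGenes)
        errors <- c(errors,
                    calledEdges$start[k] - truthEdges$start[j],
                    calledEdges$end[k] - truthEdges$end[j])
    }
    list(precision = precision, recall = recall,
         boundaryPrecision = bPrec, boundaryRecall = bRec, boundaryF1 = bF1,
         boundaryErrors = errors, nCalled = nCalled, nTruth = nTruth)
}
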