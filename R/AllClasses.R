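#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges CharacterList
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
NULL

#' CoexpressionMatrix: per-chromosome pairwise Pearson coexpression
#'
#' Symmetric matrix of Pearson correlation coefficients between the
#' expression profiles of every pair of genes on one chromosome, with genes
#' indexed by their 5'->3' chromosomal rank. Genes whose expression has zero
#' variance across samples carry `valid = FALSE`; their rows/columns are
#' `NA` but their ranks are preserved so that domain coordinates never shift.
#'
#' @slot chrom chromosome name.
#' @slot corr symmetric numeric matrix of correlations, `NA` where undefined.
#' @slot geneIds character vector of gene identifiers in rank order.
#' @slot valid logical vector, `FALSE` for zero-variance genes.
#' @exportClass CoexpressionMatrix
setClass("CoexpressionMatrix",
    representation(chrom = "character", corr = "matrix",
                   geneIds = "character", valid = "logical"))

setValidity("CoexpressionMatrix", function(object) {
    msg <- NULL
    n <- length(object@geneIds)
    if (!all(dim(object@corr) == c(n, n)))
        msg <- c(msg, "corr must be n x n for n genes")
    if (length(object@valid) != n)
        msg <- c(msg, "valid must have one flag per gene")
    finite <- object@corr[is.finite(object@corr)]
    if (length(finite) && (max(finite) > 1 + 1e-8 || min(finite) < -1 - 1e-8))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    if (n > 1 && any(abs(object@corr - t(object@corr)) > 1e-8, na.rm = TRUE))
        msg <- c(msg, "corr must be symmetric")
    if (is.null(msg)) TRUE else msg
})

#' BinSignalTrack: the windowed domain-calling statistic
#'
#' `signal[i]` is the mean Pearson coefficient over the block of correlations
#' between the window of `w` genes ending at gene `i` (upstream window,
#' including `i`) and the `w` genes that follow it (downstream window). High
#' values indicate that the junction between gene `i` and gene `i + 1` lies
#' inside a coexpression domain.
#'
#' @slot chrom chromosome name.
#' @slot w window size in genes.
#' @slot threshold coexpression cutoff used to classify the track.
#' @slot signal per-gene binsignal values (`NA` where undefined; always `NA`
#'   at the last rank, whose downstream window is empty).
#' @slot geneIds gene identifiers in rank order.
#' @exportClass BinSignalTrack
setClass("BinSignalTrack",
    representation(chrom = "character", w = "integer", threshold = "numeric",
                   signal = "numeric", geneIds = "character"))

setValidity("BinSignalTrack", function(object) {
    msg <- NULL
    if (length(object@signal) != length(object@geneIds))
        msg <- c(msg, "one signal value per gene required")
    ok <- object@signal[is.finite(object@signal)]
    if (length(ok) && (max(ok) > 1 + 1e-8 || min(ok) < -1 - 1e-8))
        msg <- c(msg, "binsignal values must lie in [-1, 1]")
    if (object@w < 1L) msg <- c(msg, "w must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' DomainSet: called or imported genomic domains
#'
#' A set of non-overlapping domains on one chromosome, stored as a `GRanges`
#' whose metadata columns carry the gene-rank interval (`firstRank`,
#' `lastRank`), the member gene identifiers, and any per-domain statistics
#' (e.g. average intra-domain coexpression and boundary p-values for CODs).
#'
#' @slot ranges `GRanges` of domain coordinates (0-based half-open on disk,
#'   `GRanges` 1-based closed in memory).
#' @slot kind one of `"COD"`, `"TAD"`, `"contact_domain"`, `"RIDGE"`,
#'   `"random"`.
#' @exportClass DomainSet
setClass("DomainSet",
    representation(ranges = "GRanges", kind = "character"))

.domain_kinds <- c("COD", "TAD", "contact_domain", "RIDGE", "random")

setValidity("DomainSet", function(object) {
    msg <- NULL
    if (!object@kind %in% .domain_kinds)
        msg <- c(msg, paste("kind must be one of:",
                            paste(.domain_kinds, collapse = ", ")))
    gr <- object@ranges
    if (length(gr)) {
        if (length(unique(as.character(seqnames(gr)))) > 1L)
            msg <- c(msg, "a DomainSet holds a single chromosome")
        if (is.unsorted(start(gr)))
            msg <- c(msg, "domains must be sorted by start")
        fr <- mcols(gr)$firstRank; lr <- mcols(gr)$lastRank
        if (!is.null(fr) && !is.null(lr)) {
            if (any(lr < fr)) msg <- c(msg, "lastRank must be >= firstRank")
            if (length(gr) > 1L &&
                any(fr[-1L] <= lr[-length(gr)]))
                msg <- c(msg, "domains overlap in rank space")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' CodCallConfig: tuning parameters of the COD caller
#'
#' Defaults reproduce the published procedure: window `w = 4` genes,
#' binsignal threshold 0.15 (the genome-wide average binsignal in breast
#' tissue), boundary significance alpha 0.05, domains of fewer than 4 genes
#' discarded, at most one consecutive below-threshold gene tolerated inside a
#' domain, and boundary regions reported when longer than three genes.
#'
#' @slot w binsignal window, in genes.
#' @slot threshold binsignal cutoff separating domain interior from boundary.
#' @slot alpha significance level of the boundary Student t-test.
#' @slot minCodGenes minimum genes per emitted COD.
#' @slot maxInternalDip maximum consecutive below-threshold genes tolerated
#'   inside a COD.
#' @slot minBoundaryRun minimum run length (genes) for a below-threshold run
#'   to be reported as a boundary region.
#' @slot qualifyingRun minimum run length for a below-threshold run to act as
#'   a domain delimiter when its t-test is significant (see the vignette for
#'   why this is allowed to be shorter than `minBoundaryRun`).
#' @slot anchor where in a below-threshold run the boundary t-test is
#'   evaluated: `"any"` (test every gene, keep the minimum p), `"min"`
#'   (minimum-binsignal gene) or `"midpoint"`.
#' @slot tWindow number of binsignal values per side entering the boundary
#'   t-test (the published test uses four a side regardless of `w`).
#' @exportClass CodCallConfig
setClass("CodCallConfig",
    representation(w = "integer", threshold = "numeric", alpha = "numeric",
                   minCodGenes = "integer", maxInternalDip = "integer",
                   minBoundaryRun = "integer", qualifyingRun = "integer",
                   anchor = "character", tWindow = "integer"),
    prototype(w = 4L, threshold = 0.15, alpha = 0.05, minCodGenes = 4L,
              maxInternalDip = 1L, minBoundaryRun = 4L, qualifyingRun = 2L,
              anchor = "any", tWindow = 4L))

setValidity("CodCallConfig", function(object) {
    msg <- NULL
    if (object@w < 1L) msg <- c(msg, "w must be >= 1")
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must lie in (0, 1)")
    if (object@minCodGenes < 1L) msg <- c(msg, "minCodGenes must be >= 1")
    if (object@maxInternalDip < 0L) msg <- c(msg, "maxInternalDip must be >= 0")
    if (object@qualifyingRun < 1L) msg <- c(msg, "qualifyingRun must be >= 1")
    if (!object@anchor %in% c("any", "min", "midpoint"))
        msg <- c(msg, "anchor must be 'any', 'min' or 'midpoint'")
    if (object@tWindow < 2L) msg <- c(msg, "tWindow must be >= 2")
    if (is.null(msg)) TRUE else msg
})

#' HiCMatrix: binned intra-chromosomal contact matrix
#'
#' Carries the raw counts plus the products of the normalization stack:
#' Knight-Ruiz balancing vector and balanced matrix, observed-over-expected
#' matrix, and the Pearson correlation matrix of O/E rows (contact-profile
#' correlation, a.k.a. connectivity). Bins excluded from balancing (all-zero
#' or too sparse) have `included = FALSE` and `NA` in derived matrices.
#'
#' @slot chrom chromosome name.
#' @slot resolution bin size in bp.
#' @slot counts symmetric raw count matrix.
#' @slot balancing per-bin Knight-Ruiz scale factors (`NA` for excluded bins).
#' @slot normalized balanced matrix.
#' @slot oe observed-over-expected matrix.
#' @slot profileCorr Pearson correlation matrix of O/E rows.
#' @slot included logical flag per bin.
#' @exportClass HiCMatrix
setClass("HiCMatrix",
    representation(chrom = "character", resolution = "numeric",
                   counts = "matrix", balancing = "numeric",
                   normalized = "matrix", oe = "matrix",
                   profileCorr = "matrix", included = "logical"),
    prototype(chrom = "chr1", resolution = 1e5,
              counts = matrix(numeric(), 0, 0), balancing = numeric(),
              normalized = matrix(numeric(), 0, 0),
              oe = matrix(numeric(), 0, 0),
              profileCorr = matrix(numeric(), 0, 0), included = logical()))

setValidity("HiCMatrix", function(object) {
    msg <- NULL
    n <- nrow(object@counts)
    if (ncol(object@counts) != n) msg <- c(msg, "counts must be square")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (n > 1 && any(abs(object@counts - t(object@counts)) > 1e-8))
        msg <- c(msg, "counts must be symmetric")
    if (object@resolution <= 0) msg <- c(msg, "resolution must be positive")
    if (is.null(msg)) TRUE else msg
})

#' SyntheticSpec: parameters of the synthetic cohort generator
#'
#' Describes a synthetic chromosome: `nGenes` evenly spaced genes, planted
#' blocks of mutually correlated genes (latent-factor model, target
#' within-block correlation `rhoIntra`), optional long-range coupling between
#' designated block pairs (shared factor inducing cross-block correlation
#' `rhoInter`), uncorrelated background genes, and a companion Hi-C map with
#' power-law distance decay plus a compartment boost aligned to the coupled
#' block groups.
#'
#' @slot nGenes number of genes on the synthetic chromosome.
#' @slot nSamples number of samples in the expression cohort.
#' @slot geneSpacing distance between consecutive gene starts, bp.
#' @slot geneLength gene length, bp (must be < `geneSpacing`).
#' @slot chrom chromosome name used in all emitted objects.
#' @slot blocks data.frame with columns `firstRank`, `lastRank`, `rhoIntra`.
#' @slot coupledPairs data.frame with columns `blockA`, `blockB`, `rhoInter`.
#' @slot exprMean,exprSd affine placement of the simulated values on a
#'   nonnegative RSEM-like scale (correlations are unaffected).
#' @slot hicResolution Hi-C bin size, bp.
#' @slot hicDecay power-law distance-decay exponent (> 0).
#' @slot hicBoost multiplicative contact enrichment for same-compartment bins.
#' @slot hicDepth expected contact count at distance 1 bin, off-compartment.
#' @slot seed integer seed; fixed seed implies bit-reproducible output.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(nGenes = "integer", nSamples = "integer",
                   geneSpacing = "numeric", geneLength = "numeric",
                   chrom = "character", blocks = "data.frame",
                   coupledPairs = "data.frame", exprMean = "numeric",
                   exprSd = "numeric", hicResolution = "numeric",
                   hicDecay = "numeric", hicBoost = "numeric",
                   hicDepth = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- NULL
    b <- object@blocks
    if (nrow(b)) {
        if (!all(c("firstRank", "lastRank", "rhoIntra") %in% names(b)))
            msg <- c(msg, "blocks needs firstRank, lastRank, rhoIntra")
        else {
            if (any(b$firstRank < 1L) || any(b$lastRank > object@nGenes))
                msg <- c(msg, "block ranks must lie in 1..nGenes")
            if (any(b$lastRank < b$firstRank))
                msg <- c(msg, "block lastRank must be >= firstRank")
            if (any(b$rhoIntra < 0) || any(b$rhoIntra >= 1))
                msg <- c(msg, "rhoIntra must lie in [0, 1)")
            o <- order(b$firstRank)
            if (nrow(b) > 1L &&
                any(b$firstRank[o][-1L] <= b$lastRank[o][-nrow(b)]))
                msg <- c(msg, "blocks must be disjoint in rank space")
        }
    }
    cp <- object@coupledPairs
    if (nrow(cp)) {
        if (!all(c("blockA", "blockB", "rhoInter") %in% names(cp)))
            msg <- c(msg, "coupledPairs needs blockA, blockB, rhoInter")
        else if (any(cp$blockA < 1L) || any(cp$blockB < 1L) ||
                 any(cp$blockA > nrow(b)) || any(cp$blockB > nrow(b)))
            msg <- c(msg, "coupledPairs must index existing blocks")
        else if (any(cp$rhoInter < 0))
            msg <- c(msg, "rhoInter must be >= 0")
    }
    if (object@geneLength >= object@geneSpacing)
        msg <- c(msg, "geneLength must be smaller than geneSpacing")
    if (object@hicDecay <= 0) msg <- c(msg, "hicDecay must be > 0")
    if (is.null(msg)) TRUE else msg
})
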