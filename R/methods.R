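# Accessors and show() methods for the core classes.

#' @rdname CoexpressionMatrix-class
#' @export
setMethod("corrMatrix", "CoexpressionMatrix", function(x) x@corr)

#' @rdname CoexpressionMatrix-class
#' @export
setMethod("validGenes", "CoexpressionMatrix", function(x) x@valid)

#' @rdname geneIds
#' @export
setMethod("geneIds", "CoexpressionMatrix", function(x) x@geneIds)

#' @rdname geneIds
#' @export
setMethod("chrom", "CoexpressionMatrix", function(x) x@chrom)

setMethod("show", "CoexpressionMatrix", function(object) {
    n <- length(object@geneIds)
    cat("CoexpressionMatrix on", object@chrom, "with", n, "genes (",
        sum(object@valid), "valid )\n")
    if (n > 1) {
        v <- object@corr[upper.tri(object@corr)]
        cat("  mean pairwise r:", round(mean(v, na.rm = TRUE), 4), "\n")
    }
})

#' @rdname BinSignalTrack-class
#' @export
setMethod("binsignal", "BinSignalTrack", function(x) x@signal)

#' @rdname geneIds
#' @export
setMethod("geneIds", "BinSignalTrack", function(x) x@geneIds)

#' @rdname geneIds
#' @export
setMethod("chrom", "BinSignalTrack", function(x) x@chrom)

setMethod("show", "BinSignalTrack", function(object) {
    cat("BinSignalTrack on", object@chrom, "| w =", object@w,
        "| threshold =", object@threshold, "\n")
    s <- object@signal
    cat("  ", length(s), "genes;", sum(!is.na(s)), "defined values;",
        sum(s >= object@threshold, na.rm = TRUE), "at/above threshold\n")
})

#' @rdname DomainSet-class
#' @export
setMethod("domainRanges", "DomainSet", function(x) x@ranges)

#' @rdname DomainSet-class
#' @export
setMethod("domainKind", "DomainSet", function(x) x@kind)

#' @rdname DomainSet-class
#' @export
setMethod("nDomains", "DomainSet", function(x) length(x@ranges))

#' @rdname DomainSet-class
#' @export
setMethod("domainGenes", "DomainSet", function(x) {
    g <- mcols(x@ranges)$geneIds
    if (is.null(g)) stop("this DomainSet carries no gene lists")
    as.list(g)
})

#' @rdname geneIds
#' @export
setMethod("chrom", "DomainSet", function(x)
    as.character(seqnames(x@ranges))[1L])

setMethod("show", "DomainSet", function(object) {
    gr <- object@ranges
    cat("DomainSet of kind", object@kind, "with", length(gr), "domains")
    if (length(gr)) {
        cat(" on", as.character(seqnames(gr))[1L],
            "| median width", stats::median(width(gr)), "bp")
        ng <- mcols(gr)$nGenes
        if (!is.null(ng)) cat(" | median genes", stats::median(ng))
    }
    cat("\n")
})

setMethod("show", "CodCallConfig", function(object) {
    cat("CodCallConfig: w =", object@w, "| threshold =", object@threshold,
        "| alpha =", object@alpha, "| minCodGenes =", object@minCodGenes,
        "\n  maxInternalDip =", object@maxInternalDip,
        "| minBoundaryRun =", object@minBoundaryRun,
        "| qualifyingRun =", object@qualifyingRun,
        "| anchor =", object@anchor, "| tWindow =", object@tWindow, "\n")
})

#' @rdname HiCMatrix-class
#' @export
setMethod("contactCounts", "HiCMatrix", function(x) x@counts)

#' @rdname HiCMatrix-class
#' @export
setMethod("balancingVector", "HiCMatrix", function(x) x@balancing)

#' @rdname HiCMatrix-class
#' @export
setMethod("balancedMatrix", "HiCMatrix", function(x) x@normalized)

#' @rdname HiCMatrix-class
#' @export
setMethod("oeMatrix", "HiCMatrix", function(x) x@oe)

#' @rdname HiCMatrix-class
#' @export
setMethod("profileCorr", "HiCMatrix", function(x) x@profileCorr)

#' @rdname HiCMatrix-class
#' @export
setMethod("includedBins", "HiCMatrix", function(x) x@included)

#' @rdname geneIds
#' @export
setMethod("chrom", "HiCMatrix", function(x) x@chrom)

setMethod("show", "HiCMatrix", function(object) {
    n <- nrow(object@counts)
    cat("HiCMatrix on", object@chrom, "|", n, "bins at",
        object@resolution, "bp\n")
    stage <- c(balanced = length(object@balancing) > 0,
               oe = length(object@oe) > 0,
               profileCorr = length(object@profileCorr) > 0)
    cat("  stages computed:",
        if (any(stage)) paste(names(stage)[stage], collapse = ", ")
        else "none (raw counts)", "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec:", object@nGenes, "genes x", object@nSamples,
        "samples on", object@chrom, "| seed", object@seed, "\n")
    cat("  ", nrow(object@blocks), "planted blocks,",
        nrow(object@coupledPairs), "coupled pairs\n")
})
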