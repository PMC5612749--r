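#' @rdname CoexpressionMatrix-class
#' @param object,x an object.
#' @export
setGeneric("corrMatrix", function(x) standardGeneric("corrMatrix"))

#' @rdname CoexpressionMatrix-class
#' @export
setGeneric("validGenes", function(x) standardGeneric("validGenes"))

#' @rdname BinSignalTrack-class
#' @export
setGeneric("binsignal", function(x) standardGeneric("binsignal"))

#' @rdname DomainSet-class
#' @export
setGeneric("domainRanges", function(x) standardGeneric("domainRanges"))

#' @rdname DomainSet-class
#' @export
setGeneric("domainKind", function(x) standardGeneric("domainKind"))

#' @rdname DomainSet-class
#' @export
setGeneric("nDomains", function(x) standardGeneric("nDomains"))

#' @rdname DomainSet-class
#' @export
setGeneric("domainGenes", function(x) standardGeneric("domainGenes"))

#' Generic accessors shared by several classes
#'
#' `geneIds()` returns gene identifiers in rank order; `chrom()` the
#' chromosome name.
#'
#' @param x an object with genes or a chromosome.
#' @return a character vector.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))

#' @rdname HiCMatrix-class
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @rdname HiCMatrix-class
#' @export
setGeneric("balancingVector", function(x) standardGeneric("balancingVector"))

#' @rdname HiCMatrix-class
#' @export
setGeneric("balancedMatrix", function(x) standardGeneric("balancedMatrix"))

#' @rdname HiCMatrix-class
#' @export
setGeneric("oeMatrix", function(x) standardGeneric("oeMatrix"))

#' @rdname HiCMatrix-class
#' @export
setGeneric("profileCorr", function(x) standardGeneric("profileCorr"))

#' @rdname HiCMatrix-class
#' @export
setGeneric("includedBins", function(x) standardGeneric("includedBins"))

#' Knight-Ruiz balancing of a Hi-C contact matrix
#'
#' @param x a [HiCMatrix-class] object (or symmetric matrix, for the
#'   low-level method).
#' @param ... passed on to methods.
#' @export
setGeneric("krBalance", function(x, ...) standardGeneric("krBalance"))

#' Observed-over-expected transform of a balanced Hi-C matrix
#'
#' @param x a [HiCMatrix-class] object.
#' @param ... passed on to methods.
#' @export
setGeneric("observedOverExpected",
           function(x, ...) standardGeneric("observedOverExpected"))

#' Contact-profile (connectivity) correlation matrix
#'
#' @param x a [HiCMatrix-class] object.
#' @param ... passed on to methods.
#' @export
setGeneric("profileCorrelation",
           function(x, ...) standardGeneric("profileCorrelation"))
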