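#' Construct a DomainSet
#'
#' @param ranges `GRanges` of domain coordinates on a single chromosome
#'   (1-based closed, the in-memory Bioconductor convention; BED I/O
#'   converts to 0-based half-open).
#' @param kind `"COD"`, `"TAD"`, `"contact_domain"`, `"RIDGE"` or
#'   `"random"`.
#' @param checkOverlap forbid base-pair overlap between domains. Defaults to
#'   `TRUE` for kinds called along the gene rank axis (COD, RIDGE, random)
#'   and `FALSE` for imported chromatin domains, which may nest.
#' @return a [DomainSet-class] object, sorted by start.
#' @export
domainSet <- function(ranges, kind = "COD",
                      checkOverlap = kind %in% c("COD", "RIDGE", "random")) {
    ranges <- ranges[order(start(ranges), end(ranges))]
    if (checkOverlap && length(ranges) > 1L &&
        any(start(ranges)[-1L] <= end(ranges)[-length(ranges)]))
        stop("overlapping intervals are not allowed in a ", kind, " set")
    new("DomainSet", ranges = ranges, kind = kind)
}

#' Read a domain BED file
#'
#' Accepts BED3+ (0-based half-open). Unsorted input is accepted and
#' sorted. Files spanning several chromosomes are split into one
#' [DomainSet-class] per chromosome.
#'
#' @param path BED file path, or a 1-based inclusive interval table when
#'   `oneBased = TRUE` (3 columns: chrom, start, end; tab-delimited).
#' @param kind domain kind to stamp on the result.
#' @param oneBased input uses 1-based inclusive coordinates instead of BED
#'   convention.
#' @param simplify return a bare `DomainSet` when only one chromosome is
#'   present (otherwise a named list).
#' @return `DomainSet` or named list of `DomainSet`.
#' @export
readDomainsBed <- function(path, kind = "TAD", oneBased = FALSE,
                           simplify = TRUE) {
    if (oneBased) {
        tab <- data.table::fread(path, header = FALSE, data.table = FALSE)
        if (any(tab[[3L]] < tab[[2L]]))
            stop("interval end before start in ", path)
        gr <- GRanges(as.character(tab[[1L]]),
                      IRanges(as.integer(tab[[2L]]), as.integer(tab[[3L]])))
    } else {
        gr <- rtracklayer::import(path, format = "BED")
    }
    if (any(width(gr) < 1L))
        stop("empty interval (start >= end) in ", path)
    mcols(gr) <- mcols(gr)[intersect("name", names(mcols(gr)))]
    out <- lapply(split(gr, droplevels(seqnames(gr))),
                  function(g) domainSet(g, kind = kind))
    if (simplify && length(out) == 1L) out[[1L]] else out
}

#' Write domains to BED (and optionally a statistics sidecar)
#'
#' The BED file is 0-based half-open, lossless for coordinates under
#' [readDomainsBed()]. For CODs a sidecar TSV mirrors the per-domain table:
#' gene list, gene count, average intra-domain coexpression, and the two
#' boundary p-values.
#'
#' @param x a [DomainSet-class] or list of them.
#' @param path output BED path.
#' @param sidecar optional TSV path for per-domain statistics.
#' @return `path`, invisibly.
#' @export
writeDomainsBed <- function(x, path, sidecar = NULL) {
    sets <- if (is(x, "DomainSet")) list(x) else x
    rows <- lapply(sets, function(ds) {
        gr <- domainRanges(ds)
        data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = mcols(gr)$name %||%
                       sprintf("%s_%s_%d", domainKind(ds),
                               as.character(seqnames(gr)), seq_along(gr)))
    })
    bed <- do.call(rbind, rows)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    if (!is.null(sidecar)) {
        sc <- do.call(rbind, lapply(sets, .sidecar_frame))
        utils::write.table(sc, sidecar, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

.sidecar_frame <- function(ds) {
    gr <- domainRanges(ds)
    mc <- mcols(gr)
    genes <- if (!is.null(mc$geneIds))
        vapply(as.list(mc$geneIds), paste, "", collapse = ",")
    else NA_character_
    data.frame(
        name = mc$name %||% sprintf("%s_%s_%d", domainKind(ds),
                                    as.character(seqnames(gr)), seq_along(gr)),
        chrom = as.character(seqnames(gr)),
        start = start(gr) - 1L, end = end(gr),
        first_rank = mc$firstRank %||% NA_integer_,
        last_rank = mc$lastRank %||% NA_integer_,
        n_genes = mc$nGenes %||% NA_integer_,
        genes = genes,
        avg_intra_coexpression = mc$avgIntraCoexpression %||% NA_real_,
        p_left = mc$pLeft %||% NA_real_,
        p_right = mc$pRight %||% NA_real_)
}

#' Read a domain set together with its statistics sidecar
#'
#' Restores the metadata written by [writeDomainsBed()] so that
#' write-then-read round-trips coordinates, gene lists and per-domain
#' statistics.
#'
#' @param path BED path.
#' @param sidecar sidecar TSV path.
#' @param kind domain kind.
#' @return `DomainSet` or named list of `DomainSet`.
#' @export
readDomains <- function(path, sidecar = NULL, kind = "COD") {
    out <- readDomainsBed(path, kind = kind, simplify = FALSE)
    if (!is.null(sidecar)) {
        sc <- data.table::fread(sidecar, sep = "\t", header = TRUE,
                                data.table = FALSE)
        out <- lapply(out, function(ds) {
            gr <- domainRanges(ds)
            key <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
            idx <- match(key, paste(sc$chrom, sc$start, sc$end))
            mcols(gr)$name <- sc$name[idx]
            mcols(gr)$firstRank <- as.integer(sc$first_rank[idx])
            mcols(gr)$lastRank <- as.integer(sc$last_rank[idx])
            mcols(gr)$nGenes <- as.integer(sc$n_genes[idx])
            mcols(gr)$geneIds <- CharacterList(
                lapply(strsplit(sc$genes[idx], ","), function(g)
                    if (length(g) == 1L && is.na(g)) character() else g))
            mcols(gr)$avgIntraCoexpression <- sc$avg_intra_coexpression[idx]
            mcols(gr)$pLeft <- sc$p_left[idx]
            mcols(gr)$pRight <- sc$p_right[idx]
            initialize(ds, ranges = gr)
        })
    }
    if (length(out) == 1L) out[[1L]] else out
}
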