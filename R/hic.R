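#' Construct a HiCMatrix from raw binned counts
#'
#' @param counts symmetric nonnegative contact matrix.
#' @param chrom chromosome name.
#' @param resolution bin size in bp (default 100,000, the analysis
#'   resolution used throughout).
#' @return a [HiCMatrix-class] holding raw counts (run [krBalance()],
#'   [observedOverExpected()], [profileCorrelation()] to fill the stack).
#' @export
hicMatrix <- function(counts, chrom = "chr1", resolution = 1e5) {
    new("HiCMatrix", chrom = chrom, resolution = resolution,
        counts = unname(as.matrix(counts)),
        balancing = numeric(), normalized = matrix(numeric(), 0, 0),
        oe = matrix(numeric(), 0, 0), profileCorr = matrix(numeric(), 0, 0),
        included = rep(TRUE, nrow(counts)))
}

#' Read intra-chromosomal Hi-C triplets
#'
#' Three-column text (`pos_i`, `pos_j`, `count`), upper-triangle storage,
#' mirrored on load. Positions are bin start coordinates in bp
#' (the common dump format for published contact maps; `coords = "bin"`
#' accepts 1-based bin indices instead).
#'
#' @param path triplet file.
#' @param resolution bin size in bp.
#' @param chrom chromosome name.
#' @param nBins matrix dimension; default: the largest bin observed.
#' @param coords `"bp"` or `"bin"`.
#' @return a [HiCMatrix-class].
#' @export
readHicTriplets <- function(path, resolution = 1e5, chrom = "chr1",
                            nBins = NULL, coords = c("bp", "bin")) {
    coords <- match.arg(coords)
    tab <- data.table::fread(path, header = FALSE, data.table = FALSE)
    i <- if (coords == "bp") floor(tab[[1L]] / resolution) + 1L
         else as.integer(tab[[1L]])
    j <- if (coords == "bp") floor(tab[[2L]] / resolution) + 1L
         else as.integer(tab[[2L]])
    cnt <- as.numeric(tab[[3L]])
    if (any(cnt < 0)) stop("negative contact count in ", path)
    n <- nBins %||% max(i, j)
    m <- matrix(0, n, n)
    m[cbind(i, j)] <- cnt
    m[cbind(j, i)] <- cnt
    hicMatrix(m, chrom = chrom, resolution = resolution)
}

#' Write a contact matrix as upper-triangle triplets
#'
#' @param x a [HiCMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHicTriplets <- function(x, path) {
    m <- contactCounts(x)
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    data.table::fwrite(data.frame(
        pos_i = (idx[, 1L] - 1L) * x@resolution,
        pos_j = (idx[, 2L] - 1L) * x@resolution,
        count = m[idx]), path, sep = "\t", col.names = FALSE)
    invisible(path)
}

# --- Knight-Ruiz balancing ------------------------------------------------

# Newton-type Knight-Ruiz iteration (inner conjugate-gradient solve) on a
# fully supported symmetric nonnegative matrix; returns the positive scaling
# vector x with rowSums(diag(x) A diag(x)) ~= 1, or NULL on failure.
kr_newton <- function(A, tol = 1e-6, max_outer = 100L) {
    n <- nrow(A)
    e <- rep(1, n); x <- e
    delta <- 0.1; Delta <- 3; g <- 0.9; etamax <- 0.1; eta <- etamax
    stop_tol <- tol * 0.5
    v <- x * drop(A %*% x); rk <- 1 - v
    rho_km1 <- sum(rk * rk); rout <- rho_km1; rold <- rout
    it <- 0L
    while (sqrt(rout) > stop_tol) {
        it <- it + 1L
        if (it > max_outer) return(NULL)
        k <- 0L; y <- e
        innertol <- max(eta^2 * rout, stop_tol^2)
        rho_km2 <- rho_km1
        Z <- p <- NULL
        while (rho_km1 > innertol) {
            k <- k + 1L
            if (k == 1L) {
                Z <- rk / v; p <- Z
                rho_km1 <- sum(rk * Z)
            } else {
                beta <- rho_km1 / rho_km2
                p <- Z + beta * p
            }
            w <- x * drop(A %*% (x * p)) + v * p
            denom <- sum(p * w)
            if (!is.finite(denom) || denom <= 0) return(NULL)
            alpha <- rho_km1 / denom
            ap <- alpha * p
            ynew <- y + ap
            if (min(ynew) <= delta) {
                ind <- which(ap < 0)
                gamma <- min((delta - y[ind]) / ap[ind])
                y <- y + gamma * ap
                break
            }
            if (max(ynew) >= Delta) {
                ind <- which(ynew > Delta)
                gamma <- min((Delta - y[ind]) / ap[ind])
                y <- y + gamma * ap
                break
            }
            y <- ynew
            rk <- rk - alpha * w
            rho_km2 <- rho_km1
            Z <- rk / v
            rho_km1 <- sum(rk * Z)
            if (k > 2L * n) break
        }
        x <- x * y
        v <- x * drop(A %*% x)
        rk <- 1 - v
        rho_km1 <- sum(rk * rk); rout <- rho_km1
        rat <- rout / rold; rold <- rout
        eta <- g * rat
        eta <- max(min(eta, etamax), stop_tol / sqrt(rout))
        if (any(!is.finite(x)) || any(x <= 0)) return(NULL)
    }
    x
}

# Symmetric Sinkhorn-Knopp alternating scaling; slower but unconditionally
# stable on fully supported matrices. Used when the Newton step stalls.
kr_sinkhorn <- function(A, tol = 1e-6, max_iter = 1000L) {
    n <- nrow(A)
    x <- rep(1, n)
    for (k in seq_len(max_iter)) {
        r <- x * drop(A %*% x)
        if (max(abs(r - 1)) < tol) return(x)
        x <- x / sqrt(r)
    }
    NULL
}

.kr_core <- function(counts, tol, maxIter, minNonzero, context = "matrix") {
    if (any(counts < 0)) stop("negative entries in contact matrix")
    included <- apply(counts != 0, 1L, sum) >= minNonzero
    A <- counts[included, included, drop = FALSE]
    if (!nrow(A)) stop("no bins left after the sparse-bin filter")
    x <- kr_newton(A, tol = tol)
    if (is.null(x)) x <- kr_sinkhorn(A, tol = tol, max_iter = maxIter)
    if (is.null(x))
        stop("Knight-Ruiz balancing did not converge on ", context)
    n <- nrow(counts)
    v <- rep(NA_real_, n)
    v[included] <- x
    balanced <- matrix(NA_real_, n, n)
    balanced[included, included] <- A * outer(x, x)
    list(vector = v, balanced = balanced, included = included)
}

#' @describeIn krBalance balance the counts of a `HiCMatrix`; returns the
#'   updated object with the balancing vector and balanced matrix filled.
#'   Bins with fewer than `minNonzero` nonzero entries are excluded before
#'   balancing (default 1, i.e. all-zero rows). Balanced row sums over
#'   included bins equal a common constant (1) within `tol`.
#' @param tol relative tolerance on the row-sum spread (default 1e-6).
#' @param maxIter iteration cap for the Sinkhorn fallback.
#' @param minNonzero sparse-bin filter threshold.
#' @export
setMethod("krBalance", "HiCMatrix",
    function(x, tol = 1e-6, maxIter = 1000L, minNonzero = 1L) {
        res <- .kr_core(x@counts, tol, maxIter, minNonzero,
                        context = x@chrom)
        initialize(x, balancing = res$vector, normalized = res$balanced,
                   included = res$included)
    })

#' @describeIn krBalance low-level method on a plain symmetric matrix;
#'   returns `list(vector, balanced, included)`.
#' @export
setMethod("krBalance", "matrix",
    function(x, tol = 1e-6, maxIter = 1000L, minNonzero = 1L) {
        .kr_core(x, tol, maxIter, minNonzero)
    })

#' @describeIn observedOverExpected divide each balanced entry by the mean
#'   balanced value at its genomic distance (per-diagonal mean over
#'   included bins), so that the per-distance mean of O/E is 1 wherever
#'   defined. Distances whose expected value is 0 give `NA`.
#' @export
setMethod("observedOverExpected", "HiCMatrix", function(x) {
    if (!length(x@normalized))
        stop("run krBalance() before observedOverExpected()")
    m <- x@normalized
    n <- nrow(m)
    d <- abs(row(m) - col(m))
    expected <- vapply(0:(n - 1L), function(k) {
        vals <- m[d == k]
        mean_defined(vals)
    }, numeric(1L))
    ex <- expected[d + 1L]
    oe <- m / ex
    oe[!is.finite(oe)] <- NA_real_
    initialize(x, oe = oe)
})

#' @describeIn profileCorrelation Pearson correlation of every pair of O/E
#'   rows, excluding undefined entries pairwise and the two self-contact
#'   columns of the pair; at least `minShared` shared defined entries are
#'   required (else `NA`). Constant rows give `NA` correlations.
#' @param minShared minimum shared defined entries per row pair.
#' @export
setMethod("profileCorrelation", "HiCMatrix", function(x, minShared = 3L) {
    if (!length(x@oe))
        stop("run observedOverExpected() before profileCorrelation()")
    oe <- x@oe
    n <- nrow(oe)
    pc <- matrix(NA_real_, n, n)
    inc <- which(x@included)
    for (ii in seq_along(inc)) {
        i <- inc[ii]
        pc[i, i] <- 1
        if (ii == length(inc)) break
        for (j in inc[(ii + 1L):length(inc)]) {
            keep <- which(!is.na(oe[i, ]) & !is.na(oe[j, ]))
            keep <- setdiff(keep, c(i, j))
            if (length(keep) < minShared) next
            a <- oe[i, keep]; b <- oe[j, keep]
            if (stats::sd(a) == 0 || stats::sd(b) == 0) next
            pc[i, j] <- pc[j, i] <- stats::cor(a, b)
        }
    }
    initialize(x, profileCorr = pc)
})

#' Connectivity of gene pairs from the contact-profile correlation
#'
#' Genes are assigned to Hi-C anchors (bins) by midpoint integer division;
#' the connectivity of a gene pair is the profile-correlation entry of the
#' corresponding anchor pair. Two genes sharing one anchor get connectivity
#' 1 by convention (identical profiles; configurable). Genes whose midpoint
#' lies beyond the matrix extent are skipped with a warning (`NA` rows).
#'
#' @param annotation ranked `GRanges` of genes on the matrix chromosome,
#'   sorted by rank.
#' @param hic a [HiCMatrix-class] with `profileCorr` computed.
#' @param sameBinValue connectivity assigned to same-anchor pairs.
#' @return symmetric genes x genes matrix of connectivity values, indexed
#'   like the chromosome's [CoexpressionMatrix-class].
#' @export
genePairConnectivity <- function(annotation, hic, sameBinValue = 1) {
    pc <- profileCorr(hic)
    if (!length(pc))
        stop("run profileCorrelation() before genePairConnectivity()")
    ann <- annotation[order(mcols(annotation)$rank)]
    bin <- floor(.mid0(ann) / hic@resolution) + 1L
    n <- length(ann)
    off <- bin > nrow(pc) | bin < 1L
    if (any(off)) {
        warning(sum(off), " gene(s) beyond the Hi-C matrix extent skipped")
        bin[off] <- NA_integer_
    }
    conn <- matrix(NA_real_, n, n,
                   dimnames = list(mcols(ann)$gene_id, mcols(ann)$gene_id))
    okBin <- !is.na(bin)
    conn[okBin, okBin] <- pc[bin[okBin], bin[okBin]]
    same <- outer(bin, bin, "==")
    conn[same & !is.na(same)] <- sameBinValue
    conn
}

#' Ranked connectivity versus coexpression
#'
#' Ranks gene pairs by connectivity, cuts them into `nBins` equal-count
#' groups (counts differ by at most 1; reduced when fewer pairs exist) and
#' reports the mean connectivity and mean coexpression of each group.
#'
#' @param connectivity genes x genes matrix from [genePairConnectivity()].
#' @param C matching [CoexpressionMatrix-class].
#' @param nBins number of groups (default 20).
#' @return data.frame with `bin`, `n_pairs`, `mean_connectivity`,
#'   `mean_coexpression`.
#' @export
binnedConnectivityVsCoexpression <- function(connectivity, C, nBins = 20L) {
    corr <- corrMatrix(C)
    stopifnot(all(dim(connectivity) == dim(corr)))
    up <- upper.tri(corr)
    ok <- up & is.finite(connectivity) & is.finite(corr)
    conn <- connectivity[ok]; coex <- corr[ok]
    n <- length(conn)
    if (!n)
        return(data.frame(bin = integer(), n_pairs = integer(),
                          mean_connectivity = numeric(),
                          mean_coexpression = numeric()))
    nBins <- min(as.integer(nBins), n)
    o <- order(conn)  # stable
    bin <- ceiling(seq_len(n) * nBins / n)
    data.frame(bin = seq_len(nBins),
               n_pairs = as.integer(table(bin)),
               mean_connectivity = as.numeric(tapply(conn[o], bin, mean)),
               mean_coexpression = as.numeric(tapply(coex[o], bin, mean)))
}

#' Connectivity of COD gene pairs versus the rest
#'
#' Compares contact-profile similarity (connectivity) for (i) gene pairs
#' inside the same COD versus all remaining pairs versus pairs inside the
#' same randomized (inverted) COD, and (ii) pairs spanning two coexpressed
#' CODs (inter-COD classification `positive` or `negative` under the
#' +-0.2 rule) versus the rest versus pairs spanning two randomized CODs.
#' Group (ii) is skipped with a message when the chromosome has no
#' coexpressed COD pair.
#'
#' @param cods [DomainSet-class] of CODs with rank metadata.
#' @param C matching [CoexpressionMatrix-class].
#' @param connectivity matrix from [genePairConnectivity()].
#' @param annotation ranked `GRanges` (used for the inversion null).
#' @param sigThreshold classification cutoff for coexpressed COD pairs.
#' @param nTests Bonferroni multiplier per comparison table.
#' @return list with elements `intra` and `coexpressedInter` (each holding
#'   `populations` and `tests`), the latter `NULL` when skipped.
#' @export
codConnectivityComparison <- function(cods, C, connectivity, annotation,
                                      sigThreshold = 0.2, nTests = NULL) {
    gr <- domainRanges(cods)
    if (!length(gr))
        return(list(intra = NULL, coexpressedInter = NULL))
    n <- nrow(connectivity)
    membership <- .rank_membership(gr, n)
    rnd <- invertDomains(cods, annotation = annotation)
    membershipR <- .rank_membership(domainRanges(rnd), n)
    pops <- .population_split(connectivity, membership)
    popsR <- .population_split(connectivity, membershipR)
    intraGroups <- list(intra_cod = pops$intra,
                        rest = c(pops$inter, pops$rest),
                        intra_random = popsR$intra)
    intraGroups <- intraGroups[lengths(intraGroups) > 0]
    intra <- list(populations = intraGroups,
                  tests = compareDistributions(intraGroups, nTests = nTests))
    summ <- codCoexpressionSummary(cods, C, sigThreshold = sigThreshold)
    sig <- summ$pairs[!is.na(summ$pairs$classification) &
                      summ$pairs$classification != "neutral", , drop = FALSE]
    coexpr <- NULL
    if (nrow(sig)) {
        fr <- mcols(gr)$firstRank; lr <- mcols(gr)$lastRank
        inSig <- matrix(FALSE, n, n)
        for (k in seq_len(nrow(sig))) {
            ra <- fr[sig$cod_a[k]]:lr[sig$cod_a[k]]
            rb <- fr[sig$cod_b[k]]:lr[sig$cod_b[k]]
            inSig[ra, rb] <- TRUE; inSig[rb, ra] <- TRUE
        }
        up <- upper.tri(connectivity)
        sigVals <- connectivity[up & inSig & is.finite(connectivity)]
        restVals <- connectivity[up & !inSig & is.finite(connectivity)]
        groups <- list(coexpressed_inter = sigVals, rest = restVals,
                       inter_random = popsR$inter)
        groups <- groups[lengths(groups) > 0]
        coexpr <- list(populations = groups,
                       tests = compareDistributions(groups, nTests = nTests))
    } else {
        message("no coexpressed COD pair on ", chrom(C),
                "; skipping group (ii)")
    }
    list(intra = intra, coexpressedInter = coexpr)
}

.rank_membership <- function(gr, n) {
    membership <- rep(NA_integer_, n)
    fr <- mcols(gr)$firstRank; lr <- mcols(gr)$lastRank
    for (k in seq_along(gr)) {
        if (is.na(fr[k]) || is.na(lr[k])) next
        membership[fr[k]:lr[k]] <- k
    }
    membership
}
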