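.sym <- function(v, n) {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- v
    m + t(m)
}

test_that("KR balancing equalizes row sums", {
    # all off-diagonal entries equal: already balanced, constant vector
    m <- .sym(rep(1, 3), 3)
    out <- krBalance(m)
    expect_equal(diff(range(out$vector)), 0, tolerance = 1e-8)
    rs <- rowSums(out$balanced)
    expect_lt(max(abs(rs - rs[1])), 1e-8)

    # 3x3 toy against a plain Sinkhorn-Knopp oracle run to convergence
    m <- matrix(c(0, 2, 1, 2, 0, 4, 1, 4, 0), 3)
    out <- krBalance(m, tol = 1e-9)
    x <- rep(1, 3)
    for (k in 1:100000) {
        r <- x * drop(m %*% x)
        if (max(abs(r - 1)) < 1e-12) break
        x <- x / sqrt(r)
    }
    expect_equal(out$vector, x, tolerance = 1e-5)
    expect_lt(max(abs(rowSums(out$balanced) - 1)), 1e-8)

    # random 50-bin symmetric matrices balance within 1e-6
    set.seed(8)
    for (rep in 1:3) {
        m <- .sym(rexp(choose(50, 2)) * 10, 50)
        out <- krBalance(m)
        expect_lt(max(abs(rowSums(out$balanced) - 1)), 1e-6)
        expect_true(all(out$vector > 0))
    }
})

test_that("all-zero bins are excluded and the remainder balanced", {
    m <- .sym(rexp(choose(6, 2)), 6)
    m[3, ] <- m[, 3] <- 0
    out <- krBalance(m)
    expect_false(out$included[3])
    expect_true(is.na(out$vector[3]))
    rs <- rowSums(out$balanced[out$included, out$included])
    expect_lt(max(abs(rs - 1)), 1e-6)
})

test_that("balancing is invariant to global count scale", {
    set.seed(4)
    m <- .sym(rexp(choose(20, 2)), 20)
    b1 <- krBalance(m)$balanced
    b2 <- krBalance(2 * m)$balanced
    expect_equal(b1, b2, tolerance = 1e-5)
    expect_error(krBalance(-m), "negative")
})

test_that("O/E removes the distance trend exactly", {
    # matrix constant along each diagonal -> O/E all 1
    n <- 6
    m <- outer(1:n, 1:n, function(i, j) 10 / (1 + abs(i - j)))
    h <- initialize(hicMatrix(m), normalized = m,
                    included = rep(TRUE, n))
    oe <- oeMatrix(observedOverExpected(h))
    expect_equal(oe, matrix(1, n, n), tolerance = 1e-12)

    # hand-worked toy: first-diagonal entries (2, 4, 2, 4) -> expected 3
    m <- matrix(0, 5, 5)
    m[cbind(1:4, 2:5)] <- c(2, 4, 2, 4)
    m <- m + t(m); diag(m) <- 6
    h <- initialize(hicMatrix(m), normalized = m,
                    included = rep(TRUE, 5))
    oe <- oeMatrix(observedOverExpected(h))
    expect_equal(oe[cbind(1:4, 2:5)], c(2, 4, 2, 4) / 3, tolerance = 1e-12)

    # per-diagonal O/E means are 1 wherever defined
    set.seed(12)
    m <- .sym(rexp(choose(30, 2)), 30); diag(m) <- rexp(30)
    h <- initialize(hicMatrix(m), normalized = m,
                    included = rep(TRUE, 30))
    oe <- oeMatrix(observedOverExpected(h))
    d <- abs(row(oe) - col(oe))
    for (k in 0:29)
        expect_equal(mean(oe[d == k]), 1, tolerance = 1e-9)
})

test_that("profile correlation matches a brute-force Pearson on O/E rows", {
    set.seed(77)
    n <- 12
    oe <- .sym(runif(choose(n, 2), 0.2, 2), n); diag(oe) <- 1
    oe[2, ] <- oe[3, ] * 1.7          # duplicate profile up to scale
    oe[, 2] <- oe[, 3] * 1.7
    h <- initialize(hicMatrix(matrix(1, n, n)), normalized = oe, oe = oe,
                    included = rep(TRUE, n))
    pc <- profileCorr(profileCorrelation(h))
    expect_true(isSymmetric(pc))
    expect_equal(diag(pc), rep(1, n))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
        keep <- setdiff(seq_len(n), c(i, j))
        expect_equal(pc[i, j], pearson_oracle(oe[i, keep], oe[j, keep]),
                     tolerance = 1e-12)
    }
    # exact duplicates correlate to 1 once self columns are dropped
    oe[2, ] <- oe[3, ]; oe[, 2] <- oe[, 3]; oe[2, 2] <- 1
    h <- initialize(hicMatrix(matrix(1, n, n)), normalized = oe, oe = oe,
                    included = rep(TRUE, n))
    pc <- profileCorr(profileCorrelation(h))
    expect_equal(pc[2, 3], 1, tolerance = 1e-12)
})

test_that("genes map to Hi-C anchors by midpoint division", {
    n <- 6
    pc <- .sym(runif(choose(n, 2), -1, 1), n); diag(pc) <- 1
    h <- initialize(hicMatrix(matrix(1, n, n), resolution = 1e5),
                    normalized = pc, oe = pc, profileCorr = pc,
                    included = rep(TRUE, n))
    # genes at 150 kb and 420 kb -> anchors 2 and 5 (bins 1-based)
    ann <- orderGenes(geneAnnotation(c("a", "b"), "chr1",
                                     c(140001, 410001), c(160000, 430000)))
    conn <- genePairConnectivity(ann, h)
    expect_equal(conn["a", "b"], pc[2, 5])
    # same-anchor pair gets connectivity 1 by convention
    ann2 <- orderGenes(geneAnnotation(c("a", "b"), "chr1",
                                      c(110001, 140001), c(120000, 150000)))
    conn2 <- genePairConnectivity(ann2, h)
    expect_equal(conn2["a", "b"], 1)
    # gene beyond the matrix extent is skipped with a warning
    ann3 <- orderGenes(geneAnnotation(c("a", "b"), "chr1",
                                      c(1, 9e5 + 1), c(1e4, 9.2e5)))
    expect_warning(conn3 <- genePairConnectivity(ann3, h), "extent")
    expect_true(all(is.na(conn3["b", ])))
    # 10 genes against hand binning
    set.seed(3)
    starts <- sample.int(5.8e5, 10)
    ann4 <- orderGenes(geneAnnotation(sprintf("g%02d", 1:10), "chr1",
                                      starts, starts + 1e4))
    conn4 <- genePairConnectivity(ann4, h)
    ann4 <- ann4[order(mcols(ann4)$rank)]
    bins <- floor(((start(ann4) - 1 + end(ann4)) / 2) / 1e5) + 1
    for (i in 1:9) for (j in (i + 1):10) {
        want <- if (bins[i] == bins[j]) 1 else pc[bins[i], bins[j]]
        expect_equal(conn4[i, j], want)
    }
})

test_that("ranked connectivity bins have equal counts and track identity coupling", {
    n <- 40 * 2  # pairs from a 13-gene toy clipped below
    set.seed(6)
    ng <- 13
    conn <- .sym(runif(choose(ng, 2), -1, 1), ng); diag(conn) <- 1
    C <- coexpressionMatrix(conn)   # coexpression == connectivity
    out <- binnedConnectivityVsCoexpression(conn, C, nBins = 20)
    expect_lte(diff(range(out$n_pairs)), 1L)
    expect_equal(sum(out$n_pairs), choose(ng, 2))
    expect_equal(out$mean_connectivity, out$mean_coexpression,
                 tolerance = 1e-12)
    expect_true(!is.unsorted(out$mean_connectivity))
    # 40 pairs into 20 bins -> 2 per bin
    sub <- binnedConnectivityVsCoexpression(conn[1:10, 1:10],
        coexpressionMatrix(conn[1:10, 1:10]), nBins = 20)
    expect_true(all(sub$n_pairs >= 2 | length(sub$n_pairs) < 20))
})

test_that("triplet I/O round-trips the counts", {
    set.seed(10)
    m <- .sym(rpois(choose(8, 2), 4), 8); diag(m) <- rpois(8, 2)
    h <- hicMatrix(m, chrom = "chrT", resolution = 1e5)
    path <- withr::local_tempfile(fileext = ".txt")
    writeHicTriplets(h, path)
    back <- readHicTriplets(path, resolution = 1e5, chrom = "chrT",
                            nBins = 8)
    expect_equal(contactCounts(back), m)
})

test_that("two-compartment synthetic maps recover the checkerboard", {
    blocks <- data.frame(firstRank = c(1, 21, 41, 61),
                         lastRank = c(20, 40, 60, 80), rhoIntra = 0.6)
    cp <- data.frame(blockA = c(1, 2), blockB = c(3, 4), rhoInter = 0.3)
    spec <- syntheticSpec(nGenes = 80, nSamples = 100, blocks = blocks,
                          coupledPairs = cp, seed = 23)
    hic <- generateHic(spec)
    h <- profileCorrelation(observedOverExpected(krBalance(hic$hic)))
    pc <- profileCorr(h)
    comp <- hic$compartments
    same <- outer(comp, comp, "==")
    up <- upper.tri(pc) & !is.na(same) & same
    across <- upper.tri(pc) & !is.na(same) & !same
    expect_gt(mean(pc[up], na.rm = TRUE), 0)
    expect_lt(mean(pc[across], na.rm = TRUE), 0)
    expect_gt(mean(pc[up] > 0, na.rm = TRUE), 0.85)
    expect_gt(mean(pc[across] < 0, na.rm = TRUE), 0.85)
})

test_that("COD connectivity comparison separates coupled structure", {
    blocks <- data.frame(firstRank = c(3, 21, 45, 63),
                         lastRank = c(14, 34, 56, 76), rhoIntra = 0.6)
    cp <- data.frame(blockA = c(1, 2), blockB = c(3, 4), rhoInter = 0.3)
    spec <- syntheticSpec(nGenes = 85, nSamples = 100, blocks = blocks,
                          coupledPairs = cp, seed = 29)
    sim <- generateExpression(spec)
    C <- buildCoexpressionMatrix(sim$expr)[["chrS"]]
    hic <- generateHic(spec)
    h <- profileCorrelation(observedOverExpected(krBalance(hic$hic)))
    conn <- genePairConnectivity(sim$annotation, h)
    cods <- callCods(C, sim$annotation)$cods
    out <- codConnectivityComparison(cods, C, conn, sim$annotation)
    expect_gt(median(out$intra$populations$intra_cod),
              median(out$intra$populations$rest))
    row <- out$intra$tests[out$intra$tests$group_a == "intra_cod" &
                           out$intra$tests$group_b == "rest", ]
    expect_lt(row$p_adjusted, 0.01)
    # coexpressed (coupled) COD pairs share compartments: high connectivity
    expect_false(is.null(out$coexpressedInter))
    expect_gt(median(out$coexpressedInter$populations$coexpressed_inter),
              median(out$coexpressedInter$populations$rest))
})
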