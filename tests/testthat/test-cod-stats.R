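.two_cod_set <- function(ranks, ann) {
    gr <- GRanges("chrS", IRanges(
        start(ann)[vapply(ranks, min, integer(1))],
        end(ann)[vapply(ranks, max, integer(1))]))
    mcols(gr)$firstRank <- vapply(ranks, min, integer(1))
    mcols(gr)$lastRank <- vapply(ranks, max, integer(1))
    mcols(gr)$nGenes <- lengths(ranks)
    mcols(gr)$geneIds <- CharacterList(lapply(ranks, function(r)
        mcols(ann)$gene_id[r]))
    domainSet(gr, kind = "COD")
}

test_that("inter-COD averages and the +-0.2 classification", {
    ann <- toy_annotation(10)
    # cross entries all zero -> neutral
    corr <- block_corr(10, list(1:3, 6:8), rho = 0.9)
    cods <- .two_cod_set(list(1:3, 6:8), ann)
    summ <- codCoexpressionSummary(cods, coexpressionMatrix(corr))
    expect_equal(summ$pairs$avg_inter_coexpression, 0)
    expect_equal(summ$pairs$classification, "neutral")
    # cross entries all 0.25 -> positive at the inclusive 0.2 rule
    corr[1:3, 6:8] <- 0.25; corr[6:8, 1:3] <- 0.25
    summ <- codCoexpressionSummary(cods, coexpressionMatrix(corr))
    expect_equal(summ$pairs$avg_inter_coexpression, 0.25)
    expect_equal(summ$pairs$classification, "positive")
    expect_equal(summ$intra$avg_intra_coexpression, c(0.9, 0.9))
    # midpoint distance: blocks span genes 1-3 and 6-8 on the 100 kb grid
    gr <- domainRanges(cods)
    expect_equal(summ$pairs$distance,
                 abs(mean(c(start(gr)[1], end(gr)[1])) -
                     mean(c(start(gr)[2], end(gr)[2]))))
})

test_that("pair populations match exhaustive enumeration", {
    set.seed(21)
    n <- 30
    r <- matrix(runif(n * n, -1, 1), n); r <- (r + t(r)) / 2; diag(r) <- 1
    ann <- toy_annotation(n)
    ranks <- list(3:7, 12:17, 24:28)
    cods <- .two_cod_set(ranks, ann)
    pops <- codCoexpressionSummary(cods, coexpressionMatrix(r))$populations
    # brute force over all gene pairs
    member <- rep(NA_integer_, n)
    for (k in seq_along(ranks)) member[ranks[[k]]] <- k
    intra <- inter <- rest <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
        v <- r[i, j]
        if (!is.na(member[i]) && !is.na(member[j])) {
            if (member[i] == member[j]) intra <- c(intra, v)
            else inter <- c(inter, v)
        } else rest <- c(rest, v)
    }
    expect_equal(sort(pops$intra), sort(intra))
    expect_equal(sort(pops$inter), sort(inter))
    expect_equal(sort(pops$rest), sort(rest))
    # pair counts recompose the global pair count
    expect_equal(length(pops$intra) + length(pops$inter) +
                 length(pops$rest), choose(n, 2))
})

test_that("distance binning splits ranked pairs into equal-count groups", {
    pairs <- data.frame(distance = 1:100,
                        avg_inter_coexpression = runif(100))
    out <- distanceBinnedCoexpression(pairs, 50)
    expect_equal(out$n_pairs, rep(2L, 50))
    # hand-enumerated example: distances 1..10, coexpression d/10, 5 bins
    pairs <- data.frame(distance = 1:10,
                        avg_inter_coexpression = (1:10) / 10)
    out <- distanceBinnedCoexpression(pairs, 5)
    expect_equal(out$mean_coexpression, c(0.15, 0.35, 0.55, 0.75, 0.95))
    expect_equal(out$mean_distance, c(1.5, 3.5, 5.5, 7.5, 9.5))
    # clamp: more bins than pairs
    out <- distanceBinnedCoexpression(pairs[1:3, ], 50)
    expect_equal(nrow(out), 3L)
    expect_equal(out$n_pairs, rep(1L, 3))
    # bin counts never differ by more than 1
    pairs <- data.frame(distance = runif(103),
                        avg_inter_coexpression = runif(103))
    out <- distanceBinnedCoexpression(pairs, 50)
    expect_lte(diff(range(out$n_pairs)), 1L)
})

test_that("coordinate inversion is an isometry and an involution", {
    gr <- GRanges("chrS", IRanges(c(1, 31), c(10, 45)))
    ds <- domainSet(gr, kind = "COD")
    inv <- invertDomains(ds, chromLength = 100)
    # [0,10) on L=100 -> [90,100)
    expect_equal(start(domainRanges(inv)), c(56, 91))
    expect_equal(end(domainRanges(inv)), c(70, 100))
    # gaps preserved: 31-10 = 21 -> 91-70 = 21
    expect_equal(diff(c(end(domainRanges(inv))[1],
                        start(domainRanges(inv))[2])), 21)
    expect_equal(sort(width(domainRanges(inv))), sort(width(gr)))
    # involution
    inv2 <- invertDomains(inv, chromLength = 100)
    expect_equal(start(domainRanges(inv2)), start(gr))
    expect_equal(end(domainRanges(inv2)), end(gr))
    expect_equal(domainKind(inv), "random")
})

test_that("inverted domains lose the planted coexpression signal", {
    real <- rand <- c()
    for (s in 1:3) {
        spec <- plantedBlockSpec(gapGenes = c(4, 11, 6, 15),
                                 flankGenes = c(2, 13), seed = s)
        sim <- generateExpression(spec)
        C <- buildCoexpressionMatrix(sim$expr)[["chrS"]]
        res <- callCods(C, sim$annotation)
        inv <- invertDomains(res$cods, annotation = sim$annotation)
        mc <- mcols(domainRanges(res$cods))
        mi <- mcols(domainRanges(inv))
        real <- c(real, vapply(seq_along(mc$firstRank), function(k)
            averagePairwiseCoexpression(C,
                mc$firstRank[k]:mc$lastRank[k])$average, numeric(1)))
        rand <- c(rand, vapply(seq_along(mi$firstRank), function(k) {
            if (is.na(mi$firstRank[k]) || mi$lastRank[k] == mi$firstRank[k])
                return(NA_real_)
            averagePairwiseCoexpression(C,
                mi$firstRank[k]:mi$lastRank[k])$average
        }, numeric(1)))
    }
    rand <- rand[!is.na(rand)]
    expect_gt(mean(real), mean(rand))
    expect_lt(wilcox.test(real, rand)$p.value, 0.01)
})

test_that("border shifting preserves interior sizes and clips at ends", {
    gr <- GRanges("chrS", IRanges(c(200001, 400001), c(300000, 500000)))
    ds <- domainSet(gr, kind = "COD")
    sh <- shiftDomains(ds, shift = 1e5, direction = "downstream",
                       chromLength = 1e6)
    expect_equal(start(domainRanges(sh)), c(300001, 500001))
    expect_equal(end(domainRanges(sh)), c(400000, 600000))
    expect_equal(width(domainRanges(sh)), width(gr))
    # domain pushed fully off the chromosome is dropped with a warning
    ds2 <- domainSet(GRanges("chrS", IRanges(1, 50000)), kind = "COD")
    expect_warning(sh2 <- shiftDomains(ds2, 1e5, "upstream",
                                       chromLength = 1e6), "dropped")
    expect_equal(nDomains(sh2), 0L)
})

test_that("Mann-Whitney comparisons match exact enumeration and Bonferroni caps", {
    # fully separated n = m = 4: exact two-sided p = 2/70
    x <- c(1, 2, 3, 4); y <- c(10, 11, 12, 13)
    out <- compareDistributions(list(a = x, b = y), nTests = 1)
    expect_equal(out$statistic, 0)
    expect_equal(out$p_value, mw_exact_oracle(x, y), tolerance = 1e-12)
    expect_equal(out$p_value, 2 / 70, tolerance = 1e-12)
    # random small groups agree with the enumeration oracle too
    set.seed(5)
    x <- rnorm(5); y <- rnorm(6)
    out <- compareDistributions(list(a = x, b = y), nTests = 1)
    expect_equal(out$p_value, mw_exact_oracle(x, y), tolerance = 1e-12)
    # no shift: p in the non-significant region
    out <- compareDistributions(list(a = c(1, 2, 3), b = c(1, 2, 3)))
    expect_gt(out$p_value, 0.99)
    # Bonferroni multiplies and caps at 1
    out <- compareDistributions(list(a = rnorm(10), b = rnorm(10) + 0.1,
                                     c = rnorm(10)), nTests = 23)
    expect_equal(out$p_adjusted, pmin(1, out$p_value * 23))
    # identical constant groups
    out <- compareDistributions(list(a = rep(2, 4), b = rep(2, 4)))
    expect_equal(out$p_value, 1)
})
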