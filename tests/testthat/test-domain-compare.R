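.bare_set <- function(starts, ends, kind = "COD", chrom = "chrS",
                      checkOverlap = FALSE) {
    domainSet(GRanges(chrom, IRanges(starts, ends)), kind = kind,
              checkOverlap = checkOverlap)
}

test_that("length matching follows the 80%-of-length rule", {
    cod <- .bare_set(1, 1e6)
    expect_true(matchDomainsByLength(cod, .bare_set(1, 1e6))$matched)
    # TAD covering 850 kb of a 1 Mb COD: 85% -> match
    expect_true(matchDomainsByLength(cod,
        .bare_set(150001, 1e6, "TAD"))$matched)
    # 50% overlap -> no match
    expect_false(matchDomainsByLength(cod,
        .bare_set(500001, 2e6, "TAD"))$matched)
    # empty sets
    empty <- domainSet(GRanges(character(), IRanges()), kind = "TAD")
    expect_equal(matchDomainsByLength(cod, empty)$nMatched, 0L)
})

test_that("length matching is directional", {
    a <- .bare_set(1, 1e6)                 # 1 Mb
    b <- .bare_set(1, 2e5, "TAD")          # 200 kb inside a
    expect_false(matchDomainsByLength(a, b)$matched)  # 20% of a
    expect_true(matchDomainsByLength(b, a)$matched)   # 100% of b
})

test_that("boundary matching uses a per-domain bp tolerance", {
    # 1 Mb COD ending at 2.00 Mb -> tolerance 100 kb
    cod <- .bare_set(1e6 + 1, 2e6)
    near <- .bare_set(1.05e6, 2.09e6, "TAD")
    out <- matchBoundaries(cod, near)
    expect_equal(out$matched, c(TRUE, TRUE))
    far <- .bare_set(1.2e6, 2.15e6, "TAD")
    out <- matchBoundaries(cod, far)
    expect_equal(out$matched, c(FALSE, FALSE))
    # identical sets match everywhere
    out <- matchBoundaries(cod, cod)
    expect_equal(out$nMatched, out$nTotal)
})

test_that("gene-count boundary tolerance works in rank units", {
    mk <- function(fr, lr) {
        gr <- GRanges("chrS", IRanges(fr * 1e5, lr * 1e5 + 5e4))
        mcols(gr)$firstRank <- fr; mcols(gr)$lastRank <- lr
        domainSet(gr, kind = "COD", checkOverlap = FALSE)
    }
    a <- mk(11L, 40L)   # 30 genes -> tolerance 3 ranks
    expect_true(all(matchBoundaries(a, mk(9L, 42L),
                                    unit = "genes")$matched))
    expect_false(any(matchBoundaries(a, mk(7L, 44L),
                                     unit = "genes")$matched))
})

test_that("gene-composition matching uses the inclusive 80% rule", {
    mk <- function(ids, start = 1, end = 100) {
        gr <- GRanges("chrS", IRanges(start, end))
        mcols(gr)$geneIds <- CharacterList(list(ids))
        domainSet(gr, kind = "COD", checkOverlap = FALSE)
    }
    g10 <- sprintf("g%02d", 1:10)
    expect_true(matchDomainsByGenes(mk(g10), mk(g10))$matched)
    expect_true(matchDomainsByGenes(mk(g10), mk(g10[1:8]))$matched)
    expect_false(matchDomainsByGenes(mk(g10), mk(g10[1:7]))$matched)
    expect_error(matchDomainsByGenes(.bare_set(1, 10), mk(g10)),
                 "gene lists")
})

test_that("overlap and boundary operations agree with a brute-force oracle", {
    set.seed(13)
    for (rep in 1:5) {
        nA <- sample(30:100, 1); nB <- sample(30:100, 1)
        sA <- sort(sample.int(1e6, nA)); wA <- sample(1e3:5e4, nA, TRUE)
        sB <- sort(sample.int(1e6, nB)); wB <- sample(1e3:5e4, nB, TRUE)
        a <- .bare_set(sA, sA + wA, "TAD")
        b <- .bare_set(sB, sB + wB, "TAD")
        ga <- domainRanges(a); gb <- domainRanges(b)
        out <- matchDomainsByLength(a, b, minLengthFrac = 0.5)
        oracle <- vapply(seq_along(ga), function(i)
            any(vapply(seq_along(gb), function(j)
                overlap_len(start(ga)[i], end(ga)[i],
                            start(gb)[j], end(gb)[j]) >=
                    0.5 * width(ga)[i], logical(1))), logical(1))
        expect_equal(out$matched, oracle)
        bnd <- matchBoundaries(a, b, 0.10)
        bOracle <- c()
        for (i in seq_along(ga)) {
            tol <- 0.10 * width(ga)[i]
            for (p in c(start(ga)[i], end(ga)[i]))
                bOracle <- c(bOracle,
                             any(abs(c(start(gb), end(gb)) - p) < tol))
        }
        expect_equal(bnd$matched, bOracle)
    }
})

test_that("midpoint gene assignment follows the half-open convention", {
    # gene [100, 300) in BED terms: 1-based [101, 300], midpoint 200
    ann <- orderGenes(geneAnnotation("g1", "chrS", 101, 300))
    expect_equal(assignGenesToDomains(ann,
        .bare_set(151, 250)), 1L)                 # domain [150, 250)
    # midpoint exactly at the half-open end of [100, 200) -> outside
    expect_true(is.na(assignGenesToDomains(ann, .bare_set(101, 200))))
    # brute-force scan on random genes and domains
    set.seed(31)
    starts <- sort(sample.int(1e5, 20)) * 10
    ann <- orderGenes(geneAnnotation(sprintf("g%02d", 1:20), "chrS",
                                     starts, starts + 5000))
    ds <- .bare_set(c(1e4, 3e5, 6e5), c(2e5, 5e5, 9e5))
    got <- assignGenesToDomains(ann, ds)
    ann <- ann[order(mcols(ann)$rank)]
    mid <- (start(ann) - 1 + end(ann)) / 2
    for (g in 1:20) {
        hit <- which(mid[g] >= c(1e4, 3e5, 6e5) - 1 &
                     mid[g] < c(2e5, 5e5, 9e5))
        expect_equal(got[g], if (length(hit)) hit else NA_integer_)
    }
    # at most one domain per gene
    expect_true(all(table(got[!is.na(got)]) >= 1))
})

test_that("hypergeometric overlap test is exact", {
    # universe 10, category 5, draw 4, all 4 hits: 5/210
    expect_equal(geneSetOverlapTest(4, 4, 5, 10), 5 / 210,
                 tolerance = 1e-12)
    # enumeration oracle for a mid-range case
    p_oracle <- sum(vapply(2:4, function(k)
        choose(5, k) * choose(5, 4 - k), numeric(1))) / choose(10, 4)
    expect_equal(geneSetOverlapTest(2, 4, 5, 10), p_oracle,
                 tolerance = 1e-12)
    expect_gt(geneSetOverlapTest(2, 4, 5, 10), 0.5)
    # category equals universe: certainty
    expect_equal(geneSetOverlapTest(4, 4, 10, 10), 1)
    expect_error(geneSetOverlapTest(5, 4, 5, 10), "inconsistent")
})

test_that("chi-square coincidence test matches the textbook formula", {
    out <- boundaryCoincidenceChi2(30, 60, 30, 60)
    expect_equal(out$statistic, 0)
    expect_equal(out$p_value, 1)
    # hand-computed Pearson statistic for (90,10 / 50,50)
    tab <- matrix(c(90, 10, 50, 50), 2, byrow = TRUE)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi2 <- sum((tab - E)^2 / E)
    out <- boundaryCoincidenceChi2(90, 100, 50, 100)
    expect_equal(out$statistic, chi2, tolerance = 1e-12)
    expect_equal(out$p_value, pchisq(chi2, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_error(boundaryCoincidenceChi2(-1, 10, 5, 10), "negative")
    expect_warning(out <- boundaryCoincidenceChi2(0, 0, 0, 10), "margin")
    expect_true(is.na(out$p_value))
})

test_that("TADs coinciding with coexpression blocks show an intra excess", {
    sim <- generateExpression(plantedBlockSpec(
        gapGenes = c(4, 11, 6, 15), flankGenes = c(2, 13), seed = 17))
    C <- buildCoexpressionMatrix(sim$expr)[["chrS"]]
    ann <- sim$annotation
    # TADs drawn over the planted blocks
    tads <- domainSet(granges(domainRanges(sim$truth)), kind = "TAD")
    out <- intraVsInterDomainCoexpression(tads, C, ann)
    expect_gt(mean(out$populations$intra), mean(out$populations$inter))
    expect_gt(mean(out$populations$intra),
              mean(out$populations$random_intra))
    row <- out$tests[out$tests$group_a == "intra" &
                     out$tests$group_b == "random_intra", ]
    expect_lt(row$p_adjusted, 0.01)
    # TADs independent of the blocks: intra ~ random-intra
    offs <- c(5, 20, 40, 60) * 1e5
    indep <- domainSet(GRanges("chrS", IRanges(offs + 1, offs + 8e5)),
                       kind = "TAD", checkOverlap = FALSE)
    out2 <- intraVsInterDomainCoexpression(indep, C, ann)
    expect_lt(abs(mean(out2$populations$intra) -
                  mean(out2$populations$random_intra)), 0.15)
    # empty set
    empty <- domainSet(GRanges(character(), IRanges()), kind = "TAD")
    expect_message(out3 <- intraVsInterDomainCoexpression(empty, C, ann),
                   "empty")
    expect_null(out3)
})
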