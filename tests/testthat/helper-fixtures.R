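# Shared fixtures, built in code.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(withr)
})

# A block-structured correlation matrix: `blocks` is a list of rank
# vectors, each filled with `rho`; background 0; unit diagonal.
block_corr <- function(n, blocks, rho = 0.8, background = 0) {
    m <- matrix(background, n, n)
    for (b in blocks) m[b, b] <- rho
    diag(m) <- 1
    m
}

# Evenly spaced toy annotation on one chromosome.
toy_annotation <- function(n, chrom = "chrS", spacing = 1e5, len = 2e4) {
    starts <- (seq_len(n) - 1L) * spacing + 1
    orderGenes(geneAnnotation(sprintf("g%04d", seq_len(n)), chrom,
                              starts, starts + len - 1))
}

# Independent Pearson oracle: textbook sample covariance / sd formula.
pearson_oracle <- function(x, y) {
    n <- length(x)
    sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
    sxy / (stats::sd(x) * stats::sd(y))
}

# Independent binsignal oracle: literal double sum over the U x D block
# with truncation at the ends, skipping undefined entries.
binsignal_oracle <- function(corr, i, w) {
    n <- nrow(corr)
    U <- max(1, i - w + 1):i
    D <- if (i + 1 > n) integer() else (i + 1):min(n, i + w)
    if (!length(D)) return(NA_real_)
    vals <- c()
    for (l in U) for (m in D) vals <- c(vals, corr[l, m])
    vals <- vals[is.finite(vals)]
    if (!length(vals)) NA_real_ else sum(vals) / length(vals)
}

# Pooled-variance two-sample t-test oracle (textbook formula).
pooled_t_oracle <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
        (nx + ny - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    2 * stats::pt(-abs(t), df = nx + ny - 2)
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mw_exact_oracle <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    nx <- length(x)
    obsU <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    combos <- utils::combn(length(pooled), nx)
    Us <- apply(combos, 2, function(idx)
        sum(r[idx]) - nx * (nx + 1) / 2)
    EU <- nx * length(y) / 2
    mean(abs(Us - EU) >= abs(obsU - EU) - 1e-12)
}

# Brute-force interval tools on 1-based closed intervals.
overlap_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2) + 1)
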