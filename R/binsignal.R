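#' Compute the binsignal track
#'
#' For gene `i`, binsignal is the mean of the `w x w` block of correlation
#' coefficients between the upstream window `U = {i-w+1, ..., i}` and the
#' downstream window `D = {i+1, ..., i+w}`:
#' `binsignal(i) = 1/w^2 * sum_l sum_m C(U(l), D(m))`.
#' Because `U` ends at gene `i` and `D` starts at gene `i + 1`, the value
#' measures coexpression across the junction between genes `i` and `i + 1`;
#' it is high inside coexpression domains and drops at their boundaries.
#'
#' At chromosome ends windows truncate to the available genes and the mean
#' is taken over the existing block; undefined entries (zero-variance genes)
#' are excluded and the divisor reduced accordingly. The value is `NA` at
#' the last rank (empty downstream window) and wherever no defined entry
#' remains.
#'
#' @param C a [CoexpressionMatrix-class].
#' @param w window size in genes (default 4).
#' @param threshold classification cutoff stored with the track
#'   (default 0.15).
#' @return a [BinSignalTrack-class].
#' @export
computeBinsignal <- function(C, w = 4L, threshold = 0.15) {
    corr <- corrMatrix(C)
    n <- nrow(corr)
    w <- as.integer(w)
    if (n <= w)
        stop("chromosome must have more genes than the window size")
    signal <- rep(NA_real_, n)
    for (i in seq_len(n - 1L)) {
        U <- max(1L, i - w + 1L):i
        D <- (i + 1L):min(n, i + w)
        signal[i] <- mean_defined(corr[U, D])
    }
    new("BinSignalTrack", chrom = chrom(C), w = w, threshold = threshold,
        signal = signal, geneIds = geneIds(C))
}

#' Boundary Student t-test
#'
#' Two-sided two-sample Student t-test (pooled variance) comparing the
#' binsignal values of the `tWindow` genes ending at gene `i` against those
#' of the `tWindow` genes following it. Windows truncate at chromosome ends
#' and undefined values are dropped; at least two defined values per side
#' are required (otherwise `NA`). Two constant and equal windows give
#' `p = 1` by convention.
#'
#' @param track a [BinSignalTrack-class].
#' @param i gene rank at which to evaluate the test.
#' @param tWindow number of binsignal values per side (default 4, the
#'   published choice, independent of the binsignal window `w`).
#' @return the two-sided p-value.
#' @export
boundaryTest <- function(track, i, tWindow = 4L) {
    s <- binsignal(track)
    n <- length(s)
    tWindow <- as.integer(tWindow)
    x <- s[max(1L, i - tWindow + 1L):i]
    y <- if (i + 1L > n) numeric() else s[(i + 1L):min(n, i + tWindow)]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L)
        return(NA_real_)
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
        return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    stats::t.test(x, y, var.equal = TRUE)$p.value
}
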