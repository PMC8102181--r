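#' Round half away from zero
#'
#' Reported percentages follow the printed style of clinical MRD tables:
#' one decimal, halves rounded up (so 70.95 prints as 71.0, not base R's
#' banker's rounding).
#'
#' @param x Numeric vector.
#' @param digits Integer number of decimal places (default 1).
#' @return Numeric vector rounded half-up.
#' @examples
#' roundHalfUp(c(0.25, 0.35), 1)  # 0.3 0.4
#' @export
roundHalfUp <- function(x, digits = 1L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector \code{c(lower, upper)}.
#' @export
wilsonInterval <- function(x, n, conf = 0.95) {
    stopifnot(n > 0, x >= 0, x <= n)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    p <- x / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

## Derive a stream of sub-seeds (< 2^31) from one master seed.
deriveSeeds <- function(seed, n) {
    withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

## Random UMIs. replace = FALSE keeps one molecule per (target, UMI) key;
## requires n <= 4^len.
randomUmis <- function(n, len, replace = FALSE) {
    if (!replace && n > 4^len)
        stop("cannot draw ", n, " distinct UMIs of length ", len,
             " (space is ", 4^len, "); increase umiLength")
    codes <- if (replace) sample.int(4^len, n, replace = TRUE)
             else sample.int(4^len, n) # without replacement
    codes <- codes - 1L
    m <- matrix("", nrow = n, ncol = len)
    for (j in seq_len(len)) {
        m[, len - j + 1L] <- DNA_BASES[codes %% 4L + 1L]
        codes <- codes %/% 4L
    }
    do.call(paste0, asplit(m, 2L))
}

## Character matrix (reads x positions) -> vector of sequences.
matrixToSeqs <- function(m) {
    if (nrow(m) == 0L) return(character())
    do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

## Vector of equal-length sequences -> character matrix, via Biostrings.
seqsToMatrix <- function(seqs) {
    w <- unique(nchar(seqs))
    if (length(w) > 1L)
        stop("sequences of unequal length cannot be stacked positionally")
    as.matrix(Biostrings::DNAStringSet(seqs))
}

## Longest common prefix / suffix lengths between two strings.
commonPrefixLen <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    if (n == 0L) return(0L)
    av <- substring(a, seq_len(n), seq_len(n))
    bv <- substring(b, seq_len(n), seq_len(n))
    d <- which(av != bv)
    if (length(d)) d[1L] - 1L else n
}

commonSuffixLen <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    if (n == 0L) return(0L)
    av <- substring(a, nchar(a) - seq_len(n) + 1L, nchar(a) - seq_len(n) + 1L)
    bv <- substring(b, nchar(b) - seq_len(n) + 1L, nchar(b) - seq_len(n) + 1L)
    d <- which(av != bv)
    if (length(d)) d[1L] - 1L else n
}

hammingDist <- function(a, b) {
    n <- nchar(a)
    stopifnot(nchar(b) == n)
    sum(substring(a, seq_len(n), seq_len(n)) != substring(b, seq_len(n), seq_len(n)))
}
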