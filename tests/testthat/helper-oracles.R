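## Independent oracles for the estimators, coded directly from first
## principles (brute force or literal formula transcription) so that
## agreement with the package functions is a two-route check.

## brute-force pairwise diversity: fraction of discordant chromosome
## pairs among all C(n,2) pairs
oracle_site_pi <- function(n, j) {
    alleles <- c(rep(1L, j), rep(0L, n - j))
    pairs <- utils::combn(n, 2L)
    mean(alleles[pairs[1L, ]] != alleles[pairs[2L, ]])
}

## high-precision direct evaluation of Tajima's D closed form
oracle_tajima_d <- function(S, piSum, n) {
    i <- seq_len(n - 1L)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    (piSum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## literal transcription of the Weir-Cockerham (1984) definitions of
## nbar, nc, pbar, s2, hbar and the a, b, c components for r populations
oracle_wc_components <- function(nDip, p, h) {
    r <- length(nDip)
    nbar <- mean(nDip)
    nc <- (r * nbar - sum(nDip^2) / (r * nbar)) / (r - 1)
    pbar <- sum(nDip * p) / (r * nbar)
    s2 <- sum(nDip * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(nDip * h) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
        ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    c(a = a, b = b, c = cc)
}

## HWE chi-squared via explicit expected counts and an independent
## upper-tail chi2_1 distribution function (via the error function
## identity P(X > x) = erfc(sqrt(x/2)))
oracle_hwe <- function(nAA, nAa, naa) {
    N <- nAA + nAa + naa
    p <- (2 * nAA + nAa) / (2 * N)
    if (p == 0 || p == 1) return(c(chi2 = 0, p = 1))
    e <- c(N * p^2, 2 * N * p * (1 - p), N * (1 - p)^2)
    o <- c(nAA, nAa, naa)
    chi2 <- sum((o - e)^2 / e)
    erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
    c(chi2 = chi2, p = erfc(sqrt(chi2 / 2)))
}

## 2x2 chi-squared by the N(ad-bc)^2 / margins formula
oracle_chi2x2 <- function(a, b, c, d) {
    N <- a + b + c + d
    chi2 <- N * (a * d - b * c)^2 /
        ((a + b) * (c + d) * (a + c) * (b + d))
    erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
    c(chi2 = chi2, p = erfc(sqrt(chi2 / 2)))
}

## exact two-sided Mann-Whitney p by exhaustive enumeration of all
## choose(n1+n2, n1) group assignments (no ties assumed)
oracle_mw_exact <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    v <- c(a, b)
    uStat <- function(idx) {
        x <- v[idx]; y <- v[-idx]
        U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
        min(U, n1 * n2 - U)
    }
    obs <- uStat(seq_len(n1))
    sets <- utils::combn(n1 + n2, n1)
    us <- apply(sets, 2L, uStat)
    mean(us <= obs)
}

## Pearson r via the covariance formula
oracle_pearson_r <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
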