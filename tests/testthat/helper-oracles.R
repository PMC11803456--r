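# Independent oracles: each statistic is recomputed here from first
# principles (explicit rank bookkeeping, exhaustive enumeration, direct
# transfer-function algebra), deliberately avoiding the code paths and
# base-R routines used by the package implementations.

# mid-ranks computed by sorting, without rank()
oracle_midranks <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Kruskal-Wallis H with tie correction, from the defining formula
oracle_kruskal <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- oracle_midranks(x)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 0
  for (g in seq_along(groups)) {
    rg <- r[idx == g]
    h <- h + length(rg) * (mean(rg) - (N + 1) / 2)^2
  }
  H <- 12 / (N * (N + 1)) * h
  tie_sizes <- as.numeric(table(x))
  corr <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  H <- if (corr > 0) H / corr else 0
  list(H = H, p = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# Dunn pairwise z and Bonferroni-adjusted p, direct formula evaluation
oracle_dunn <- function(groups, i, j, m) {
  x <- unlist(groups)
  N <- length(x)
  r <- oracle_midranks(x)
  idx <- rep(seq_along(groups), lengths(groups))
  tie_sizes <- as.numeric(table(x))
  s2 <- N * (N + 1) / 12 - sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  ri <- mean(r[idx == i]); rj <- mean(r[idx == j])
  ni <- sum(idx == i); nj <- sum(idx == j)
  z <- (ri - rj) / sqrt(s2 * (1 / ni + 1 / nj))
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, p_adjusted = min(1, m * p))
}

# Mann-Whitney U and exact two-sided p by full enumeration of labelings
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  combs <- utils::combn(n1 + n2, n1)
  u_of <- function(xi) {
    xs <- pool[xi]; ys <- pool[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_all <- apply(combs, 2L, u_of)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = u_obs, p = min(1, p))
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) stats::dhyper(k, c1, n - c1, r1),
                  numeric(1))
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# pooled-variance two-sample t from the defining formula
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# exact magnitude of the digital Butterworth cascade (bilinear transform
# with prewarped cutoffs), from the closed-form prototype response
oracle_butter_mag <- function(f, fs, cutoff, order, type = c("high", "low"),
                              passes = 1) {
  type <- match.arg(type)
  wf <- tan(pi * f / fs); wc <- tan(pi * cutoff / fs)
  ratio <- if (type == "high") wc / wf else wf / wc
  (1 / sqrt(1 + ratio^(2 * order)))^passes
}

# least-squares log-log slope of the periodogram of x sampled at fs
oracle_psd_slope <- function(x, fs, fmin = 1, fmax = 100) {
  n <- length(x)
  pg <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) / n * fs
  keep <- f >= fmin & f <= fmax
  stats::coef(stats::lm(log(pg[keep]) ~ log(f[keep])))[[2]]
}

# fraction of spectral power inside a band
band_power_fraction <- function(x, fs, band = c(60, 170)) {
  n <- length(x)
  pg <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  sum(pg[f >= band[1] & f <= band[2]]) / sum(pg)
}
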