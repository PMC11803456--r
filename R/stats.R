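# Shared rank-based and exact tests used by the attenuation and spatial
# stages. Omnibus, t and exact tests delegate to the base-R implementations;
# Dunn's post hoc test is implemented from the rank formula since no
# installed package provides it.

as_group_list <- function(groups) {
  if (!is.list(groups)) stop("groups must be a list of numeric vectors",
                             call. = FALSE)
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (sum(lengths(groups) > 0L) < 2L)
    stop("need at least 2 non-empty groups", call. = FALSE)
  groups
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected Kruskal-Wallis H on mid-ranks with a chi-square reference
#' distribution (k - 1 degrees of freedom). Completely tied data (zero rank
#' variance) yields `H = 0, p = 1`.
#'
#' @param groups List of numeric vectors, one per group.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  x <- unlist(groups)
  if (length(x) < 3L) stop("kruskal_wallis: need total N >= 3", call. = FALSE)
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Dunn's post hoc pairwise test
#'
#' Rank-based pairwise comparison after a Kruskal-Wallis omnibus. For a pair
#' (i, j), `z = (Ri - Rj) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/ni + 1/nj))`
#' where `Ri` are mean mid-ranks of the pooled sample, and
#' `T = sum(t^3 - t)` over tie groups. Two-sided p from the standard normal,
#' Bonferroni-adjusted by the declared family size.
#'
#' @param groups List of numeric vectors, one per group.
#' @param pairs List of 2-element integer vectors naming the compared
#'   groups; defaults to all pairs.
#' @param m Family size for the Bonferroni adjustment; defaults to
#'   `length(pairs)`.
#' @return Data frame with columns `i`, `j`, `z`, `p`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, pairs = NULL, m = NULL) {
  groups <- as_group_list(groups)
  k <- length(groups)
  if (is.null(pairs))
    pairs <- utils::combn(k, 2L, simplify = FALSE)
  if (is.null(m)) m <- length(pairs)
  n <- lengths(groups)
  if (any(vapply(pairs, function(p) any(n[p] == 0L), logical(1))))
    stop("dunn_posthoc: empty group in a requested pair", call. = FALSE)
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  mean_rank <- tapply(r, rep(seq_len(k), n), mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  s2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  out <- lapply(pairs, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt(s2 * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (mean_rank[i] - mean_rank[j]) / se else 0
    p_raw <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
    data.frame(i = i, j = j, z = unname(z), p = unname(p_raw))
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- pmin(1, m * out$p)
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. `U` is computed from mid-ranks. The p-value is
#' exact (by enumeration of labelings) when the pooled sample has at most 12
#' observations and no ties; otherwise the normal approximation with tie and
#' continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Pooled-size threshold below which the exact distribution
#'   is used (tie-free data only).
#' @return List with `U` (statistic for `x`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  x <- as.numeric(x[!is.na(x)]); y <- as.numeric(y[!is.na(y)])
  if (length(x) < 1L || length(y) < 1L)
    stop("mann_whitney: both samples must be non-empty", call. = FALSE)
  ties <- any(duplicated(c(x, y)))
  use_exact <- !ties && (length(x) + length(y)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p = min(1, unname(wt$p.value)),
       method = if (use_exact) "exact" else "normal")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities (at the
#' observed margins) of all tables no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return List with `table` and `p`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab)))
    stop("fisher_exact: need a 2x2 table of non-negative counts",
         call. = FALSE)
  if (sum(tab) == 0L) stop("fisher_exact: empty table", call. = FALSE)
  list(table = tab, p = stats::fisher.test(tab)$p.value)
}

#' Pooled-variance two-sample t-test
#'
#' Classic Student t with pooled variance and `n1 + n2 - 2` degrees of
#' freedom, two-sided.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
pooled_t_test <- function(x, y) {
  x <- as.numeric(x[!is.na(x)]); y <- as.numeric(y[!is.na(y)])
  if (length(x) < 2L || length(y) < 2L)
    stop("pooled_t_test: need >= 2 samples per condition", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("pooled_t_test: zero variance in both groups", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}
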