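#' Two-sided permutation test on a difference of group means
#'
#' Tests whether two groups of per-nucleosome values (occupancies, ratios)
#' share a location, using the statistic T = |mean(a) − mean(b)| under
#' random relabeling that preserves group sizes. When the number of
#' distinct arrangements C(n, n_a) is at most \code{exhaustive_limit} every
#' arrangement is enumerated and the p-value is the exact fraction with
#' permuted T at least the observed T; otherwise \code{n_perm} Monte-Carlo
#' relabelings are drawn and the add-one rule p = (b + 1)/(m + 1) guards
#' against p = 0 claims.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed Integer seed for the Monte-Carlo path.
#' @param exhaustive_limit Enumerate exhaustively when the arrangement
#'   count is at most this (default 1e5).
#' @return List: \code{observed}, \code{p_two_sided}, \code{n_permutations},
#'   \code{exhaustive}, \code{seed}.
#' @export
permutation_test <- function(a, b, n_perm = 10000L, seed = 1L,
                             exhaustive_limit = 1e5) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  pool <- c(a, b)
  na <- length(a)
  n <- length(pool)
  t_obs <- abs(mean(a) - mean(b))
  n_arr <- choose(n, na)
  tot <- sum(pool)
  stat_from_a_sum <- function(sa) {
    abs(sa / na - (tot - sa) / (n - na))
  }
  if (n_arr <= exhaustive_limit) {
    combs <- utils::combn(n, na)
    sa <- colSums(matrix(pool[combs], nrow = na))
    t_perm <- stat_from_a_sum(sa)
    p <- mean(t_perm >= t_obs - 1e-12)
    list(observed = t_obs, p_two_sided = p, n_permutations = ncol(combs),
         exhaustive = TRUE, seed = seed)
  } else {
    set.seed(seed)
    t_perm <- vapply(seq_len(n_perm), function(i) {
      stat_from_a_sum(sum(pool[sample.int(n, na)]))
    }, 0)
    p <- (sum(t_perm >= t_obs - 1e-12) + 1) / (n_perm + 1)
    list(observed = t_obs, p_two_sided = p, n_permutations = n_perm,
         exhaustive = FALSE, seed = seed)
  }
}

#' Correlation with a bootstrap confidence interval
#'
#' Spearman rank correlation by default (robust to the heavy-tailed
#' occupancy scale); Pearson optional. The confidence interval is a seeded
#' percentile bootstrap over paired resamples.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List: \code{estimate}, \code{ci_lo}, \code{ci_hi},
#'   \code{method}, \code{n}. Zero variance in either vector gives
#'   \code{NA} estimates.
#' @export
correlation <- function(x, y, method = c("spearman", "pearson"),
                        n_boot = 1000L, conf = 0.95, seed = 1L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(estimate = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                method = method, n = length(x)))
  }
  est <- stats::cor(x, y, method = method)
  set.seed(seed)
  n <- length(x)
  bs <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, replace = TRUE)
    suppressWarnings(stats::cor(x[idx], y[idx], method = method))
  }, 0)
  bs <- bs[is.finite(bs)]
  alpha <- (1 - conf) / 2
  list(estimate = est,
       ci_lo = unname(stats::quantile(bs, alpha)),
       ci_hi = unname(stats::quantile(bs, 1 - alpha)),
       method = method, n = n)
}
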