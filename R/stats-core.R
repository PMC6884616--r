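#' Fisher's exact test for a 2x2 table
#'
#' Exact test of association in a 2x2 contingency table by hypergeometric
#' enumeration, conditioning on both margins. The one-sided `"greater"`
#' alternative tests for an excess in the top-left cell relative to
#' independence; the two-sided p-value sums the probabilities of all tables
#' (with the same margins) at most as probable as the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative One of `"greater"`, `"less"`, `"two.sided"`.
#' @return A list with `p_value`, `odds_ratio` (conditional MLE of the
#'   noncentral hypergeometric odds parameter), `alternative`, and the
#'   input `table`.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2), "greater")
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) {
    stop("'tab' must be a 2x2 matrix")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("'tab' must contain non-negative integer counts")
  }
  if (sum(tab) == 0) stop("'tab' must contain at least one positive count")
  x <- tab[1L, 1L]
  m <- sum(tab[1L, ])          # first-row margin
  n <- sum(tab[2L, ])          # second-row margin
  k <- sum(tab[, 1L])          # first-column margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p <- switch(alternative,
    greater = sum(dens[support >= x]),
    less = sum(dens[support <= x]),
    two.sided = {
      rel <- 1 + 1e-7  # guard against ties lost to floating error
      sum(dens[dens <= dens[support == x] * rel])
    }
  )
  list(
    p_value = min(1, p),
    odds_ratio = cond_mle_odds_ratio(x, m, n, k),
    alternative = alternative,
    table = tab
  )
}

# Conditional MLE of the odds ratio: the value psi for which the expected
# top-left count under the noncentral hypergeometric distribution equals
# the observed count. Degenerate supports give the boundary values.
cond_mle_odds_ratio <- function(x, m, n, k) {
  lo <- max(0L, k - n)
  hi <- min(k, m)
  if (lo == hi) return(NA_real_)
  if (x == lo) return(0)
  if (x == hi) return(Inf)
  support <- lo:hi
  log_dc <- stats::dhyper(support, m, n, k, log = TRUE)
  expected_x <- function(log_psi) {
    logw <- log_dc + support * log_psi
    w <- exp(logw - max(logw))
    sum(support * w) / sum(w)
  }
  root <- stats::uniroot(function(lp) expected_x(lp) - x,
                         lower = -50, upper = 50, tol = 1e-10)
  exp(root$root)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample rank-sum test. The exact null distribution of the
#' Mann-Whitney U statistic is used when both samples together hold at most
#' 20 observations and carry no ties; otherwise a normal approximation with
#' tie and continuity corrections is applied.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"`
#'   (`"greater"` means `x` tends to exceed `y`).
#' @return List with `p_value`, `statistic` (U for the first sample),
#'   `exact` (logical), and `alternative`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- (nx + ny <= 20) && !ties
  if (exact) {
    p <- switch(alternative,
      two.sided = {
        if (u > nx * ny / 2) {
          min(1, 2 * stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE))
        } else {
          min(1, 2 * stats::pwilcox(u, nx, ny))
        }
      },
      greater = stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE),
      less = stats::pwilcox(u, nx, ny)
    )
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sigma2 <- (nx * ny / 12) *
      ((nx + ny + 1) - sum(tie_tab^3 - tie_tab) / ((nx + ny) * (nx + ny - 1)))
    z <- u - mu
    correction <- switch(alternative,
      two.sided = sign(z) * 0.5, greater = 0.5, less = -0.5)
    z <- (z - correction) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
    p <- min(1, p)
  }
  list(p_value = p, statistic = u, exact = exact, alternative = alternative)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper around
#' [stats::p.adjust()] so every module shares one multiple-testing route.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs propagated).
#' @return Vector of BH-adjusted q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
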