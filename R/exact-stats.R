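# Exact combinatorial primitives shared by the analysis stages.

new_interval <- function(lower, upper, level, method) {
  stopifnot(lower <= upper)
  structure(list(lower = lower, upper = upper, level = level, method = method),
            class = "lat_interval")
}

#' @export
print.lat_interval <- function(x, ...) {
  cat(sprintf("%.1f%% CI [%s]: %.4f to %.4f\n",
              100 * x$level, x$method, x$lower, x$upper))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, computed from beta
#' quantiles. The lower bound is exactly 0 when `x = 0` and the upper bound
#' exactly 1 when `x = n`.
#'
#' @param x Number of successes (integer, `0 <= x <= n`).
#' @param n Number of trials (integer, `n >= 1`).
#' @param level Confidence coefficient, default 0.95.
#' @return A list of class `lat_interval` with elements `lower`, `upper`,
#'   `level` and `method`, plus an `estimate` attribute `x/n`.
#' @examples
#' clopper_pearson_ci(55, 74)   # 0.628 to 0.838
#' clopper_pearson_ci(2, 42)    # 0.006 to 0.162
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("'x' must be an integer in [0, n] and 'n' a positive integer")
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  alpha <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(alpha, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha, x + 1, n - x)
  out <- new_interval(lower, upper, level, "clopper-pearson")
  out$estimate <- x / n
  out
}

#' Exact McNemar test for paired discordant counts
#'
#' Exact two-sided sign-test p-value for the hypothesis that the two
#' members of a discordant pair are equally likely, computed from the
#' Binomial(b + c, 1/2) distribution:
#' `p = min(1, 2 * min(P(X <= min(b, c)), P(X >= max(b, c))))`.
#'
#' @param b Discordant count favouring test 1.
#' @param c Discordant count favouring test 2.
#' @return The exact two-sided p-value; 1 when `b + c = 0`.
#' @examples
#' exact_mcnemar_p(10, 2)  # 0.0386
#' @export
exact_mcnemar_p <- function(b, c) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c))
    stop("'b' and 'c' must be non-negative integers")
  n <- b + c
  if (n == 0) return(1)
  lo <- min(b, c)
  hi <- max(b, c)
  min(1, 2 * min(stats::pbinom(lo, n, 0.5),
                 1 - stats::pbinom(hi - 1, n, 0.5)))
}

#' Fisher's exact test for an r x c contingency table
#'
#' Two-sided exact test for independence in a small contingency table of
#' non-negative integer counts, using the probability method: the p-value
#' sums the conditional (multivariate hypergeometric) probabilities of all
#' tables with the observed margins that are no more probable than the
#' observed one. Enumeration is delegated to [stats::fisher.test()]; for
#' tables too large to enumerate a seeded Monte Carlo approximation can be
#' requested.
#'
#' @param table Matrix of non-negative integer counts with positive margins.
#' @param monte_carlo Use Monte Carlo p-value estimation instead of full
#'   enumeration (for tables too large to enumerate). Default `FALSE`.
#' @param B Number of Monte Carlo replicates when `monte_carlo = TRUE`.
#' @param seed Optional seed for the Monte Carlo draw.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_rxc(matrix(c(54, 33, 24, 17), 2, byrow = TRUE))  # 0.703
#' @export
fisher_exact_rxc <- function(table, monte_carlo = FALSE, B = 1e5, seed = NULL) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("'table' must contain non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all row and column margins must be positive")
  if (monte_carlo) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    return(stats::fisher.test(table, simulate.p.value = TRUE, B = B)$p.value)
  }
  p <- tryCatch(stats::fisher.test(table)$p.value, error = function(e) e)
  if (inherits(p, "error"))
    stop("table too large for full enumeration; rerun with monte_carlo = TRUE ",
         "and a seed (", conditionMessage(p), ")")
  p
}

#' Odds ratio with Woolf (log-scale) confidence interval
#'
#' Cross-product odds ratio `ad/bc` for a 2x2 table with a normal-theory
#' interval on the log scale. When any cell is zero the Haldane-Anscombe
#' correction (0.5 added to every cell) is applied and flagged.
#'
#' @param a,b,c,d Cell counts: `a`/`b` exposed successes/failures, `c`/`d`
#'   unexposed successes/failures.
#' @param level Confidence coefficient.
#' @return List with `estimate`, `interval` (a `lat_interval` on the OR
#'   scale) and `corrected` (logical, Haldane-Anscombe applied).
#' @export
odds_ratio_ci <- function(a, b, c, d, level = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  zero <- counts == 0
  # a zero row or column leaves the OR undefined even after correction
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0))
    stop("odds ratio undefined: a full row or column of the 2x2 table is zero")
  corrected <- any(zero)
  if (corrected) counts <- counts + 0.5
  or <- (counts[1] * counts[4]) / (counts[2] * counts[3])
  se <- sqrt(sum(1 / counts))
  z <- stats::qnorm(1 - (1 - level) / 2)
  int <- new_interval(or * exp(-z * se), or * exp(z * se), level, "woolf")
  list(estimate = or, interval = int, corrected = corrected)
}
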