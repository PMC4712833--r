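# Shared statistical kernels: paired Wilcoxon signed-rank with an exact
# small-sample mode that tolerates ties, Benjamini-Hochberg FDR, and the
# nuclear shape-factor rule.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on a vector of paired differences. Zero
#' differences are dropped by default (Wilcoxon's original treatment; Pratt's
#' zero-rank method is available). Absolute differences are midranked under
#' ties; the reported statistic is `W = min(W+, W-)`.
#'
#' The exact two-sided p-value is computed from the full null distribution of
#' `W+` over all 2^n sign assignments (obtained by convolution over the
#' doubled midranks, so ties are handled exactly), and equals
#' `2 * min(P(W+ <= w), P(W+ >= w))` capped at 1. `mode = "auto"` uses the
#' exact computation for n <= 25 pairs and a normal approximation with tie
#' and continuity corrections above that.
#'
#' This differs from [stats::wilcox.test()], which abandons the exact
#' distribution as soon as ties or zeros occur.
#'
#' @param differences Numeric vector of paired differences (condition A −
#'   condition B per unit).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param zero_method `"drop"` (discard zero differences) or `"pratt"`
#'   (rank zeros with the rest, then discard their ranks).
#' @param exact_limit Pair count up to which `"auto"` stays exact.
#' @return An object of class `wsr_test`: a list with `statistic` (W),
#'   `w_plus`, `w_minus`, `p_value`, `n` (pairs used), `n_zero`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value  # 2/32
#' @export
wilcoxon_signed_rank <- function(differences,
                                 mode = c("auto", "exact", "approx"),
                                 zero_method = c("drop", "pratt"),
                                 exact_limit = 25L) {
  mode <- match.arg(mode)
  zero_method <- match.arg(zero_method)
  d <- differences[is.finite(differences)]
  if (length(d) < length(differences)) abort("differences must be finite")
  if (length(d) == 0) abort("no differences supplied")
  n_zero <- sum(d == 0)
  if (n_zero == length(d)) {
    warn("all differences are zero; test is degenerate")
    out <- list(statistic = 0, w_plus = 0, w_minus = 0, p_value = 1,
                n = 0L, n_zero = n_zero, method = "degenerate")
    class(out) <- "wsr_test"
    return(out)
  }
  if (zero_method == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]
    d <- d[keep]
  }
  n <- length(d)
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r) - w_plus
  w <- min(w_plus, w_minus)
  use_exact <- switch(mode, exact = TRUE, approx = FALSE,
                      auto = n <= exact_limit)
  if (use_exact) {
    p <- wsr_exact_p(r, w_plus)
    method <- "exact"
  } else {
    p <- wsr_normal_p(r, w_plus)
    method <- "normal approximation"
  }
  out <- list(statistic = w, w_plus = w_plus, w_minus = w_minus,
              p_value = p, n = n, n_zero = n_zero, method = method)
  class(out) <- "wsr_test"
  out
}

# exact two-sided tail of W+ given midranks r; doubled ranks are integers so
# the 2^n sign-assignment distribution is a polynomial product
wsr_exact_p <- function(r, w_plus) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with 2*W+ = s
  counts[1L] <- 1
  for (k in r2) {
    shifted <- c(numeric(k), counts[seq_len(total + 1L - k)])
    counts <- counts + shifted
  }
  counts <- counts / sum(counts)
  w2 <- as.integer(round(2 * w_plus))
  p_le <- sum(counts[seq_len(w2 + 1L)])
  p_ge <- sum(counts[seq.int(w2 + 1L, total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

# normal approximation with tie correction and continuity correction
wsr_normal_p <- function(r, w_plus) {
  n <- length(r)
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  dev <- w_plus - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' @export
print.wsr_test <- function(x, ...) {
  cat("Paired Wilcoxon signed-rank test (", x$method, ")\n", sep = "")
  cat(sprintf("  n = %d pairs (%d zero differences)\n", x$n, x$n_zero))
  cat(sprintf("  W = %g (W+ = %g, W- = %g), two-sided p = %.4g\n",
              x$statistic, x$w_plus, x$w_minus, x$p_value))
  invisible(x)
}

#' @export
tidy.wsr_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, n = x$n,
         method = x$method)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order. A thin
#' validating wrapper around [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Nuclear shape factor
#'
#' Ratio of the largest to the smallest nuclear diameter; nuclei at or above
#' the threshold (default 2, i.e. about twice as long as wide) are labeled
#' elongated, the rest round. Vectorized over measurements.
#'
#' @param d_max Largest diameter(s); same units as `d_min`.
#' @param d_min Smallest diameter(s); must be positive and `<= d_max`.
#' @param threshold Elongation cutoff on the ratio.
#' @return A tibble with columns `d_max`, `d_min`, `factor`, `label`.
#' @export
shape_factor <- function(d_max, d_min, threshold = 2) {
  if (any(d_min <= 0)) abort("d_min must be positive")
  if (any(d_max < d_min)) abort("d_max must be >= d_min")
  f <- d_max / d_min
  tibble(d_max = d_max, d_min = d_min, factor = f,
         label = ifelse(f >= threshold, "elongated", "round"))
}
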