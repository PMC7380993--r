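#' Pooled two-proportion z-test
#'
#' The textbook pooled-variance test of H0: p1 = p2,
#' `z = (x1/n1 - x2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))` with pooled
#' `p = (x1+x2)/(n1+n2)`, and a two-sided normal tail p-value. No
#' continuity correction. When the pooled proportion is 0 or 1 the
#' statistic is undefined: `z` is `NA`, `p_raw` is 1 and the row is
#' flagged degenerate.
#'
#' @param x1,n1 Successes and trials of sample 1.
#' @param x2,n2 Successes and trials of sample 2.
#' @return Tibble `z`, `p_raw`, `degenerate` (vectorized over inputs).
#' @examples
#' two_prop_ztest(60, 100, 40, 100)  # z = 2.8284, p = 0.00468
#' @export
two_prop_ztest <- function(x1, n1, x2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) rlang::abort("n1 and n2 must be positive")
  if (any(x1 < 0) || any(x2 < 0) || any(x1 > n1) || any(x2 > n2)) {
    rlang::abort("counts must satisfy 0 <= x <= n")
  }
  pooled <- (x1 + x2) / (n1 + n2)
  degenerate <- pooled <= 0 | pooled >= 1
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- ifelse(degenerate, NA_real_, (x1 / n1 - x2 / n2) / se)
  p_raw <- ifelse(degenerate, 1, 2 * stats::pnorm(-abs(z)))
  tibble::tibble(z = z, p_raw = p_raw, degenerate = degenerate)
}

#' Bonferroni adjustment with strict significance flags
#'
#' `p_adj = min(1, m * p)` with `m` the number of comparisons, and a
#' significance flag per the strict two-sided rule `p_adj < alpha`.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Number of comparisons; defaults to `length(p)`.
#' @return Tibble `p_raw`, `p_adj`, `significant`.
#' @export
bonferroni <- function(p, alpha = 0.05, m = length(p)) {
  if (length(p) == 0) {
    return(tibble::tibble(p_raw = numeric(), p_adj = numeric(),
                          significant = logical()))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    rlang::abort("p-values must be in [0, 1]")
  }
  p_adj <- stats::p.adjust(p, method = "bonferroni", n = max(m, length(p)))
  tibble::tibble(p_raw = p, p_adj = p_adj, significant = p_adj < alpha)
}

#' Positive-vs-negative proportion tests per flavor category
#'
#' For each unflagged category, compares the proportion of positive posts
#' with the proportion of negative posts by a pooled two-proportion z-test,
#' treating the two label counts as samples of size `n_posts` each, then
#' Bonferroni-adjusts across the tested categories. Fidelity note: the two
#' proportions come from the same posts, so the independence assumption of
#' the test is a modeling convention here, matching how such comparisons
#' are conventionally reported.
#'
#' @param category_sentiment Tibble from [aggregate_category()].
#' @param alpha Family-wise significance level.
#' @param include_flagged Test flagged (low-count) categories too?
#' @return Tibble `category`, `x1`, `n1`, `x2`, `n2`, `prop_pos`,
#'   `prop_neg`, `z`, `p_raw`, `p_adj`, `significant`, `degenerate`,
#'   `direction` (`"positive_dominant"`, `"negative_dominant"` or
#'   `"none"`).
#' @export
proportion_tests <- function(category_sentiment, alpha = 0.05,
                             include_flagged = FALSE) {
  cs <- category_sentiment
  if (!include_flagged) cs <- cs[!cs$flagged, , drop = FALSE]
  if (nrow(cs) == 0) {
    return(tibble::tibble(category = character(), x1 = integer(),
                          n1 = integer(), x2 = integer(), n2 = integer(),
                          prop_pos = numeric(), prop_neg = numeric(),
                          z = numeric(), p_raw = numeric(),
                          p_adj = numeric(), significant = logical(),
                          degenerate = logical(), direction = character()))
  }
  zt <- two_prop_ztest(cs$n_pos, cs$n_posts, cs$n_neg, cs$n_posts)
  adj <- bonferroni(zt$p_raw, alpha = alpha, m = nrow(cs))
  direction <- ifelse(!adj$significant | zt$degenerate, "none",
                      ifelse(zt$z > 0, "positive_dominant",
                             "negative_dominant"))
  tibble::tibble(category = cs$category,
                 x1 = cs$n_pos, n1 = cs$n_posts,
                 x2 = cs$n_neg, n2 = cs$n_posts,
                 prop_pos = cs$prop_pos, prop_neg = cs$prop_neg,
                 z = zt$z, p_raw = zt$p_raw, p_adj = adj$p_adj,
                 significant = adj$significant,
                 degenerate = zt$degenerate, direction = direction)
}
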