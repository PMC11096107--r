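#' One-sided Fisher's exact test (enrichment in the first row)
#'
#' Upper-tail hypergeometric probability `P(X >= a)` for a 2x2 table with rows
#' = groups and columns = carrier / non-carrier, conditioning on both margins.
#' The default path accumulates log-factorials (via `lgamma`), so the log10
#' p-value is exact far below double underflow (usable down to
#' `log10(p) ~ -1e6`); `mode = "direct"` sums binomial coefficients in double
#' precision and is intended as an independent small-table cross-check.
#'
#' @param a,b Carriers and non-carriers in the first group (e.g. cases).
#' @param c,d Carriers and non-carriers in the second group (e.g. controls).
#' @param mode `"log"` (default) or `"direct"`.
#' @return List with `p` (one-sided p-value, upper tail on `a`) and `log10_p`.
#' @examples
#' fisher_exact_one_sided(3, 30, 3, 38719)  # p ~ 1.12e-8
#' @export
fisher_exact_one_sided <- function(a, b, c, d, mode = c("log", "direct")) {
  mode <- match.arg(mode)
  for (v in list(a, b, c, d)) if (!is_count(v)) stop_input("table entries must be non-negative integers")
  if (a + b + c + d == 0) {
    warning("all-zero table; p = 1")
    return(list(p = 1, log10_p = 0))
  }
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  x <- seq.int(a, min(r1, k))
  if (length(x) == 0L || a > min(r1, k)) return(list(p = 0, log10_p = -Inf))
  if (mode == "direct") {
    p <- sum(choose(r1, x) * choose(r2, k - x)) / choose(N, k)
    p <- min(p, 1)
    return(list(p = p, log10_p = log10(p)))
  }
  lg <- function(n) lgamma(n + 1)
  lnum <- (lg(r1) - lg(x) - lg(r1 - x)) + (lg(r2) - lg(k - x) - lg(r2 - k + x))
  l10 <- (lnum - (lg(N) - lg(k) - lg(N - k))) / log(10)
  log10_p <- min(log10_sum_exp(l10), 0)
  list(p = 10^log10_p, log10_p = log10_p)
}

#' Binomial proportion with confidence interval
#'
#' Point estimate `100 k / n` (percent) with a Wilson score or Clopper-Pearson
#' interval. The CI method is always recorded in the result because published
#' intervals are often method-unlabelled and methods differ in the tails.
#'
#' @param k Successes (carriers).
#' @param n Trials (cohort size), `n >= 1`.
#' @param method `"wilson"` (default) or `"clopper_pearson"`.
#' @param level Confidence level (default 0.95).
#' @return List with `estimate_pct`, `display` (one-decimal percent string),
#'   `ci_pct` (length-2 vector), `method`, `k`, `n`.
#' @examples
#' proportion_with_ci(137, 989)$display  # "13.9%"
#' @export
proportion_with_ci <- function(k, n, method = c("wilson", "clopper_pearson"),
                               level = 0.95) {
  method <- match.arg(method)
  if (!is_count(k) || !is_count(n) || n < 1 || k > n) {
    stop_input("need 0 <= k <= n with n >= 1")
  }
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- if (method == "wilson") {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(max(0, centre - half), min(1, centre + half))
  } else {
    lo <- if (k == 0) 0 else stats::qbeta((1 - level) / 2, k, n - k + 1)
    hi <- if (k == n) 1 else stats::qbeta(1 - (1 - level) / 2, k + 1, n - k)
    c(lo, hi)
  }
  list(estimate_pct = 100 * p,
       display = sprintf("%.1f%%", 100 * p),
       ci_pct = 100 * ci, method = method, level = level, k = k, n = n)
}

#' Carrier prevalence as "1 in N"
#'
#' Inverts a carrier proportion into a population prevalence. `N` is rounded to
#' 3 significant figures; the CI is the chosen proportion interval inverted
#' (upper proportion bound -> smaller denominator).
#'
#' @param k_carriers Carriers observed in the panel.
#' @param n_panel Panel size.
#' @param ci_method Passed to [proportion_with_ci()].
#' @param level Confidence level.
#' @return List with `one_in` (NA when `k_carriers = 0`), `ci_one_in`
#'   (denominators for the upper and lower proportion bounds), `method`.
#' @examples
#' prevalence_estimate(3, 38722)$one_in  # 12900
#' @export
prevalence_estimate <- function(k_carriers, n_panel,
                                ci_method = c("wilson", "clopper_pearson"),
                                level = 0.95) {
  ci_method <- match.arg(ci_method)
  pr <- proportion_with_ci(k_carriers, n_panel, ci_method, level)
  one_in <- if (k_carriers > 0) signif(n_panel / k_carriers, 3) else NA_real_
  ci <- pr$ci_pct / 100
  ci_one_in <- c(lower_denominator = if (ci[2] > 0) signif(1 / ci[2], 3) else NA_real_,
                 upper_denominator = if (ci[1] > 0) signif(1 / ci[1], 3) else Inf)
  list(one_in = one_in, ci_one_in = ci_one_in, method = ci_method,
       k = k_carriers, n = n_panel)
}

#' Two-sided Welch's t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' as used for reporter-assay comparisons. Degenerate zero-variance inputs are
#' resolved deterministically instead of erroring.
#'
#' @param xs,ys Numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t_test <- function(xs, ys) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) < 2L || length(ys) < 2L) stop_input("need >= 2 observations per sample")
  vx <- stats::var(xs); vy <- stats::var(ys)
  if (vx == 0 && vy == 0) {
    if (mean(xs) == mean(ys)) return(list(t = 0, df = NA_real_, p = 1))
    warning("both variances zero with unequal means; p = 0")
    return(list(t = sign(mean(xs) - mean(ys)) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(xs, ys, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Diagnostic yield per cohort subgroup
#'
#' Percentage of variant carriers in each subgroup of a patient cohort (whole
#' cohort, family-history subgroup, parent-to-offspring subgroup, ...), with
#' Wilson confidence intervals. Empty subgroups are dropped with a warning.
#'
#' @param counts A data.frame with columns `subgroup`, `carriers`, `n`.
#' @return A data.frame with columns subgroup, carriers, n, pct (numeric),
#'   display, ci_lo_pct, ci_hi_pct.
#' @examples
#' diagnostic_yield(data.frame(subgroup = "whole", carriers = 137, n = 989))
#' @export
diagnostic_yield <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (!all(c("subgroup", "carriers", "n") %in% names(counts))) {
    stop_input("`counts` needs columns subgroup, carriers, n")
  }
  empty <- counts$n == 0
  if (any(empty)) {
    warning(sprintf("omitting empty subgroup(s): %s",
                    paste(counts$subgroup[empty], collapse = ", ")))
    counts <- counts[!empty, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    pr <- proportion_with_ci(counts$carriers[i], counts$n[i], "wilson")
    data.frame(subgroup = counts$subgroup[i], carriers = counts$carriers[i],
               n = counts$n[i], pct = pr$estimate_pct, display = pr$display,
               ci_lo_pct = pr$ci_pct[1], ci_hi_pct = pr$ci_pct[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
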