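#' Summary statistics of a metric sample
#'
#' Mean, sample standard deviation, standard error, median, and two 95%
#' interval half-widths for a pooled set of per-cell-per-pulse metric
#' values: the conventional `1.96 * sd / sqrt(n)` and, flagged separately,
#' the `sd / n` convention used in the source scatter plots (which
#' understates the interval for n > 1; both are reported so either display
#' can be reproduced).
#'
#' @param x numeric vector of metric values, `n >= 2`.
#' @return one-row data.frame: `n`, `mean`, `sd`, `sem`, `median`,
#'   `ci95_half`, `ci_sd_over_n` (the non-standard convention).
#' @export
group_summary <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 finite values")
  s <- stats::sd(x)
  data.frame(n = n, mean = mean(x), sd = s, sem = s / sqrt(n),
             median = stats::median(x),
             ci95_half = 1.96 * s / sqrt(n),
             ci_sd_over_n = s / n)
}

#' Compare two metric groups (paired one-tailed t test)
#'
#' One-tailed Student t test between pooled metric samples. When the two
#' groups have equal length the test is paired (the pairing used throughout:
#' the two pulse measurements of each cell, or matched cells across
#' conditions); otherwise a Welch two-sample test is used and flagged.
#' Degenerate input (zero variance everywhere with equal means) returns
#' `p = 0.5`, `t = 0` by convention, flagged.
#'
#' @param a,b numeric vectors of metric values.
#' @param alternative `"greater"` tests mean(a) > mean(b), `"less"` the
#'   reverse.
#' @param paired force or forbid pairing; default pairs iff lengths match.
#' @return list: `t`, `p`, `df`, `effect` (mean difference), `paired`,
#'   `degenerate`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, alternative = c("greater", "less"),
                           paired = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(a), is.numeric(b))
  if (is.null(paired)) paired <- length(a) == length(b)
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal lengths")
  d_sd <- if (paired) stats::sd(a - b) else max(stats::sd(a), stats::sd(b))
  if (!is.na(d_sd) && d_sd == 0 && isTRUE(all.equal(mean(a), mean(b)))) {
    return(list(t = 0, p = 0.5, df = NA_real_, effect = 0, paired = paired,
                degenerate = TRUE, n_a = length(a), n_b = length(b)))
  }
  tt <- stats::t.test(a, b, alternative = alternative, paired = paired,
                      var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), effect = mean(a) - mean(b),
       paired = paired, degenerate = FALSE,
       n_a = length(a), n_b = length(b))
}

#' Permutation oracle for the paired one-tailed comparison
#'
#' Sign-flip permutation test on the paired differences; used as an
#' independent check of the t-test p-values.
#'
#' @param a,b paired numeric vectors.
#' @param alternative as in [compare_groups()].
#' @param n_perm number of random sign assignments.
#' @param seed integer seed.
#' @return the permutation p-value.
#' @export
paired_permutation_p <- function(a, b, alternative = c("greater", "less"),
                                 n_perm = 10000, seed = 1) {
  alternative <- match.arg(alternative)
  d <- a - b
  if (alternative == "less") d <- -d
  obs <- mean(d)
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                  nrow = n_perm)
  null_means <- as.vector(flips %*% d) / length(d)
  (1 + sum(null_means >= obs)) / (n_perm + 1)
}
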