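#' One-way fixed-effects analysis of variance
#'
#' Classical between/within sum-of-squares decomposition over k groups, with
#' the F statistic and its p-value.  The decomposition fields are exposed so
#' downstream reports can print the full table.
#'
#' @param groups list (optionally named) of numeric samples, k >= 2, each
#'   with >= 2 observations.
#' @return A list of class `segqa_anova`: `k`, `n_i`, `N`, `grand_mean`,
#'   `group_means`, `ss_between`, `ss_within`, `ss_total`, `df_between`,
#'   `df_within`, `ms_between`, `ms_within`, `F`, `p`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, as.numeric)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  n_i <- vapply(groups, length, 0L)
  if (any(n_i < 2)) stop("each group needs at least 2 observations")
  all_x <- unlist(groups)
  if (!all(is.finite(all_x))) stop("observations must be finite")
  N <- sum(n_i)
  grand <- mean(all_x)
  means <- vapply(groups, mean, 0)
  ss_b <- sum(n_i * (means - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ss_w == 0)
    stop("degenerate: zero within-group variance")
  df_b <- k - 1
  df_w <- N - k
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  F <- ms_b / ms_w
  structure(list(k = k, n_i = n_i, N = N, grand_mean = grand,
                 group_means = means,
                 ss_between = ss_b, ss_within = ss_w,
                 ss_total = ss_b + ss_w,
                 df_between = df_b, df_within = df_w,
                 ms_between = ms_b, ms_within = ms_w,
                 F = F, p = pf(F, df_b, df_w, lower.tail = FALSE)),
            class = "segqa_anova")
}

#' @export
print.segqa_anova <- function(x, ...) {
  cat(sprintf(
    "<segqa_anova> k = %d groups, N = %d\n  SS_between = %.6g (df %d), SS_within = %.6g (df %d)\n  F = %.6g, p = %.4g\n",
    x$k, x$N, x$ss_between, x$df_between, x$ss_within, x$df_within, x$F, x$p))
  invisible(x)
}

#' Upper quantile of the studentized range distribution
#'
#' The critical value q(alpha; k, df) used by Tukey-Kramer all-pairs
#' comparisons, e.g. q(0.05; 6, 39) = 4.237.
#'
#' @param alpha significance level in (0, 1).
#' @param k number of groups, >= 2.
#' @param df within-group (error) degrees of freedom, >= 1.
#' @return The upper-alpha quantile.
#' @examples
#' q_critical(0.05, 6, 39)  # 4.237
#' @export
q_critical <- function(alpha, k, df) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (k < 2) stop("k must be >= 2")
  if (df < 1) stop("df must be >= 1")
  qtukey(1 - alpha, nmeans = k, df = df)
}

#' Tukey-Kramer all-pairs post-hoc comparison
#'
#' After a one-way ANOVA, every pair of group means is compared with the
#' studentized range statistic q = |mean_i - mean_j| / SE with
#' SE = sqrt(MSw/2 (1/n_i + 1/n_j)) (the Kramer form, valid for unequal
#' group sizes), against the critical value q(alpha; k, df_within).
#'
#' @param groups as in [one_way_anova()].
#' @param alpha family significance level.
#' @return A list of class `segqa_tukey`: `table` (data frame with columns
#'   i, j, mean_diff, se, q, q_critical, p, significant), `alpha`,
#'   `q_crit`, `k`, `df`, and the underlying `anova`.
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  an <- one_way_anova(groups)
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  k <- an$k
  qc <- q_critical(alpha, k, an$df_within)
  rows <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(an$ms_within / 2 * (1 / an$n_i[i] + 1 / an$n_i[j]))
    diff <- an$group_means[i] - an$group_means[j]
    q <- abs(diff) / se
    rows[[length(rows) + 1]] <- data.frame(
      i = nm[i], j = nm[j], mean_diff = unname(diff), se = se, q = q,
      q_critical = qc,
      p = ptukey(q, nmeans = k, df = an$df_within, lower.tail = FALSE),
      significant = q > qc)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, alpha = alpha, q_crit = qc, k = k,
                 df = an$df_within, anova = an),
            class = "segqa_tukey")
}

#' @export
print.segqa_tukey <- function(x, ...) {
  cat(sprintf("<segqa_tukey> k = %d, df = %d, q_crit(%.3g) = %.4f\n",
              x$k, x$df, x$alpha, x$q_crit))
  print(x$table, digits = 4)
  invisible(x)
}
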