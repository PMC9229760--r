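test_that("one-way ANOVA matches a from-scratch sum-of-squares oracle", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  an <- one_way_anova(groups)

  # oracle: direct decomposition computed here, independently
  x <- unlist(groups)
  g <- rep(names(groups), lengths(groups))
  grand <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  Fo <- (ssb / 2) / (ssw / 6)
  expect_equal(an$ss_between, ssb, tolerance = 1e-12)
  expect_equal(an$ss_within, ssw, tolerance = 1e-12)
  expect_equal(an$F, Fo, tolerance = 1e-12)
  expect_lt(abs(an$ss_total - (an$ss_between + an$ss_within)) /
              an$ss_total, 1e-9)

  # cross-check against the reference fitter
  fit <- anova(stats::lm(x ~ g))
  expect_equal(an$F, fit$`F value`[1], tolerance = 1e-9)
  expect_equal(an$p, fit$`Pr(>F)`[1], tolerance = 1e-9)
})

test_that("F equals t-squared for two groups", {
  set.seed(21)
  for (rep in 1:5) {
    a <- rnorm(4 + rep)
    b <- rnorm(7) + 0.5
    an <- one_way_anova(list(a, b))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(an$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("total sum of squares is label-invariant and degeneracy is caught", {
  set.seed(33)
  x <- rnorm(12)
  g1 <- list(x[1:4], x[5:8], x[9:12])
  perm <- sample(12)
  g2 <- list(x[perm[1:4]], x[perm[5:8]], x[perm[9:12]])
  expect_equal(one_way_anova(g1)$ss_total, one_way_anova(g2)$ss_total,
               tolerance = 1e-12)

  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(one_way_anova(list(1:3)), "2 groups")
  expect_error(one_way_anova(list(1, 1:3)), "2 observations")
})

test_that("studentized-range critical values reproduce reference quantiles", {
  # the printed Tukey-Kramer constant for 6 groups, 39 df
  expect_lt(abs(q_critical(0.05, 6, 39) - 4.237), 0.005)
  # k = 2 identity with the t distribution
  for (df in c(5, 10, 30))
    expect_lt(abs(q_critical(0.05, 2, df) - sqrt(2) * qt(0.975, df)), 1e-3)
  # monotone in the number of groups
  expect_lt(q_critical(0.05, 3, 10), q_critical(0.05, 6, 10))
  expect_error(q_critical(0, 3, 10), "alpha")
  expect_error(q_critical(0.05, 1, 10), "k")
})

test_that("Tukey-Kramer agrees with TukeyHSD and the k = 2 t test", {
  set.seed(5)
  groups <- list(a = rnorm(6), b = rnorm(6) + 1, c = rnorm(6) - 0.5,
                 d = rnorm(6))
  tk <- tukey_kramer(groups, alpha = 0.05)
  expect_identical(nrow(tk$table), 6L)

  x <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)))
  ref <- TukeyHSD(stats::aov(x ~ g))$g
  # same pairs, same p-values (order: pairs j-i in TukeyHSD)
  for (r in seq_len(nrow(tk$table))) {
    key <- paste0(tk$table$j[r], "-", tk$table$i[r])
    expect_equal(unname(ref[key, "p adj"]), tk$table$p[r], tolerance = 1e-6)
    expect_equal(unname(ref[key, "diff"]), -tk$table$mean_diff[r],
                 tolerance = 1e-9)
  }

  # all means equal: nothing significant
  same <- lapply(1:3, function(i) c(-1, 0, 1) + 1e-8 * i)
  expect_false(any(tukey_kramer(same)$table$significant))

  # k = 2: Tukey decision coincides with the pooled t test at level alpha
  set.seed(8)
  for (delta in c(0, 0.8, 2.5)) {
    a <- rnorm(5); b <- rnorm(6) + delta
    tk2 <- tukey_kramer(list(a = a, b = b), alpha = 0.05)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_identical(tk2$table$significant[1], tt$p.value < 0.05)
    expect_equal(tk2$table$q[1], abs(unname(tt$statistic)) * sqrt(2),
                 tolerance = 1e-9)
  }

  # equal n: SE reduces to sqrt(MSw / n)
  eq <- tukey_kramer(groups)
  msw <- eq$anova$ms_within
  expect_true(all(abs(eq$table$se - sqrt(msw / 6)) < 1e-12))
})

test_that("Tukey significance set is invariant under relabeling and shifts", {
  set.seed(13)
  groups <- list(a = rnorm(5), b = rnorm(5) + 2, c = rnorm(5))
  tk <- tukey_kramer(groups)
  sig <- function(t) {
    tab <- t$table
    sort(paste(pmin(tab$i, tab$j), pmax(tab$i, tab$j))[tab$significant])
  }
  relabeled <- tukey_kramer(groups[c(3, 1, 2)])
  expect_identical(sig(relabeled), sig(tk))
  shifted <- tukey_kramer(lapply(groups, `+`, 100))
  expect_identical(sig(shifted), sig(tk))
  expect_equal(shifted$table$q, tk$table$q, tolerance = 1e-9)
})
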