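test_that("Levene gate: zero for identical groups, flagged when degenerate", {
  lt <- levene_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(lt$statistic, 0)
  deg <- levene_test(rep(4, 6), rep(c("a", "b"), each = 3))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  # detects a 9-fold variance ratio most of the time
  set.seed(31)
  rej <- mean(replicate(200, {
    levene_test(c(rnorm(50), rnorm(50, 0, 3)),
                rep(c("a", "b"), each = 50))$p_value < 0.05
  }))
  expect_gt(rej, 0.5)
})

test_that("two-way ANOVA matches hand-computed balanced sums of squares", {
  # balanced 2x2, n = 2 per cell, deterministic +/-0.5 within-cell deviations
  d <- expand.grid(rep_i = 1:2, sex = c("F", "M"),
                   intervention = c("STD", "HFHSD"))
  cell_mean <- c("F.STD" = 10, "M.STD" = 12, "F.HFHSD" = 15, "M.HFHSD" = 25)
  d$value <- cell_mean[paste(d$sex, d$intervention, sep = ".")] +
    ifelse(d$rep_i == 1, -0.5, 0.5)
  res <- two_way_anova(d)
  # hand-computed (balanced): SS_A = nb * sum (mean_A - grand)^2, etc.
  grand <- mean(cell_mean)
  ssA <- 4 * sum((tapply(cell_mean, c("F", "M", "F", "M"), mean) - grand)^2)
  ssB <- 4 * sum((tapply(cell_mean, c("S", "S", "H", "H"), mean) - grand)^2)
  ssAB <- 2 * sum((cell_mean - grand)^2) - ssA - ssB
  sse <- 8 * 0.25
  mse <- sse / 4
  expect_equal(res$statistic[res$effect == "sex"], ssA / mse)
  expect_equal(res$statistic[res$effect == "intervention"], ssB / mse)
  expect_equal(res$statistic[res$effect == "sex:intervention"], ssAB / mse)
  expect_equal(res$df_resid, rep(4, 3))
})

test_that("two-way ANOVA handles degenerate input and names empty cells", {
  d <- data.frame(sex = rep(c("F", "M"), each = 4),
                  intervention = rep(c("STD", "HFHSD"), 4), value = 7)
  res <- two_way_anova(d)
  expect_equal(res$statistic, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
  d2 <- d[!(d$sex == "M" & d$intervention == "HFHSD"), ]
  expect_error(two_way_anova(d2), "empty design cell: M x HFHSD")
})

test_that("two-way ANOVA p-values are invariant to affine response transforms", {
  set.seed(12)
  d <- expand.grid(rep_i = 1:4, sex = c("F", "M"),
                   intervention = c("STD", "HFHSD", "HFHSD+M"))
  d$value <- rnorm(nrow(d), 100, 10)
  r1 <- two_way_anova(d)
  d$value <- 3.7 * d$value - 50
  r2 <- two_way_anova(d)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-10)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-8)
})

test_that("Games-Howell matches an independent reference implementation", {
  # three groups with unequal variances; reference p-values computed with an
  # established Python implementation (pingouin.pairwise_gameshowell)
  g1 <- c(50, 52, 55, 48, 51, 53, 49, 54)
  g2 <- c(60, 72, 58, 81, 66, 75, 63, 70)
  g3 <- c(80, 79, 82, 78, 81, 80, 83, 77)
  res <- games_howell(c(g1, g2, g3), rep(c("a", "b", "c"), each = 8))
  expect_equal(res$p_value[res$group1 == "a" & res$group2 == "b"],
               9.763439e-04, tolerance = 1e-3)
  expect_lt(abs(res$p_value[res$group1 == "a" & res$group2 == "c"] -
                  2.492340e-12), 1e-3)
  expect_equal(res$p_value[res$group1 == "b" & res$group2 == "c"],
               8.201093e-03, tolerance = 1e-3)
  expect_equal(res$df[res$group1 == "a" & res$group2 == "b"], 8.351820,
               tolerance = 1e-5)
})

test_that("Games-Howell with two groups reduces to the Welch t-test", {
  a <- c(1.2, 2.3, 1.8, 2.9, 3.1, 0.7, 2.2, 1.5)
  b <- c(3.4, 4.1, 2.8, 5.0, 3.9, 4.4, 3.2, 4.8)
  gh <- games_howell(c(a, b), rep(c("a", "b"), each = 8))
  wt <- t.test(a, b)
  expect_equal(gh$p_value, wt$p.value, tolerance = 1e-6)
  # equal-mean equal-variance large groups: p near 1
  set.seed(77)
  x <- rnorm(200); y <- x + rnorm(200, 0, 1e-8)
  ph <- games_howell(c(x, y), rep(c("a", "b"), each = 200))
  expect_gt(ph$p_value, 0.9)
  # zero-variance pair handled by the limiting case
  z <- games_howell(c(rep(1, 3), rep(1, 3)), rep(c("a", "b"), each = 3))
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)
})

test_that("multiplicity adjustments follow their definitions", {
  expect_equal(bonferroni_adjust(0.01), 0.01)
  expect_equal(bonferroni_adjust(c(0.03, 0.04)), c(0.06, 0.08))
  expect_true(all(bonferroni_adjust(runif(20)) <= 1))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.9)),
               c(0.04, 0.04, 4 * 0.04 / 3, 0.9))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(6)
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))
  expect_true(all(bonferroni_adjust(p) >= p))
  expect_true(all(bh_fdr(p) <= bonferroni_adjust(p)))
  expect_true(!is.unsorted(bh_fdr(sort(p))))
})

test_that("Kruskal-Wallis H matches the rank formula; rank-only dependence", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # brute-force rank computation: H = 12/(N(N+1)) * sum n_i rbar_i^2 - 3(N+1)
  H <- 12 / (6 * 7) * (3 * 2^2 + 3 * 5^2) - 3 * 7
  expect_equal(kw$statistic, H)
  expect_equal(kw$p_value, pchisq(H, 1, lower.tail = FALSE))
  tied <- kruskal_wallis(rep(3, 8), rep(c("a", "b"), each = 4))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)
  set.seed(91)
  x <- rlnorm(30); g <- rep(c("a", "b", "c"), 10)
  expect_equal(kruskal_wallis(x, g)$statistic,
               kruskal_wallis(log(x), g)$statistic)
  expect_equal(dunn_bonferroni(x, g)$statistic,
               dunn_bonferroni(exp(x / 10), g)$statistic)
})

test_that("Dunn with two groups equals the rank-sum normal approximation", {
  set.seed(14)
  x <- rnorm(12); y <- rnorm(10, 1)
  d <- dunn_bonferroni(c(x, y), rep(c("a", "b"), c(12, 10)))
  # independent route: normal approximation of the Wilcoxon rank-sum
  r <- rank(c(x, y))
  n1 <- 12; n2 <- 10; N <- n1 + n2
  W <- sum(r[1:12])
  z_ref <- (W - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(abs(d$statistic), abs(z_ref), tolerance = 1e-10)
  ident <- dunn_bonferroni(rep(2, 8), rep(c("a", "b"), each = 4))
  expect_equal(ident$p_value, 1)
})

test_that("post-hoc selection is gated by the Levene test", {
  set.seed(42)
  uneq <- c(rnorm(30, 0, 0.2), rnorm(30, 0, 4), rnorm(30, 1, 0.2))
  g <- rep(c("a", "b", "c"), each = 30)
  sel <- pairwise_posthoc(uneq, g)
  expect_equal(sel$method, "games_howell")
  eq <- rnorm(90)
  sel2 <- pairwise_posthoc(eq, g)
  expect_equal(sel2$method, "bonferroni_t")
  expect_true(all(sel2$pairwise$p_adjusted >= 0 &
                    sel2$pairwise$p_adjusted <= 1))
})

test_that("repeated-measures mixed ANOVA detects a within-subject shift", {
  set.seed(55)
  subj <- expand.grid(rep_i = 1:4, sex = c("F", "M"),
                      intervention = c("STD", "HFHSD"))
  subj$subject <- sprintf("s%02d", seq_len(nrow(subj)))
  base <- rnorm(nrow(subj), 10)
  long <- do.call(rbind, lapply(c("pre", "early", "late"), function(p) {
    shift <- c(pre = 0, early = 1.5, late = 3)[p]
    data.frame(subject = subj$subject, sex = subj$sex,
               intervention = subj$intervention, period = p,
               value = base + shift + rnorm(nrow(subj), 0, 0.5))
  }))
  res <- rm_three_way_anova(long)
  per <- res[res$effect == "period", ]
  expect_lt(per$p_gg, 0.01)
  expect_false(is.na(per$gg_epsilon))
  # between-subject effects carry no sphericity correction
  expect_true(is.na(res$p_gg[res$effect == "sex"]))
})

test_that("a single-period dataset collapses to the two-way factorial", {
  set.seed(56)
  subj <- expand.grid(rep_i = 1:4, sex = c("F", "M"),
                      intervention = c("STD", "HFHSD"))
  subj$subject <- sprintf("s%02d", seq_len(nrow(subj)))
  long <- data.frame(subject = subj$subject, sex = subj$sex,
                     intervention = subj$intervention, period = "only",
                     value = rnorm(nrow(subj)))
  res1 <- rm_three_way_anova(long)
  res2 <- two_way_anova(data.frame(sex = subj$sex,
                                   intervention = subj$intervention,
                                   value = long$value))
  expect_equal(res1$p_value, res2$p_value, tolerance = 1e-10)
})

test_that("incomplete within-subject measurements trigger listwise deletion", {
  set.seed(57)
  subj <- expand.grid(rep_i = 1:3, sex = c("F", "M"),
                      intervention = c("STD", "HFHSD"))
  subj$subject <- sprintf("s%02d", seq_len(nrow(subj)))
  long <- do.call(rbind, lapply(c("pre", "late"), function(p) {
    data.frame(subject = subj$subject, sex = subj$sex,
               intervention = subj$intervention, period = p,
               value = rnorm(nrow(subj), 10))
  }))
  long <- long[-1, ]  # drop one subject's "pre" measurement
  expect_warning(res <- rm_three_way_anova(long), "listwise")
  expect_true(all(is.finite(res$statistic)))
})
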