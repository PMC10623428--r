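# Statistical layer used throughout the study: variance-equality gating,
# factorial ANOVA with Bonferroni or Games-Howell post-hocs, repeated-measures
# mixed ANOVA for the weekly caloric intake, and the nonparametric KW +
# Dunn-Bonferroni screen with FDR used for the imaging-MS signals.

.as_groups <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  ns <- tapply(values, g, length)
  if (any(ns < 2L)) stop("every group needs at least 2 values")
  list(values = as.numeric(values), g = g)
}

#' Levene's test for equality of variances
#'
#' Classical Levene test on absolute deviations from the group mean
#' (\code{center = mean}), with an F reference distribution. Used as the gate
#' choosing between Bonferroni and Games-Howell post-hocs.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param center centering function, \code{mean} (classical, default) or
#'   \code{median} (Brown-Forsythe).
#' @return data.frame with \code{statistic}, \code{df1}, \code{df2},
#'   \code{p_value} and a \code{degenerate} flag (all-equal input gives
#'   p = 1, flagged).
#' @export
levene_test <- function(values, groups, center = mean) {
  d <- .as_groups(values, groups)
  if (stats::sd(d$values) == 0) {
    return(data.frame(statistic = 0, df1 = nlevels(d$g) - 1L,
                      df2 = length(d$values) - nlevels(d$g),
                      p_value = 1, degenerate = TRUE))
  }
  lt <- car::leveneTest(d$values, d$g, center = center)
  data.frame(statistic = lt[1, "F value"], df1 = lt[1, "Df"],
             df2 = lt[2, "Df"], p_value = lt[1, "Pr(>F)"],
             degenerate = FALSE)
}

#' Two-way factorial ANOVA (sex x intervention)
#'
#' Fits \code{value ~ fA * fB} and reports F tests for both main effects and
#' the interaction. Type II sums of squares are used so unbalanced designs
#' (e.g. after animal loss) are handled sensibly.
#'
#' @param data data.frame containing the response and two factor columns.
#' @param response,factor_a,factor_b column names (defaults \code{"value"},
#'   \code{"sex"}, \code{"intervention"}).
#' @return data.frame: one row per effect with F, df, p.
#' @export
two_way_anova <- function(data, response = "value", factor_a = "sex",
                          factor_b = "intervention") {
  stopifnot(all(c(response, factor_a, factor_b) %in% names(data)))
  fa <- factor(data[[factor_a]]); fb <- factor(data[[factor_b]])
  tab <- table(fa, fb)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: ", rownames(tab)[empty[1]], " x ",
         colnames(tab)[empty[2]])
  }
  y <- data[[response]]
  fit <- stats::lm(y ~ fa * fb)
  if (stats::sd(y) == 0) {
    eff <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
    return(data.frame(effect = eff, statistic = 0, df = c(
      nlevels(fa) - 1L, nlevels(fb) - 1L,
      (nlevels(fa) - 1L) * (nlevels(fb) - 1L)),
      df_resid = stats::df.residual(fit), p_value = 1))
  }
  an <- car::Anova(fit, type = 2)
  keep <- setdiff(rownames(an), "Residuals")
  eff <- gsub("fa", factor_a, gsub("fb", factor_b, keep))
  data.frame(effect = eff,
             statistic = an[keep, "F value"],
             df = an[keep, "Df"],
             df_resid = an["Residuals", "Df"],
             p_value = an[keep, "Pr(>F)"],
             row.names = NULL)
}

#' Games-Howell pairwise post-hoc test
#'
#' Pairwise comparisons robust to unequal variances: Welch-type t statistics
#' with Welch-Satterthwaite degrees of freedom, referred to the studentized
#' range distribution with k groups via the \code{q = t * sqrt(2)}
#' convention. With k = 2 this reduces to the Welch t-test.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, each with >= 2 values).
#' @return data.frame: one row per pair with the mean difference, SE, t,
#'   Welch df and studentized-range p-value; a zero-variance pair is handled
#'   by the limiting case and flagged.
#' @export
games_howell <- function(values, groups) {
  d <- .as_groups(values, groups)
  lev <- levels(d$g)
  k <- length(lev)
  m <- tapply(d$values, d$g, mean)
  v <- tapply(d$values, d$g, stats::var)
  n <- tapply(d$values, d$g, length)
  pairs <- utils::combn(lev, 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- v[[i]] / n[[i]] + v[[j]] / n[[j]]
    diff <- m[[i]] - m[[j]]
    if (se2 == 0) {
      p <- if (diff == 0) 1 else 0
      return(data.frame(group1 = i, group2 = j, diff = diff, se = 0,
                        statistic = if (diff == 0) 0 else Inf,
                        df = NA_real_, p_value = p, degenerate = TRUE))
    }
    tstat <- diff / sqrt(se2)
    df <- se2^2 / ((v[[i]] / n[[i]])^2 / (n[[i]] - 1) +
                     (v[[j]] / n[[j]])^2 / (n[[j]] - 1))
    p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    data.frame(group1 = i, group2 = j, diff = diff, se = sqrt(se2),
               statistic = tstat, df = df, p_value = p, degenerate = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bonferroni adjustment
#'
#' \code{min(1, m * p)} over the supplied family.
#'
#' @param p_values raw p-values.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values) stats::p.adjust(p_values, "bonferroni")

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p-values.
#'
#' @param p_values raw p-values.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p_values) stats::p.adjust(p_values, "BH")

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-squared reference.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @return data.frame with \code{statistic}, \code{df}, \code{p_value};
#'   all-tied input returns H = 0, p = 1.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (stats::sd(values) == 0) {
    return(data.frame(statistic = 0, df = nlevels(g) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(values, g)
  data.frame(statistic = unname(kt$statistic), df = unname(kt$parameter),
             p_value = kt$p.value)
}

#' Dunn's pairwise test with Bonferroni correction
#'
#' Pairwise z statistics on pooled ranks with the tie correction
#' \eqn{\sum (t^3 - t) / (12 (N - 1))}, two-sided normal p-values, and
#' Bonferroni adjustment over the \eqn{k(k-1)/2} pairs.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @return data.frame: one row per pair with z, raw and adjusted p.
#' @export
dunn_bonferroni <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(s2 * (1 / n[[i]] + 1 / n[[j]]))
    z <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    p <- if (se == 0) 1 else 2 * stats::pnorm(-abs(z))
    data.frame(group1 = i, group2 = j, statistic = z, p_value = p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_adjusted <- bonferroni_adjust(res$p_value)
  res
}

#' Variance-gated post-hoc comparisons
#'
#' The study's post-hoc selector: Levene's test on the groups decides the
#' pairwise procedure — unequal variances (Levene p below
#' \code{levene_alpha}) select Games-Howell, otherwise pooled-SD pairwise t
#' tests with Bonferroni adjustment.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param levene_alpha gate threshold, default 0.05.
#' @return List with the Levene gate result, the method chosen, and the
#'   pairwise results data.frame.
#' @export
pairwise_posthoc <- function(values, groups, levene_alpha = 0.05) {
  gate <- levene_test(values, groups)
  if (!is.na(gate$p_value) && gate$p_value < levene_alpha) {
    res <- games_howell(values, groups)
    res$p_adjusted <- res$p_value  # studentized-range p is already familywise
    method <- "games_howell"
  } else {
    g <- factor(groups)
    pt <- stats::pairwise.t.test(values, g, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)
    cmb <- which(!is.na(pt$p.value), arr.ind = TRUE)
    res <- data.frame(group1 = colnames(pt$p.value)[cmb[, 2]],
                      group2 = rownames(pt$p.value)[cmb[, 1]],
                      p_adjusted = pt$p.value[cmb])
    method <- "bonferroni_t"
  }
  list(levene = gate, method = method, pairwise = res)
}

#' Repeated-measures three-way mixed ANOVA
#'
#' Mixed ANOVA with two between-subject factors (sex, intervention) and one
#' within-subject factor (period), as used for the weekly caloric-intake
#' periods. Fitted as a multivariate linear model on the within-subject
#' response matrix; univariate F tests for effects involving the
#' within-subject factor carry Greenhouse-Geisser corrected p-values.
#' Subjects with incomplete period measurements are dropped with a warning.
#'
#' @param data long-format data.frame with columns \code{subject},
#'   \code{sex}, \code{intervention}, \code{period}, \code{value}.
#' @return data.frame: one row per effect with F, df, p and (for
#'   within-subject effects) the Greenhouse-Geisser epsilon and corrected p.
#' @export
rm_three_way_anova <- function(data) {
  need <- c("subject", "sex", "intervention", "period", "value")
  stopifnot(all(need %in% names(data)))
  data$period <- factor(data$period)
  periods <- levels(data$period)
  wide <- stats::reshape(
    data[, need], direction = "wide", idvar = "subject",
    timevar = "period", v.names = "value")
  value_cols <- paste0("value.", periods)
  complete <- stats::complete.cases(wide[, value_cols])
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) with incomplete period measurements",
            " dropped (listwise deletion)")
    wide <- wide[complete, , drop = FALSE]
  }
  Y <- as.matrix(wide[, value_cols])
  colnames(Y) <- periods
  sex <- factor(wide$sex); intervention <- factor(wide$intervention)
  if (length(periods) < 2L) {
    # a single period collapses to the ordinary two-way factorial
    df2 <- data.frame(value = Y[, 1], sex = sex, intervention = intervention)
    return(two_way_anova(df2))
  }
  mlm <- stats::lm(Y ~ sex * intervention)
  idata <- data.frame(period = factor(periods, levels = periods))
  aov2 <- car::Anova(mlm, idata = idata, idesign = ~period, type = 2)
  s <- summary(aov2, multivariate = FALSE)
  ut <- s$univariate.tests
  fcol <- intersect(c("F value", "F"), colnames(ut))[1]
  eff <- setdiff(rownames(ut), "(Intercept)")
  res <- data.frame(effect = eff,
                    statistic = ut[eff, fcol],
                    df = ut[eff, "num Df"],
                    df_error = ut[eff, "den Df"],
                    p_value = ut[eff, "Pr(>F)"],
                    gg_epsilon = NA_real_, p_gg = NA_real_,
                    row.names = NULL)
  pv <- s$pval.adjustments
  if (!is.null(pv) && length(pv) && !is.null(rownames(pv))) {
    # with 2 within levels sphericity is trivial and no correction applies
    keep <- rownames(pv) %in% res$effect & is.finite(pv[, "GG eps"])
    idx <- match(rownames(pv)[keep], res$effect)
    res$gg_epsilon[idx] <- pv[keep, "GG eps"]
    res$p_gg[idx] <- pv[keep, "Pr(>F[GG])"]
  }
  res
}
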