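#!/usr/bin/env Rscript
# Stage 4: the study's statistical layer on the phenotypes.
#
# For each scalar endpoint: Levene's test gates the post-hoc choice
# (Games-Howell under unequal variances, Bonferroni-adjusted t otherwise),
# with a sex x intervention two-way ANOVA (Type II) for main effects and
# interaction. The weekly caloric intake is analysed with the
# repeated-measures three-way mixed ANOVA (period within, sex and
# intervention between, Greenhouse-Geisser correction).

library(metabodyn)

horm <- read.csv("results/phenotypes.csv")
results <- list()
for (endpoint in c("homa_ir", "fasting_glucose_mgdl", "leptin_ng_ml")) {
  d <- data.frame(value = horm[[endpoint]], sex = horm$sex,
                  intervention = horm$intervention)
  aov2 <- two_way_anova(d)
  aov2$endpoint <- endpoint
  ph <- pairwise_posthoc(horm[[endpoint]], horm$group)
  message(sprintf("%s: Levene p = %.3g -> %s post-hoc", endpoint,
                  ph$levene$p_value, ph$method))
  for (i in seq_len(nrow(aov2))) {
    message(sprintf("  %-18s F(%d,%d) = %6.2f, p = %.4g", aov2$effect[i],
                    aov2$df[i], aov2$df_resid[i], aov2$statistic[i],
                    aov2$p_value[i]))
  }
  sig <- ph$pairwise[ph$pairwise$p_adjusted < 0.05, , drop = FALSE]
  message("  significant pairs: ", if (nrow(sig)) {
    paste(sig$group1, sig$group2, sep = "-", collapse = ", ")
  } else "none")
  results[[endpoint]] <- aov2
}
write.csv(do.call(rbind, results), "results/anova_endpoints.csv",
          row.names = FALSE)

# caloric intake: period (within) x sex x intervention (between). Intake is
# one value per group-week, so the k-th week of each period serves as the
# replicate "subject" (5 per group, the shortest period's length), each
# observed once per period — a proper mixed design from group-level data.
feeding <- read.csv("results/caloric_intake.csv")
periods <- list(pre = 1:5, early = 6:10, late = 11:18)
n_slot <- min(lengths(periods))
long <- do.call(rbind, lapply(names(periods), function(p) {
  wk <- periods[[p]][seq_len(n_slot)]
  sel <- feeding$week %in% wk
  d <- feeding[sel, ]
  d$slot <- match(d$week, wk)
  data.frame(subject = paste(d$group, d$slot, sep = "."), sex = d$sex,
             intervention = d$intervention, period = p,
             value = d$intake_kcal_g)
}))
rm3 <- rm_three_way_anova(long)
write.csv(rm3, "results/caloric_intake_rm_anova.csv", row.names = FALSE)
message("repeated-measures ANOVA of caloric intake (periods within):")
for (i in seq_len(nrow(rm3))) {
  p <- if (!is.na(rm3$p_gg[i])) rm3$p_gg[i] else rm3$p_value[i]
  message(sprintf("  %-28s F = %7.2f, p%s = %.4g", rm3$effect[i],
                  rm3$statistic[i],
                  if (!is.na(rm3$p_gg[i])) "[GG]" else "", p))
}
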