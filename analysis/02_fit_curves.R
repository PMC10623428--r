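#!/usr/bin/env Rscript
# Stage 2: fit the damped-oscillation glucose model to every group's GTT and
# ITT curves and derive the glycemic parameter set.
#
# Group curves are fitted on the pooled (time, glucose) points of all animals
# in a group — the convention for tolerance-test modelling when per-animal
# curves are noisy. The derived table carries, per group x week x test:
# fasting glucose G(0), peak G_max at t_max, 2-h glucose G(2), setpoint G0,
# damping alpha, period T, initial rate G'(0), steepest descent G'_I at t_I,
# model AUC, trapezoid AUC, and the dysglycemia label from G(0)/G(2).

library(metabodyn)

tt <- read_tolerance_csv("results/data/tolerance_tests.csv")
rows <- list()
for (kind in unique(tt$test_kind)) {
  weeks <- unique(tt$week[tt$test_kind == kind])
  for (wk in weeks) {
    for (grp in unique(tt$group)) {
      series <- cohort_series(tt, kind, wk, group = grp)
      fit <- fit_group_curve(series)
      par <- derive_parameters(fit)
      par$group <- grp
      par$AUC_trapezoid <- mean(vapply(series, auc_trapezoid, 0))
      rows[[paste(kind, wk, grp)]] <- par
    }
  }
}
gtt <- do.call(rbind, Filter(function(d) d$test_kind[1] == "GTT", rows))
itt <- do.call(rbind, Filter(function(d) d$test_kind[1] == "ITT", rows))
gtt <- cbind(gtt, classify_dysglycemia(gtt$G_fasting, gtt$G_2h)[
  c("fasting_status", "twohour_status", "label")])

dir.create("results", showWarnings = FALSE)
write.csv(gtt, "results/glycemic_parameters_gtt.csv", row.names = FALSE)
write.csv(itt, "results/glycemic_parameters_itt.csv", row.names = FALSE)

w18 <- gtt[gtt$week == max(gtt$week), ]
w18 <- w18[order(w18$group), ]
message("week-18 GTT group parameters:")
for (i in seq_len(nrow(w18))) {
  message(sprintf(
    "  %-10s G(0)=%5.1f G(2)=%5.1f G_max=%5.1f t_max=%4.2fh G0=%5.1f alpha=%4.2f T=%4.2fh R2=%.4f  %s",
    w18$group[i], w18$G_fasting[i], w18$G_2h[i], w18$G_max[i], w18$t_max[i],
    w18$G0_setpoint[i], w18$alpha[i], w18$T_period[i], w18$r_squared[i],
    w18$label[i]))
}
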