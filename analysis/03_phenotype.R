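#!/usr/bin/env Rscript
# Stage 3: scalar metabolic phenotyping.
#
# HOMA-IR per animal from the terminal hormone panel (the synthetic assay's
# insulin is simulated in ng/mL; the conversion factor to uU/mL is part of
# this analysis' configuration and stated explicitly — the package refuses a
# silent default), normalized weekly caloric intake per group with
# period-wise marginal means, and adipocyte size-class composition.

library(metabodyn)

# conversion for the simulated insulin immunoassay; uU per ng
INSULIN_UU_PER_NG <- 25

horm <- read_hormone_csv("results/data/hormones.csv")
horm$fasting_insulin_uU_ml <-
  insulin_unit_convert(horm$fasting_insulin_ng_ml, INSULIN_UU_PER_NG)
horm$homa_ir <- homa_ir(horm$fasting_glucose_mgdl, horm$fasting_insulin_uU_ml)
write.csv(horm, "results/phenotypes.csv", row.names = FALSE)
agg <- aggregate(homa_ir ~ group, horm, function(x)
  c(mean = mean(x), sd = sd(x)))
message("HOMA-IR by group (mean +/- SD):")
for (i in seq_len(nrow(agg))) {
  message(sprintf("  %-10s %5.2f +/- %4.2f", agg$group[i],
                  agg$homa_ir[i, "mean"], agg$homa_ir[i, "sd"]))
}

feeding <- read_feeding_csv("results/data/feeding.csv")
feeding$diet <- ifelse(feeding$intervention == "STD", "STD", "HFHSD")
feeding$intake_kcal_g <- NA_real_
for (d in c("STD", "HFHSD")) {
  sel <- feeding$diet == d
  feeding$intake_kcal_g[sel] <- caloric_intake_normalized(
    feeding$food_g[sel], diet_spec(d), feeding$group_mass_g[sel])
}
pm <- period_marginal_means(data.frame(group = feeding$group,
                                       week = feeding$week,
                                       value = feeding$intake_kcal_g))
write.csv(feeding, "results/caloric_intake.csv", row.names = FALSE)
write.csv(pm, "results/caloric_intake_periods.csv", row.names = FALSE)
late <- pm[pm$period == "late", ]
message("late-intervention (weeks 11-18) caloric intake, kcal/g/week:")
for (i in order(-late$mean)) {
  message(sprintf("  %-10s %6.4f +/- %6.4f", late$group[i], late$mean[i],
                  late$se[i]))
}

adip <- read_adipocyte_csv("results/data/adipocytes.csv")
std_areas <- adip$area_um2[adip$group %in% c("STD_F", "STD_M")]
derived <- derive_size_class_boundaries(std_areas)
message(sprintf(
  "size-class boundaries derived from STD quartiles: %.1f / %.1f / %.1f um^2 (shipped defaults 2197.5 / 4395 / 6592)",
  derived$boundaries[1], derived$boundaries[2], derived$boundaries[3]))
comp <- do.call(rbind, lapply(split(adip, adip$group), function(d) {
  b <- bin_adipocyte_areas(d$area_um2)
  data.frame(group = d$group[1], size_class = b$size_class,
             fraction = round(b$fraction, 4))
}))
write.csv(comp, "results/adipocyte_classes.csv", row.names = FALSE)
hyper <- aggregate(fraction ~ group, comp[comp$size_class == 4, ], identity)
message("class-4 (hypertrophic, > 6592 um^2) adipocyte fraction by group:")
for (i in order(-hyper$fraction)) {
  message(sprintf("  %-10s %5.1f%%", hyper$group[i], 100 * hyper$fraction[i]))
}
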