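#' Dysglycemia diagnostic thresholds
#'
#' Default cutoffs (mg/dL) follow the standard type-2-diabetes diagnostic
#' criteria: fasting glucose 100-125 prediabetes, >= 126 diabetes; 2-h
#' glucose 140-199 prediabetes, >= 200 diabetes. The prediabetes bands are
#' implemented as contiguous half-open intervals \[100, 126) and \[140, 200)
#' so non-integer values classify unambiguously.
#'
#' @param fasting_prediabetes_low,fasting_diabetes,twohour_prediabetes_low,twohour_diabetes
#'   cutoffs in mg/dL.
#' @return List of class \code{dysglycemia_thresholds}.
#' @export
dysglycemia_thresholds <- function(fasting_prediabetes_low = 100,
                                   fasting_diabetes = 126,
                                   twohour_prediabetes_low = 140,
                                   twohour_diabetes = 200) {
  if (fasting_prediabetes_low >= fasting_diabetes ||
      twohour_prediabetes_low >= twohour_diabetes) {
    stop("prediabetes lower bound must be below the diabetes cutoff")
  }
  structure(list(fasting_prediabetes_low = fasting_prediabetes_low,
                 fasting_diabetes = fasting_diabetes,
                 twohour_prediabetes_low = twohour_prediabetes_low,
                 twohour_diabetes = twohour_diabetes),
            class = "dysglycemia_thresholds")
}

.glucose_band <- function(x, lo, hi) {
  ifelse(x >= hi, "diabetes", ifelse(x >= lo, "prediabetes", "normal"))
}

#' Classify dysglycemia from fasting and 2-h glucose
#'
#' Applies the fasting and 2-h criteria jointly: the overall label is the
#' worst of the two per-criterion calls (normal < prediabetes < diabetes).
#'
#' @param g_fasting fasting glucose, mg/dL (vectorised).
#' @param g_2h 2-h post-load glucose, mg/dL.
#' @param thresholds a [dysglycemia_thresholds()] object.
#' @return data.frame with per-criterion labels \code{fasting_status},
#'   \code{twohour_status} and the overall \code{label}.
#' @examples
#' classify_dysglycemia(126, 150)  # diabetes on the fasting criterion
#' classify_dysglycemia(95, 150)   # prediabetes on the 2-h criterion
#' @export
classify_dysglycemia <- function(g_fasting, g_2h,
                                 thresholds = dysglycemia_thresholds()) {
  if (any(!is.finite(g_fasting)) || any(!is.finite(g_2h)) ||
      any(g_fasting <= 0) || any(g_2h <= 0)) {
    stop("glucose values must be finite and > 0")
  }
  lv <- c("normal", "prediabetes", "diabetes")
  f <- factor(.glucose_band(g_fasting, thresholds$fasting_prediabetes_low,
                            thresholds$fasting_diabetes), levels = lv)
  h <- factor(.glucose_band(g_2h, thresholds$twohour_prediabetes_low,
                            thresholds$twohour_diabetes), levels = lv)
  overall <- lv[pmax(as.integer(f), as.integer(h))]
  data.frame(g_fasting = g_fasting, g_2h = g_2h,
             fasting_status = as.character(f),
             twohour_status = as.character(h),
             label = overall, stringsAsFactors = FALSE)
}

#' HOMA-IR insulin-resistance index
#'
#' \code{HOMA-IR = fasting glucose (mg/dL) x fasting insulin (uU/mL) / 405}.
#'
#' @param fasting_glucose mg/dL, >= 0.
#' @param fasting_insulin uU/mL, >= 0.
#' @return HOMA-IR score (unit: (mg/dL x uU/mL)/405).
#' @examples
#' homa_ir(90, 9)  # 2.0
#' @export
homa_ir <- function(fasting_glucose, fasting_insulin) {
  if (any(fasting_glucose < 0) || any(fasting_insulin < 0)) {
    stop("fasting glucose and insulin must be non-negative")
  }
  fasting_glucose * fasting_insulin / 405
}

#' Convert insulin from ng/mL to uU/mL
#'
#' Immunoassay insulin is often reported in ng/mL while HOMA-IR needs uU/mL.
#' The conversion factor is assay- and standard-dependent, so it must be
#' supplied explicitly; there is deliberately no default.
#'
#' @param insulin_ng_ml insulin concentration, ng/mL.
#' @param uU_per_ng conversion factor in uU per ng for the assay used.
#' @return Insulin in uU/mL.
#' @export
insulin_unit_convert <- function(insulin_ng_ml, uU_per_ng) {
  if (missing(uU_per_ng) || is.null(uU_per_ng)) {
    stop("insulin unit conversion requires an explicit assay-specific ",
         "'uU_per_ng' factor; no default is assumed")
  }
  if (uU_per_ng <= 0) stop("uU_per_ng must be > 0")
  insulin_ng_ml * uU_per_ng
}

#' Diet specification
#'
#' Energy densities default to standard chow 2.84 kcal/g and the high-fat
#' high-sucrose diet 3.89 kcal/g.
#'
#' @param name "STD" or "HFHSD".
#' @param energy_density_kcal_g metabolisable energy density, kcal/g.
#' @param macronutrient_pct named percentages (must sum to 100).
#' @return List of class \code{diet_spec}.
#' @export
diet_spec <- function(name = c("STD", "HFHSD"),
                      energy_density_kcal_g = NULL,
                      macronutrient_pct = NULL) {
  name <- match.arg(name)
  if (is.null(energy_density_kcal_g)) {
    energy_density_kcal_g <- if (name == "STD") 2.84 else 3.89
  }
  if (energy_density_kcal_g <= 0) stop("energy density must be > 0")
  if (is.null(macronutrient_pct)) {
    macronutrient_pct <- if (name == "STD") {
      c(carbohydrate = 65, fat = 11, protein = 24)
    } else c(carbohydrate = 56, fat = 28, protein = 16)
  }
  if (abs(sum(macronutrient_pct) - 100) > 1e-8) {
    stop("macronutrient percentages must sum to 100")
  }
  structure(list(name = name, energy_density_kcal_g = energy_density_kcal_g,
                 macronutrient_pct = macronutrient_pct),
            class = "diet_spec")
}

#' Normalized group caloric intake
#'
#' Weekly whole-group caloric intake divided by whole-group body mass:
#' \code{food_g x energy density (kcal/g) / group mass (g)}, i.e. kcal per
#' gram of body mass per week. Using kcal rather than grams of food, and
#' group mass rather than animal counts, makes the two diets and groups that
#' lost animals comparable.
#'
#' @param group_food_g grams of food consumed by the whole group in the week.
#' @param diet a [diet_spec()].
#' @param group_mass_g summed body mass of the group, g (> 0).
#' @return Caloric intake in kcal per g body mass per week (vectorised).
#' @export
caloric_intake_normalized <- function(group_food_g, diet, group_mass_g) {
  stopifnot(inherits(diet, "diet_spec"))
  if (any(group_food_g < 0)) stop("food mass must be >= 0")
  if (any(group_mass_g <= 0)) stop("group body mass must be > 0")
  group_food_g * diet$energy_density_kcal_g / group_mass_g
}

#' Per-period marginal means of a weekly series
#'
#' Averages weekly values over study periods — by default the pre-intervention
#' weeks 1-5, early intervention 6-10 and long-term intervention 11-18 —
#' returning the mean and its standard error per group and period.
#'
#' @param data data.frame with columns \code{group}, \code{week}, \code{value}.
#' @param periods named list of integer week vectors.
#' @return data.frame of group, period, n, mean, se.
#' @export
period_marginal_means <- function(data,
                                  periods = list(pre = 1:5, early = 6:10,
                                                 late = 11:18)) {
  stopifnot(all(c("group", "week", "value") %in% names(data)))
  out <- list()
  for (p in names(periods)) {
    sub <- data[data$week %in% periods[[p]], , drop = FALSE]
    if (!nrow(sub)) stop("period '", p, "' contains no weeks present in the data")
    agg <- do.call(rbind, lapply(split(sub, sub$group), function(d) {
      n <- nrow(d)
      data.frame(group = d$group[1], period = p, n = n,
                 mean = mean(d$value),
                 se = if (n > 1) stats::sd(d$value) / sqrt(n) else 0,
                 stringsAsFactors = FALSE)
    }))
    out[[p]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Adipocyte size-class boundaries
#'
#' Defaults are the conventional cut points 2197.5, 4395 and 6592 um^2
#' delimiting classes 1 (< 2197.5), 2, 3 and 4 (> 6592).
#'
#' @param boundaries strictly ascending positive areas, um^2.
#' @return Object of class \code{adipocyte_size_classes}.
#' @export
adipocyte_size_classes <- function(boundaries = c(2197.5, 4395, 6592)) {
  if (any(boundaries <= 0) || any(diff(boundaries) <= 0)) {
    stop("boundaries must be positive and strictly ascending")
  }
  structure(list(boundaries = boundaries), class = "adipocyte_size_classes")
}

#' Bin adipocyte areas into size classes
#'
#' Half-open bins \[0, b1), \[b1, b2), \[b2, b3), \[b3, Inf): an area exactly
#' on a boundary falls in the upper class.
#'
#' @param areas_um2 adipocyte surface areas, um^2 (> 0).
#' @param classes an [adipocyte_size_classes()].
#' @return data.frame of class index, count and fraction; fractions sum to 1.
#' @export
bin_adipocyte_areas <- function(areas_um2,
                                classes = adipocyte_size_classes()) {
  stopifnot(inherits(classes, "adipocyte_size_classes"))
  if (!length(areas_um2)) stop("no areas supplied")
  if (any(areas_um2 <= 0)) stop("areas must be > 0")
  b <- classes$boundaries
  breaks <- c(0, b, Inf)
  cls <- cut(areas_um2, breaks = breaks, right = FALSE,
             labels = seq_len(length(b) + 1L))
  counts <- as.integer(table(cls))
  data.frame(size_class = seq_len(length(b) + 1L), count = counts,
             fraction = counts / length(areas_um2))
}

#' Derive size-class boundaries from standard-diet areas
#'
#' Computes the lower quartile, median and upper quartile of the pooled
#' standard-diet adipocyte areas (linear-interpolation quantiles, R type 7)
#' as the three class boundaries.
#'
#' @param std_group_areas areas (um^2) from standard-diet animals, >= 4 values.
#' @return An [adipocyte_size_classes()]; degenerate (all-equal) input yields
#'   equal boundaries and an attribute \code{degenerate = TRUE}.
#' @export
derive_size_class_boundaries <- function(std_group_areas) {
  if (length(std_group_areas) < 4L) stop("need at least 4 areas")
  q <- unname(stats::quantile(std_group_areas, c(0.25, 0.5, 0.75), type = 7))
  if (any(diff(q) <= 0)) {
    out <- structure(list(boundaries = q), class = "adipocyte_size_classes")
    attr(out, "degenerate") <- TRUE
    warning("degenerate boundaries: quartiles are not strictly ascending")
    return(out)
  }
  adipocyte_size_classes(q)
}

#' Liver-to-body mass ratio
#'
#' @param liver_g liver mass, g (>= 0).
#' @param body_g body mass, g (> 0).
#' @return Ratio as a percentage.
#' @export
liver_mass_ratio <- function(liver_g, body_g) {
  if (any(liver_g < 0)) stop("liver mass must be >= 0")
  if (any(body_g <= 0)) stop("body mass must be > 0")
  100 * liver_g / body_g
}
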