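# In-silico study generator: animals, feeding, tolerance tests, hormone
# panels, adipocyte areas and imaging-MS peak tables with the statistical
# structure the downstream stages assume, so the whole pipeline runs without
# external data. All randomness flows from one config seed, sub-streamed by
# animal / sample key so that adding animals never perturbs existing ones.

# deterministic sub-seed from the master seed and a string key (kept < 2^31)
sub_seed <- function(seed, key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 131 + c) %% 1000000007
  as.integer((seed %% 65011 + 1) * 32749 + h %% 65011) %% 2147483629L
}

#' Default group-true glucose dynamics
#'
#' The versioned fixture of per-group damped-oscillation parameters used by
#' the cohort generator: one row per intervention x sex x test kind x week.
#' Values are chosen to reproduce the qualitative between-group ordering of a
#' long-term high-fat high-sucrose study (liraglutide-treated females with
#' the highest setpoint and slowest return, standard-diet males the fastest)
#' and are not asserted as quantitative truth.
#'
#' @return data.frame with columns intervention, sex, test_kind, week, G0, A,
#'   alpha, T_period, phi.
#' @export
default_group_dynamics <- function() {
  path <- system.file("extdata", "group_dynamics.csv",
                      package = "metabodyn", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Describes the full in-silico study: 4 interventions x 2 sexes, n animals
#' per group, the tolerance-test sampling grids, study weeks, group-true
#' glucose dynamics, noise levels, and the imaging-MS peak model.
#'
#' @param interventions,sexes group factors; every combination is a group.
#' @param n_per_group animals per group (>= 2), default 8.
#' @param gtt_grid_min GTT sampling grid in minutes, default
#'   \code{c(0, 15, 30, 45, 60, 90, 120, 240)}.
#' @param itt_grid_min ITT sampling grid in minutes, default
#'   \code{c(0, 15, 30, 45, 60, 90, 120, 180)}.
#' @param weeks study weeks, default 0:18.
#' @param gtt_weeks,itt_weeks weeks at which tolerance tests are run.
#' @param group_dynamics data.frame of group-true model parameters
#'   (see [default_group_dynamics()]).
#' @param noise_sd_mgdl glucose measurement noise SD, mg/dL, default 5.
#' @param animal_effect_cv coefficient of variation of the lognormal
#'   animal-level multipliers applied to A and G0, default 0.08.
#' @param glucose_floor_mgdl physiological floor for simulated glucose,
#'   default 20 mg/dL.
#' @param ims list describing the peak model: \code{n_peaks},
#'   \code{mz_range}, \code{baseline_meanlog}, \code{between_peak_sdlog},
#'   \code{sdlog_biological}, \code{sdlog_technical}, \code{ppm_jitter_sd},
#'   \code{tic_scale_range}, \code{n_biological}, \code{n_technical}, and
#'   \code{effect_peaks} (data.frame: peak index, group label, multiplier).
#' @param seed master RNG seed (integer).
#' @return Object of class \code{cohort_config}.
#' @export
cohort_config <- function(interventions = c("STD", "HFHSD", "HFHSD+M", "HFHSD+L"),
                          sexes = c("F", "M"),
                          n_per_group = 8,
                          gtt_grid_min = c(0, 15, 30, 45, 60, 90, 120, 240),
                          itt_grid_min = c(0, 15, 30, 45, 60, 90, 120, 180),
                          weeks = 0:18,
                          gtt_weeks = c(0, 5, 12, 18),
                          itt_weeks = 18,
                          group_dynamics = default_group_dynamics(),
                          noise_sd_mgdl = 5,
                          animal_effect_cv = 0.08,
                          glucose_floor_mgdl = 20,
                          ims = list(),
                          seed = 1L) {
  check_grid <- function(g, name) {
    if (!length(g) || g[1] != 0 || any(diff(g) <= 0)) {
      stop("invalid ", name, ": must start at 0 and be strictly increasing")
    }
  }
  check_grid(gtt_grid_min, "gtt_grid_min")
  check_grid(itt_grid_min, "itt_grid_min")
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (noise_sd_mgdl < 0) stop("noise_sd_mgdl must be >= 0")
  if (animal_effect_cv < 0) stop("animal_effect_cv must be >= 0")
  groups <- expand.grid(sex = sexes, intervention = interventions,
                        stringsAsFactors = FALSE)[, 2:1]
  groups$label <- paste(groups$intervention, groups$sex, sep = "_")
  if (anyDuplicated(groups$label)) stop("group labels must be unique")
  ims_default <- list(
    n_peaks = 74, mz_range = c(300, 1000),
    baseline_meanlog = log(1000), between_peak_sdlog = 0.8,
    sdlog_biological = 0.3, sdlog_technical = 0.15,
    ppm_jitter_sd = 2, tic_scale_range = c(0.5, 2),
    n_biological = 4, n_technical = 2,
    effect_peaks = data.frame(
      peak = c(5, 23, 51),
      group = c("STD_M", "HFHSD+L_F", "STD_M"),
      multiplier = c(3, 3, 2.5)))
  user_effects <- if ("effect_peaks" %in% names(ims)) ims["effect_peaks"] else NULL
  ims$effect_peaks <- NULL
  ims <- utils::modifyList(ims_default, ims)
  if (!is.null(user_effects)) ims$effect_peaks <- user_effects$effect_peaks
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 gtt_grid_min = gtt_grid_min, itt_grid_min = itt_grid_min,
                 weeks = weeks, gtt_weeks = gtt_weeks, itt_weeks = itt_weeks,
                 group_dynamics = group_dynamics,
                 noise_sd_mgdl = noise_sd_mgdl,
                 animal_effect_cv = animal_effect_cv,
                 glucose_floor_mgdl = glucose_floor_mgdl,
                 ims = ims, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate one tolerance-test curve
#'
#' Evaluates the damped-oscillation model on the sampling grid (grid given in
#' minutes, evaluated in hours) and adds Gaussian measurement noise; values
#' are floored at a physiological minimum.
#'
#' @param model named list or \code{damped_osc} with fields
#'   \code{G0_setpoint}, \code{A}, \code{alpha}, \code{T_period}, \code{phi}.
#' @param grid_min sampling grid in minutes.
#' @param noise_sd measurement noise SD, mg/dL.
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used.
#' @param floor_mgdl lower floor for simulated glucose, default 20 mg/dL.
#' @param test_kind,id,week series metadata.
#' @return A [tolerance_series()].
#' @export
generate_gtt_curve <- function(model, grid_min, noise_sd = 0, seed = NULL,
                               floor_mgdl = 20, test_kind = "GTT",
                               id = "sim", week = NA) {
  if (!length(grid_min)) stop("grid must be non-empty")
  if (model$T_period <= 0) stop("model rejected: T_period must be > 0")
  if (!is.null(seed)) set.seed(seed)
  t_h <- grid_min / 60
  g <- osc_eval(t_h, model$G0_setpoint, model$A, model$alpha,
                model$T_period, model$phi)
  if (noise_sd > 0) g <- g + stats::rnorm(length(g), 0, noise_sd)
  g <- pmax(g, floor_mgdl)
  tolerance_series(id = id, test_kind = test_kind, week = week,
                   time_h = t_h, glucose = g)
}

.group_true_model <- function(dyn, intervention, sex, test_kind, week) {
  row <- dyn[dyn$intervention == intervention & dyn$sex == sex &
               dyn$test_kind == test_kind & dyn$week == week, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("group_dynamics must contain exactly one row for ",
         intervention, "/", sex, "/", test_kind, "/week ", week)
  }
  list(G0_setpoint = row$G0, A = row$A, alpha = row$alpha,
       T_period = row$T_period, phi = row$phi)
}

#' Generate a complete synthetic cohort
#'
#' Produces every table the pipeline consumes: animals with weekly body mass,
#' group feeding records, per-animal tolerance tests (group-true curve scaled
#' by lognormal animal effects on A and G0, plus Gaussian noise), a terminal
#' hormone panel with the configured group contrasts (e.g. elevated fasting
#' insulin in liraglutide-treated females), adipocyte area tables, and the
#' imaging-MS peak lists (lognormal intensities with group multipliers on
#' designated peaks, ppm jitter and per-sample TIC scaling). Deterministic
#' for a fixed config seed.
#'
#' @param config a [cohort_config()].
#' @return List of class \code{cohort} with elements \code{animals},
#'   \code{feeding}, \code{tolerance_tests}, \code{hormones},
#'   \code{adipocytes}, \code{peaks} and the \code{config}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- config$groups
  cv <- config$animal_effect_cv
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0

  # ---- animals and weekly body mass --------------------------------------
  animals <- list(); masses <- list()
  for (gi in seq_len(nrow(groups))) {
    for (a in seq_len(config$n_per_group)) {
      aid <- sprintf("%s_%02d", groups$label[gi], a)
      set.seed(sub_seed(config$seed, paste0("animal:", aid)))
      base <- if (groups$sex[gi] == "M") 450 else 280
      size_mult <- stats::rlnorm(1, 0, 0.06)
      hf <- groups$intervention[gi] != "STD"
      # weekly gain: modest on chow, steeper on the obesogenic diet
      gain <- if (hf) 6.5 else 2.5
      wk <- config$weeks
      mass <- base * size_mult + gain * pmax(wk, 0) +
        stats::rnorm(length(wk), 0, 4)
      animals[[aid]] <- data.frame(
        animal_id = aid, group = groups$label[gi],
        intervention = groups$intervention[gi], sex = groups$sex[gi],
        stringsAsFactors = FALSE)
      masses[[aid]] <- data.frame(animal_id = aid, group = groups$label[gi],
                                  week = wk, body_mass_g = pmax(mass, 100))
    }
  }
  animals <- do.call(rbind, animals); rownames(animals) <- NULL
  masses <- do.call(rbind, masses); rownames(masses) <- NULL

  # ---- feeding records (whole-group grams per week) ----------------------
  feeding <- list()
  for (gi in seq_len(nrow(groups))) {
    set.seed(sub_seed(config$seed, paste0("feeding:", groups$label[gi])))
    wk <- config$weeks
    per_animal <- if (groups$intervention[gi] == "STD") 135 else 120
    # liraglutide females: abrupt intake increase late in the study
    bump <- if (groups$label[gi] == "HFHSD+L_F") ifelse(wk >= 13, 1.8, 1) else 1
    drug_eff <- if (groups$intervention[gi] %in% c("HFHSD+M", "HFHSD+L")) {
      ifelse(wk >= 6, 0.88, 1)
    } else 1
    food <- per_animal * config$n_per_group * bump * drug_eff *
      stats::rlnorm(length(wk), 0, 0.04)
    gm <- tapply(masses$body_mass_g[masses$group == groups$label[gi]],
                 masses$week[masses$group == groups$label[gi]], sum)
    feeding[[gi]] <- data.frame(
      group = groups$label[gi], intervention = groups$intervention[gi],
      sex = groups$sex[gi], week = wk, food_g = as.numeric(food),
      group_mass_g = as.numeric(gm[as.character(wk)]),
      stringsAsFactors = FALSE)
  }
  feeding <- do.call(rbind, feeding); rownames(feeding) <- NULL

  # ---- tolerance tests ---------------------------------------------------
  tt <- list()
  for (gi in seq_len(nrow(groups))) {
    for (a in seq_len(config$n_per_group)) {
      aid <- sprintf("%s_%02d", groups$label[gi], a)
      set.seed(sub_seed(config$seed, paste0("tt:", aid)))
      mult_A <- if (sdlog > 0) stats::rlnorm(1, 0, sdlog) else 1
      mult_G0 <- if (sdlog > 0) stats::rlnorm(1, 0, sdlog) else 1
      sched <- rbind(
        if (length(config$gtt_weeks))
          data.frame(kind = "GTT", week = config$gtt_weeks),
        if (length(config$itt_weeks))
          data.frame(kind = "ITT", week = config$itt_weeks))
      for (si in seq_len(nrow(sched))) {
        kind <- sched$kind[si]; week <- sched$week[si]
        true <- .group_true_model(config$group_dynamics,
                                  groups$intervention[gi], groups$sex[gi],
                                  kind, week)
        true$A <- true$A * mult_A
        true$G0_setpoint <- true$G0_setpoint * mult_G0
        grid <- if (kind == "GTT") config$gtt_grid_min else config$itt_grid_min
        ser <- generate_gtt_curve(true, grid, config$noise_sd_mgdl,
                                  seed = NULL,
                                  floor_mgdl = config$glucose_floor_mgdl,
                                  test_kind = kind, id = aid, week = week)
        tt[[length(tt) + 1L]] <- data.frame(
          animal_id = aid, group = groups$label[gi],
          intervention = groups$intervention[gi], sex = groups$sex[gi],
          test_kind = kind, week = week, time_min = grid,
          glucose_mgdl = ser$glucose, stringsAsFactors = FALSE)
      }
    }
  }
  tolerance_tests <- do.call(rbind, tt); rownames(tolerance_tests) <- NULL

  # ---- terminal hormone panel -------------------------------------------
  # fasting insulin (ng/mL) multipliers encode the expected group contrasts:
  # hyperinsulinemia on the obesogenic diet, strongest in liraglutide females
  ins_mult <- c("STD_F" = 1, "STD_M" = 1, "HFHSD_F" = 2.2, "HFHSD_M" = 1.9,
                "HFHSD+M_F" = 1.5, "HFHSD+M_M" = 1.5,
                "HFHSD+L_F" = 3.2, "HFHSD+L_M" = 2.2)
  lep_mult <- c("STD_F" = 1, "STD_M" = 1, "HFHSD_F" = 2.6, "HFHSD_M" = 2.2,
                "HFHSD+M_F" = 1.7, "HFHSD+M_M" = 1.6,
                "HFHSD+L_F" = 3.0, "HFHSD+L_M" = 2.0)
  horm <- list()
  last_gtt <- max(config$gtt_weeks)
  for (gi in seq_len(nrow(groups))) {
    lbl <- groups$label[gi]
    true <- .group_true_model(config$group_dynamics, groups$intervention[gi],
                              groups$sex[gi], "GTT", last_gtt)
    g0_true <- osc_eval(0, true$G0_setpoint, true$A, true$alpha,
                        true$T_period, true$phi)
    for (a in seq_len(config$n_per_group)) {
      aid <- sprintf("%s_%02d", lbl, a)
      set.seed(sub_seed(config$seed, paste0("hormone:", aid)))
      horm[[aid]] <- data.frame(
        animal_id = aid, group = lbl,
        intervention = groups$intervention[gi], sex = groups$sex[gi],
        fasting_glucose_mgdl = max(g0_true + stats::rnorm(1, 0, 6), 40),
        fasting_insulin_ng_ml = stats::rlnorm(1, log(0.9 * ins_mult[[lbl]]), 0.25),
        leptin_ng_ml = stats::rlnorm(1, log(4 * lep_mult[[lbl]]), 0.3),
        stringsAsFactors = FALSE)
    }
  }
  hormones <- do.call(rbind, horm); rownames(hormones) <- NULL

  # ---- adipocyte areas ---------------------------------------------------
  # lognormal areas; standard-diet median near the class-2 band, obesogenic
  # diet shifted toward hypertrophy
  area_median <- c("STD" = 3300, "HFHSD" = 5400, "HFHSD+M" = 4400,
                   "HFHSD+L" = 5000)
  adip <- list()
  for (gi in seq_len(nrow(groups))) {
    for (a in seq_len(config$n_per_group)) {
      aid <- sprintf("%s_%02d", groups$label[gi], a)
      set.seed(sub_seed(config$seed, paste0("adipo:", aid)))
      n_cells <- 120
      areas <- stats::rlnorm(n_cells,
                             log(area_median[[groups$intervention[gi]]]), 0.45)
      adip[[aid]] <- data.frame(
        animal_id = aid, group = groups$label[gi],
        intervention = groups$intervention[gi], sex = groups$sex[gi],
        area_um2 = areas, stringsAsFactors = FALSE)
    }
  }
  adipocytes <- do.call(rbind, adip); rownames(adipocytes) <- NULL

  # ---- imaging-MS peak lists --------------------------------------------
  ims <- config$ims
  set.seed(sub_seed(config$seed, "ims:axis"))
  mz <- sort(stats::runif(ims$n_peaks, ims$mz_range[1], ims$mz_range[2]))
  peak_meanlog <- stats::rnorm(ims$n_peaks, ims$baseline_meanlog,
                               ims$between_peak_sdlog)
  pk <- list()
  for (gi in seq_len(nrow(groups))) {
    lbl <- groups$label[gi]
    mult <- rep(1, ims$n_peaks)
    ep <- ims$effect_peaks
    if (!is.null(ep) && nrow(ep)) {
      # effect peaks outside the configured axis are ignored
      sel <- ep$group == lbl & ep$peak <= ims$n_peaks
      if (any(sel)) mult[ep$peak[sel]] <- ep$multiplier[sel]
    }
    for (b in seq_len(ims$n_biological)) {
      set.seed(sub_seed(config$seed, paste0("ims:", lbl, ":bio", b)))
      bio_dev <- stats::rnorm(ims$n_peaks, 0, ims$sdlog_biological)
      for (tc in seq_len(ims$n_technical)) {
        set.seed(sub_seed(config$seed, paste0("ims:", lbl, ":b", b, ":t", tc)))
        tech_dev <- stats::rnorm(ims$n_peaks, 0, ims$sdlog_technical)
        inten <- exp(peak_meanlog + log(mult) + bio_dev + tech_dev)
        tic_scale <- stats::runif(1, ims$tic_scale_range[1],
                                  ims$tic_scale_range[2])
        mz_obs <- mz * (1 + stats::rnorm(ims$n_peaks, 0, ims$ppm_jitter_sd) * 1e-6)
        sid <- sprintf("%s_b%d_t%d", lbl, b, tc)
        pk[[sid]] <- data.frame(
          sample_id = sid, group = lbl,
          replicate = sprintf("b%d_t%d", b, tc),
          mz = mz_obs, intensity = inten * tic_scale,
          stringsAsFactors = FALSE)
      }
    }
  }
  peaks <- do.call(rbind, pk); rownames(peaks) <- NULL

  structure(list(animals = animals, body_mass = masses, feeding = feeding,
                 tolerance_tests = tolerance_tests, hormones = hormones,
                 adipocytes = adipocytes, peaks = peaks, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d groups x %d animals; %d tolerance-test rows; %d IMS samples\n",
    nrow(x$config$groups), x$config$n_per_group, nrow(x$tolerance_tests),
    length(unique(x$peaks$sample_id))))
  invisible(x)
}

#' Extract tolerance-test series from a cohort
#'
#' @param cohort a [generate_cohort()] result or a tolerance-test data.frame.
#' @param test_kind "GTT" or "ITT".
#' @param week study week.
#' @param group optional group label filter.
#' @return List of [tolerance_series()], one per animal.
#' @export
cohort_series <- function(cohort, test_kind, week, group = NULL) {
  df <- if (inherits(cohort, "cohort")) cohort$tolerance_tests else cohort
  df <- df[df$test_kind == test_kind & df$week == week, , drop = FALSE]
  if (!is.null(group)) df <- df[df$group == group, , drop = FALSE]
  if (!nrow(df)) stop("no matching tolerance-test rows")
  lapply(split(df, df$animal_id), function(d) {
    d <- d[order(d$time_min), ]
    tolerance_series(d$animal_id[1], test_kind, week, d$time_min / 60,
                     d$glucose_mgdl)
  })
}
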