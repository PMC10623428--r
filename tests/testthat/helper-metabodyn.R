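gtt_grid_min <- c(0, 15, 30, 45, 60, 90, 120, 240)
itt_grid_min <- c(0, 15, 30, 45, 60, 90, 120, 180)

make_series <- function(G0 = 100, A = 80, alpha = 0.8, T_period = 3,
                        phi = 0.2, grid_min = gtt_grid_min, noise_sd = 0,
                        test_kind = "GTT", id = "test", week = 18) {
  generate_gtt_curve(list(G0_setpoint = G0, A = A, alpha = alpha,
                          T_period = T_period, phi = phi),
                     grid_min, noise_sd = noise_sd, test_kind = test_kind,
                     id = id, week = week)
}

# minimal hand-built signal matrix for selection / screening tests
fake_signal_matrix <- function(M, mz = seq_len(ncol(M)) + 300,
                               group = rep("g1", nrow(M)),
                               replicate = rep(NA, nrow(M)),
                               normalize = TRUE) {
  if (normalize) M <- t(apply(M, 1, function(r) r / sum(r)))
  structure(list(matrix = M, mz = mz, sum_intensity = unname(colSums(M)),
                 group = group, replicate = replicate),
            class = "signal_matrix")
}

# tiny cohort config for fast generator tests
small_config <- function(...) {
  cohort_config(interventions = c("STD", "HFHSD"), sexes = "F",
                n_per_group = 2, gtt_weeks = 18, itt_weeks = numeric(0),
                weeks = 0:18, ims = list(n_peaks = 10, n_biological = 2,
                                         n_technical = 1),
                ...)
}
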