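test_that("TIC normalization sums to one, is idempotent and scale-free", {
  expect_equal(tic_normalize(c(10, 30, 60)), c(0.1, 0.3, 0.6))
  x <- c(5, 0, 15)
  expect_equal(tic_normalize(tic_normalize(x)), tic_normalize(x))
  expect_equal(tic_normalize(x * 1e6), tic_normalize(x))
  expect_error(tic_normalize(c(0, 0)), "all-zero")
  expect_error(tic_normalize(c(-1, 2)), ">= 0")
})

test_that("m/z alignment merges within tolerance and splits beyond it", {
  two <- data.frame(sample_id = c("s1", "s2"), group = "g",
                    replicate = NA, mz = c(500.000, 500.002),
                    intensity = c(10, 20))
  expect_length(align_mz(two, tolerance_ppm = 10)$mz, 1)   # 4 ppm apart
  far <- data.frame(sample_id = c("s1", "s2"), group = "g",
                    replicate = NA, mz = c(500.00, 500.02),
                    intensity = c(10, 20))
  expect_length(align_mz(far, tolerance_ppm = 10)$mz, 2)   # 40 ppm apart
  single <- data.frame(sample_id = "s1", group = "g", replicate = NA,
                       mz = c(310.1, 420.2, 530.3), intensity = c(1, 2, 7))
  sm <- align_mz(single)
  expect_equal(sm$mz, c(310.1, 420.2, 530.3))
  expect_equal(as.numeric(sm$matrix), c(0.1, 0.2, 0.7))
})

test_that("alignment resolves within-sample collisions by max intensity", {
  coll <- data.frame(sample_id = "s1", group = "g", replicate = NA,
                     mz = c(500.0000, 500.0005, 600),
                     intensity = c(3, 9, 8))
  sm <- align_mz(coll, tolerance_ppm = 10)
  expect_length(sm$mz, 2)
  expect_equal(attr(sm, "collisions"), 1L)
  expect_equal(as.numeric(sm$matrix), c(9, 8) / 17)
  # bin center is the intensity-weighted mean
  expect_equal(sm$mz[1], (500.0000 * 3 + 500.0005 * 9) / 12)
})

test_that("every aligned row sums to one", {
  co <- generate_cohort(small_config(seed = 2))
  sm <- align_mz(co$peaks)
  expect_equal(unname(rowSums(sm$matrix)), rep(1, nrow(sm$matrix)))
})

test_that("strong-signal selection is strict, scale-free and monotone", {
  sm <- fake_signal_matrix(rbind(c(100, 6, 4)))
  expect_equal(select_strong_signals(sm), c(1L, 2L))  # 6 > 5, 4 < 5
  one <- fake_signal_matrix(matrix(5, 1, 1))
  expect_equal(select_strong_signals(one), 1L)
  # monotone: a larger threshold keeps a subset
  sm2 <- fake_signal_matrix(rbind(c(100, 30, 8, 6, 2)))
  s05 <- select_strong_signals(sm2, 0.05)
  s20 <- select_strong_signals(sm2, 0.20)
  expect_true(all(s20 %in% s05))
})

test_that("the screen spans all group pairs and delegates correctly", {
  cfg <- cohort_config(n_per_group = 2,
                       ims = list(n_peaks = 6, n_biological = 2,
                                  n_technical = 1,
                                  effect_peaks = data.frame(
                                    peak = 2, group = "STD_M",
                                    multiplier = 50)),
                       seed = 33)
  co <- generate_cohort(cfg)
  sm <- align_mz(co$peaks)
  scr <- screen_significance(sm)
  expect_equal(nrow(scr$omnibus), length(sm$mz))
  expect_true(all(scr$omnibus$p_fdr >= scr$omnibus$p_value))
  if (!is.null(scr$pairwise)) {
    per_bin <- table(scr$pairwise$bin)
    expect_true(all(per_bin == choose(8, 2)))  # 28 pairs for 8 groups
  }
  # the alternative FDR scope adjusts over all pairwise p-values
  scr2 <- screen_significance(sm, fdr_scope = "pairwise")
  expect_true("p_fdr" %in% names(scr2$pairwise))
})

test_that("technical replicates can be collapsed before testing", {
  cfg <- cohort_config(n_per_group = 2,
                       ims = list(n_peaks = 5, n_biological = 3,
                                  n_technical = 2), seed = 44)
  co <- generate_cohort(cfg)
  sm <- align_mz(co$peaks)
  scr <- screen_significance(sm, collapse_technical = TRUE)
  expect_equal(nrow(scr$omnibus), 5)
})

test_that("PCA summary behaves on degenerate and exact structures", {
  line <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3) *
    matrix(rep(c(1, 2, 5), each = 4), ncol = 3)
  sm <- fake_signal_matrix(line + 10, normalize = FALSE)
  pc <- pca_summary(sm)
  expect_gt(pc$var_explained[1], 0.999999)
  # full reconstruction returns the centered data
  M <- sm$matrix
  rec <- pc$scores %*% t(pc$loadings)
  expect_equal(rec, scale(M, scale = FALSE), tolerance = 1e-10,
               ignore_attr = TRUE)
  flat <- fake_signal_matrix(matrix(1, 4, 3))
  expect_true(pca_summary(flat)$zero_variance)
})

test_that("Ward clustering recovers separated classes deterministically", {
  set.seed(10)
  a <- matrix(rnorm(5 * 6, 0, 0.2), 5)
  b <- matrix(rnorm(5 * 6, 5, 0.2), 5)
  M <- abs(rbind(a, b)) + 1
  rownames(M) <- sprintf("s%02d", 1:10)
  sm <- fake_signal_matrix(M, normalize = FALSE)
  hw <- ward_heatmap(sm, k = 2)
  expect_length(unique(hw$row_clusters[1:5]), 1)
  expect_length(unique(hw$row_clusters[6:10]), 1)
  expect_false(hw$row_clusters[1] == hw$row_clusters[10])
  # duplicated sample merges at height zero
  M2 <- rbind(M, M[1, , drop = FALSE])
  rownames(M2) <- c(rownames(M), "dup")
  hw2 <- ward_heatmap(fake_signal_matrix(M2, normalize = FALSE))
  expect_lt(min(hw2$row_tree$height), 1e-12)
  # scaling one bin's raw intensities does not change the z-scaled result
  sm3 <- fake_signal_matrix(M %*% diag(c(10, rep(1, 5))), normalize = FALSE)
  expect_equal(ward_heatmap(sm3)$scaled[, 1],
               ward_heatmap(fake_signal_matrix(M, normalize = FALSE))$scaled[, 1],
               tolerance = 1e-10)
})

test_that("monoisotopic masses match independent table arithmetic", {
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C"), 12)
  # inosine monophosphate; reference value from an independent calculator
  expect_equal(monoisotopic_mass("C10H13N4O8P"), 348.047100,
               tolerance = 1e-6)
  expect_error(monoisotopic_mass("C2Zz3"), "Zz")
  expect_error(monoisotopic_mass(""), "empty")
})

test_that("adduct annotation hits within tolerance and sorts by ppm", {
  tab <- data.frame(name = c("IMP", "PA C36:3"),
                    formula = c("C10H13N4O8P", "C39H71O8P"))
  hit <- annotate_mass(387.01, tab, adducts = "M+K")
  expect_equal(hit$name, "IMP")
  expect_equal(hit$theoretical_mz, 387.0103, tolerance = 1e-6)
  expect_lt(abs(hit$ppm_error), 10)
  hit2 <- annotate_mass(737.45, tab, adducts = "M+K")
  expect_equal(hit2$name, "PA C36:3")
  expect_lt(abs(hit2$ppm_error), 10)
  none <- annotate_mass(400, data.frame(name = character(0),
                                        formula = character(0)))
  expect_equal(nrow(none), 0)
  # unparsable formulas are skipped per entry, others still processed
  bad <- data.frame(name = c("broken", "IMP"),
                    formula = c("notaformula", "C10H13N4O8P"))
  expect_warning(h <- annotate_mass(387.01, bad, adducts = "M+K"),
                 "broken")
  expect_equal(h$name, "IMP")
})

test_that("default 10 ppm tolerance separates 9 ppm from 11 ppm queries", {
  theo <- adduct_mz("C10H13N4O8P", "M+K")
  tab <- data.frame(name = "IMP", formula = "C10H13N4O8P")
  expect_equal(nrow(annotate_mass(theo * (1 + 9e-6), tab, adducts = "M+K")), 1)
  expect_equal(nrow(annotate_mass(theo * (1 + 11e-6), tab, adducts = "M+K")), 0)
})

test_that("bundled annotation table reproduces its quoted masses", {
  tab <- annotation_table()
  for (i in seq_len(nrow(tab))) {
    adds <- trimws(strsplit(tab$adducts[i], ";")[[1]])
    ppm <- sapply(adds, function(a) {
      theo <- adduct_mz(tab$formula[i], a)
      (tab$reported_mz[i] - theo) / theo * 1e6
    })
    flagged <- nzchar(tab$comment[i])
    if (flagged) {
      # the known discrepant entry stays recorded, not forced to agree
      expect_gt(min(abs(ppm["M+Na"])), 10)
    } else {
      expect_lt(min(abs(ppm)), 10)
    }
  }
})
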