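# block-upsample a label volume (each voxel split in 8), halving spacing:
# same physical object on a finer grid
upsample_volume <- function(vol) {
  a <- vol$voxels
  d <- dim(a)
  idx1 <- rep(seq_len(d[1]), each = 2)
  idx2 <- rep(seq_len(d[2]), each = 2)
  idx3 <- rep(seq_len(d[3]), each = 2)
  label_volume(a[idx1, idx2, idx3], vol$spacing / 2, schema = vol$schema)
}

test_that("uniform prisms give exactly linear cumulative curves", {
  vol <- make_prism_volume(n_slices = 50, spacing = c(2, 1, 1))
  cv <- build_volume_curves(vol, 100)  # true length 50 * 2 mm
  expect_equal(cv$coverage_percent, 100)
  # scapula 100 mm^2: cumulative at p is 100 * p mm^3 = 0.1 * p ml
  expect_equal(unname(cv$cum_ml[, "scapula"]), 0.1 * (1:100))
  # supraspinatus 200 mm^2: 0.2 * p ml, exactly linear
  expect_equal(unname(cv$cum_ml[, "supraspinatus"]), 0.2 * (1:100))
  # normalized size 2.0 at every p
  expect_equal(unname(normalized_muscle_size(cv, "supraspinatus")),
               rep(2, 100))
  # curve constant beyond an ROI's medial end
  vol2 <- make_prism_volume(n_slices = 50, spacing = c(2, 1, 1))
  v2 <- vol2$voxels
  sub <- v2[26:50, , ]; sub[sub == 4L] <- 0L; v2[26:50, , ] <- sub
  vol2 <- label_volume(v2, vol2$spacing)  # supraspinatus clipped medially
  cv2 <- build_volume_curves(vol2, 100)
  expect_equal(unname(cv2$cum_ml[50:100, "supraspinatus"]),
               rep(cv2$cum_ml[50, "supraspinatus"], 51))
})

test_that("relative contributions follow volume ratios and sum to 100", {
  vol <- make_prism_volume(muscle_rows = list(supraspinatus = 1:2,
                                              infraspinatus = 11:13,
                                              teres_minor = 51:55,
                                              subscapularis = 61:70))
  cv <- build_volume_curves(vol, 100)
  expect_equal(unname(relative_contribution(cv, "supraspinatus", 30L)), 10)
  expect_equal(unname(relative_contribution(cv, "infraspinatus", 30L)), 15)
  expect_equal(unname(relative_contribution(cv, "teres_minor", 30L)), 25)
  expect_equal(unname(relative_contribution(cv, "subscapularis", 30L)), 50)
  total <- Reduce(`+`, lapply(rc_muscles(), function(m)
    relative_contribution(cv, m)))
  expect_true(all(abs(total - 100) < 1e-9))
  # a zero-volume muscle contributes 0% and the rest renormalize
  vol$voxels[vol$voxels == roi_label(vol$schema, "supraspinatus")] <- 0L
  cv0 <- build_volume_curves(vol, 100)
  expect_equal(unname(relative_contribution(cv0, "supraspinatus", 50L)), 0)
  expect_equal(unname(normalized_muscle_size(cv0, "supraspinatus", 50L)), 0)
  total0 <- Reduce(`+`, lapply(rc_muscles(), function(m)
    relative_contribution(cv0, m, 50L)))
  expect_equal(unname(total0), 100)
})

test_that("fat infiltration spans its closed-form extremes", {
  # fat-free muscle
  vol <- make_prism_volume()
  cv <- build_volume_curves(vol, 100)
  expect_equal(unname(fat_infiltration(cv, "supraspinatus")), rep(0, 100))
  # separate fat block: FI = 5 / (20 + 5) columns = 20% at every p
  volf <- make_prism_volume(fat_cols = 31:35)
  cvf <- build_volume_curves(volf, 100)
  expect_equal(unname(fat_infiltration(cvf, "infraspinatus")), rep(20, 100))
  # compartment entirely fat
  vol100 <- make_prism_volume()
  v <- vol100$voxels
  v[v == roi_label(vol100$schema, "teres_minor")] <-
    roi_label(vol100$schema, "teres_minor_fat")
  vol100 <- label_volume(v, vol100$spacing)
  cv100 <- build_volume_curves(vol100, 100)
  expect_equal(unname(fat_infiltration(cv100, "teres_minor", 40L)), 100)
})

test_that("i.i.d. fat assignment lands within binomial error of its target", {
  f <- 0.10
  ph <- generate_phantom(phantom_spec(
    length_mm = 140,
    fat_fractions = c(supraspinatus = f, infraspinatus = f,
                      teres_minor = f, subscapularis = f),
    seed = 71))
  vol <- ph$volume
  cv <- build_volume_curves(vol, ph$truth$true_length_mm)
  n_comp <- sum(muscle_boundary_mask(vol, "supraspinatus"))
  expect_gt(n_comp, 1e4)
  fi <- unname(fat_infiltration(cv, "supraspinatus", 100L))
  se3 <- 3 * sqrt(f * (1 - f) / n_comp) * 100
  expect_lt(abs(fi - 10), se3)
})

test_that("cumulative curves match the brute-force oracle at slice boundaries", {
  ph <- generate_phantom(random_blob_spec(81))
  vol <- ph$volume
  cv <- build_volume_curves(vol, ph$truth$true_length_mm /
                              ph$truth$spec$coverage)
  for (r in c("scapula", "supraspinatus", "infraspinatus_fat",
              "subscapularis")) {
    expect_equal(unname(cv$boundary_ml[, r]), oracle_boundary_ml(vol, r))
  }
  # monotone non-decreasing in p over the defined range
  for (r in colnames(cv$cum_ml)) {
    v <- cv$cum_ml[!is.na(cv$cum_ml[, r]), r]
    expect_true(all(diff(v) >= -1e-12))
  }
})

test_that("metrics are stable under voxel-size refinement", {
  ph <- generate_phantom(phantom_spec(length_mm = 120, seed = 72,
                                      fat_fractions = c(supraspinatus = 0.1,
                                                        infraspinatus = 0.1,
                                                        teres_minor = 0.1,
                                                        subscapularis = 0.1)))
  coarse <- ph$volume
  fine <- upsample_volume(coarse)
  cvc <- build_volume_curves(coarse, 120)
  cvf <- build_volume_curves(fine, 120)
  for (m in rc_muscles()) {
    for (p in c(20L, 50L, 90L)) {
      expect_lt(abs(normalized_muscle_size(cvf, m, p) /
                      normalized_muscle_size(cvc, m, p) - 1), 0.01)
      expect_lt(abs(relative_contribution(cvf, m, p) /
                      relative_contribution(cvc, m, p) - 1), 0.01)
      expect_lt(abs(fat_infiltration(cvf, m, p) /
                      fat_infiltration(cvc, m, p) - 1), 0.01)
    }
  }
})

test_that("truncation reproduces full-coverage metrics at every covered p", {
  spec_full <- phantom_spec(length_mm = 140, seed = 73)
  spec_part <- spec_full; spec_part$coverage <- 0.4
  full <- generate_phantom(spec_full)
  part <- generate_phantom(spec_part)
  L <- full$truth$true_length_mm
  cvf <- build_volume_curves(full$volume, L)
  cvp <- build_volume_curves(part$volume, L)
  pp <- defined_percents(cvp)
  expect_true(max(pp) >= 40)
  for (m in rc_muscles()) {
    expect_equal(normalized_muscle_size(cvp, m, pp),
                 normalized_muscle_size(cvf, m, pp))
    expect_equal(relative_contribution(cvp, m, pp),
                 relative_contribution(cvf, m, pp))
    expect_equal(fat_infiltration(cvp, m, pp),
                 fat_infiltration(cvf, m, pp))
  }
  # beyond coverage the grid is missing, never extrapolated
  expect_error(normalized_muscle_size(cvp, "supraspinatus", 90L),
               "beyond")
})

test_that("the per-scan pipeline reports coverage and flags low coverage", {
  spec <- phantom_spec(length_mm = 140, coverage = 0.35, seed = 74)
  ph <- generate_phantom(spec)
  # an oracle model that knows the true length (perfect prediction)
  m_fixed <- structure(list(
    coefficients = c("(Intercept)" = ph$truth$true_length_mm, PD_mm = 0,
                     PC_mm2 = 0, VB_mm = 0, HB_mm = 0),
    predictors = c("PD_mm", "PC_mm2", "VB_mm", "HB_mm"),
    response = "length_mm"), class = "scapula_length_model")
  sm <- compute_scan_metrics(ph$volume, m_fixed)
  expect_lt(abs(sm$coverage_percent - 35), 3)
  expect_false(sm$low_coverage)
  expect_true(all(sm$metrics$p <= sm$coverage_percent + 1e-9))
  # a PD-based model: at 70% coverage the lateral peak sits inside the
  # search window, so predicted length tracks the truth
  m_pd <- m_fixed
  m_pd$coefficients[] <- c(0, 1 / 0.3, 0, 0, 0)
  ph70 <- generate_phantom(phantom_spec(length_mm = 140, coverage = 0.7,
                                        seed = 74))
  sm70 <- compute_scan_metrics(ph70$volume, m_pd)
  expect_lt(abs(sm70$coverage_percent - 70), 8)
  ph25 <- generate_phantom(phantom_spec(length_mm = 140, coverage = 0.25,
                                        seed = 74))
  sm25 <- compute_scan_metrics(ph25$volume, m_fixed)
  expect_true(sm25$low_coverage)
  expect_lt(abs(sm25$coverage_percent - 25), 3)
  # full coverage: metrics defined on the whole grid
  ph100 <- generate_phantom(phantom_spec(length_mm = 140, seed = 74))
  sm100 <- compute_scan_metrics(ph100$volume, m_fixed)
  expect_equal(max(sm100$metrics$p), 100L)
  expect_equal(sm100$coverage_percent, 100)
})
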