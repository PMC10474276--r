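test_that("the normality gate picks Pearson for affine and Spearman for skewed data", {
  x <- with_seed_local(91, rnorm(33))
  cr <- correlation_gated(x, 2 * x + 1)
  expect_equal(cr$method, "pearson")
  expect_equal(cr$r, 1.0)
  # heavy-tailed monotone map: gate falls back to Spearman, rank r = 1
  h <- exp(3 * x)
  cr2 <- correlation_gated(h, h^3)
  expect_equal(cr2$method, "spearman")
  expect_equal(cr2$r, 1.0)
  expect_error(correlation_gated(rep(1, 10), rnorm(10)), "constant")
  expect_error(correlation_gated(rnorm(3), rnorm(3)), "at least 4")
})

test_that("gated correlation estimates are unbiased at the generating rho", {
  rs <- vapply(1:300, function(s) with_seed_local(1000 + s, {
    x <- rnorm(33)
    y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(33)
    correlation_gated(x, y)$r
  }), numeric(1))
  expect_lt(abs(mean(rs) - 0.8), 0.05)
})

test_that("partial-vs-full correlations are perfect for proportional cohorts", {
  # per-scan size factors chosen so voxel widths scale exactly
  scales <- seq(0.7, 1.4, by = 0.1)
  sets <- lapply(scales, function(scale) {
    vol <- make_prism_volume(n_slices = 50, spacing = c(2, 1, 1),
                             scap_cols = 11:(10 + 10 * scale),
                             muscle_cols = 11:(10 + 20 * scale))
    build_volume_curves(vol, 100)
  })
  tab <- partial_vs_full_analysis(sets)
  raw <- tab[tab$metric == "raw_volume", ]
  expect_true(all(abs(raw$r - 1) < 1e-8))
  # ratio metrics are constant across a purely proportional cohort:
  # their correlation is undefined and reported as missing
  expect_true(all(is.na(tab$r[tab$metric == "relative_contribution"])))
  expect_equal(sort(unique(tab$coverage_pct)), c(10, 20, 30, 40))
  expect_error(partial_vs_full_analysis(list()), "at least 4")
})

test_that("a cohort with independent medial information correlates better at deeper coverage", {
  r_by_cov <- function(seed) {
    specs <- lapply(1:10, function(i) {
      sp <- random_blob_spec(seed * 100 + i)
      sp$area_noise_sd <- 0.5
      sp
    })
    sets <- lapply(specs, function(sp) {
      ph <- generate_phantom(sp)
      build_volume_curves(ph$volume, ph$truth$true_length_mm)
    })
    tab <- partial_vs_full_analysis(sets)
    sub <- tab[tab$region == "supraspinatus" & tab$metric == "raw_volume", ]
    sub$r[order(sub$coverage_pct)]
  }
  rs <- t(vapply(1:12, r_by_cov, numeric(4)))
  wins <- sum(rs[, 4] > rs[, 1])
  expect_lt(stats::binom.test(wins, nrow(rs), 0.5,
                              alternative = "greater")$p.value, 0.05)
  expect_gt(mean(rs[, 4]), mean(rs[, 1]))
})

test_that("scapula-muscle sweep is exact for proportional cohorts and guards strata", {
  with_seed_local(93, {
    scales <- seq(0.6, 1.5, by = 0.1)
    sets <- lapply(scales, function(scale) {
      vol <- make_prism_volume(n_slices = 50, spacing = c(2, 1, 1),
                               scap_cols = 11:(10 + 10 * scale),
                               muscle_cols = 11:(10 + 20 * scale))
      build_volume_curves(vol, 100)
    })
    rec <- data.frame(sex = rep(c("male", "female"), 5),
                      age_years = runif(10, 18, 39))
    sw <- scapula_muscle_correlation_sweep(sets, rec, p_range = 30:32)
    expect_true(all(abs(sw$r - 1) < 1e-8))
    rec_m <- rec; rec_m$sex <- "male"
    expect_error(
      scapula_muscle_correlation_sweep(sets, rec_m,
                                       strata = c("male", "female")),
      "stratum")
  })
})

test_that("type III ANOVA matches the balanced closed-form decomposition", {
  with_seed_local(94, {
    sex <- rep(c("male", "female"), each = 24)
    bin <- rep(rep(levels(rc_age_bin(20)), each = 4), 2)
    y <- rnorm(48, 10, 2) + 0.8 * (sex == "male") +
      0.3 * as.integer(factor(bin))
    a <- two_way_anova(y, sex, bin)
    oracle <- balanced_anova_oracle(y, sex, bin)
    expect_equal(a$effects$F, oracle$F, tolerance = 1e-8)
    expect_equal(a$effects$partial_eta2, oracle$partial_eta2,
                 tolerance = 1e-8)
    expect_equal(a$effects$df, oracle$df)
    expect_equal(unique(a$effects$df_residual), oracle$df_e)
  })
})

test_that("identical group means give F of zero; empty cells error", {
  # every cell holds the same symmetric values: all cell means equal
  sex <- rep(c("male", "female"), each = 12)
  bin <- rep(rep(c("15-29", "30-39"), each = 6), 2)
  y <- rep(c(-1, 0, 1), 8)
  a <- two_way_anova(y, sex, bin)
  expect_equal(a$effects$F, rep(0, 3), tolerance = 1e-10)
  expect_equal(a$effects$partial_eta2, rep(0, 3), tolerance = 1e-10)
  bad_bin <- bin; bad_bin[sex == "male" & bin == "30-39"] <- "15-29"
  expect_error(two_way_anova(y, sex, bad_bin), "empty")
  expect_error(two_way_anova(y, rep("male", 24), bin), "2 levels")
})

test_that("reference database cells aggregate correctly and gate z-scoring", {
  met <- expand.grid(scan_id = sprintf("s%02d", 1:6),
                     muscle = rc_muscles(), stringsAsFactors = FALSE)
  met$sex <- "male"
  met$age_years <- 25
  met$metric <- "normalized_size"
  met$value <- 1.5  # identical scans
  db <- build_reference_database(met)
  expect_true(all(db$cells$sd == 0))
  expect_true(all(db$cells$n == 6L))
  expect_error(z_score(db, 1.5, "male", 25, "supraspinatus",
                       "normalized_size"), "unusable")
  # single-scan cells are flagged unusable
  db1 <- build_reference_database(met[met$scan_id == "s01", ])
  expect_true(all(!db1$cells$usable))
  # arithmetic: z of mean is 0, one SD above is 1
  met2 <- met
  met2$value <- rep(c(1, 2, 3, 4, 5, 6), times = 4)
  db2 <- build_reference_database(met2)
  mu <- mean(1:6); s <- sd(1:6)
  expect_equal(z_score(db2, mu, "male", 25, "supraspinatus",
                       "normalized_size"), 0)
  expect_equal(z_score(db2, mu + s, "male", 25, "supraspinatus",
                       "normalized_size"), 1)
  expect_error(z_score(db2, 1, "male", 104, "supraspinatus",
                       "normalized_size"), "outside")
  expect_error(z_score(db2, 1, "female", 25, "supraspinatus",
                       "normalized_size"), "no reference cell")
})

test_that("z-scores are invariant to common affine rescaling", {
  with_seed_local(96, {
    met <- data.frame(scan_id = sprintf("s%02d", 1:20),
                      sex = "female", age_years = runif(20, 30, 39),
                      muscle = "infraspinatus", metric = "normalized_size",
                      value = rnorm(20, 1.2, 0.2))
    db <- build_reference_database(met)
    z0 <- z_score(db, 1.4, "female", 35, "infraspinatus", "normalized_size")
    met2 <- met; met2$value <- 7 * met$value + 3
    db2 <- build_reference_database(met2)
    z1 <- z_score(db2, 7 * 1.4 + 3, "female", 35, "infraspinatus",
                  "normalized_size")
    expect_equal(z1, z0, tolerance = 1e-10)
  })
})

test_that("databases survive a JSON round trip", {
  with_seed_local(97, {
    met <- data.frame(scan_id = sprintf("s%02d", 1:12),
                      sex = rep(c("male", "female"), 6),
                      age_years = runif(12, 15, 89),
                      muscle = "teres_minor", metric = "fat_infiltration",
                      value = runif(12, 0, 15))
    db <- build_reference_database(met)
    path <- tempfile(fileext = ".json")
    write_reference_database(db, path)
    back <- read_reference_database(path)
    expect_equal(back$p_star, db$p_star)
    expect_equal(back$cells$mean, db$cells$mean)
    expect_equal(as.character(back$cells$age_bin),
                 as.character(db$cells$age_bin))
  })
})
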