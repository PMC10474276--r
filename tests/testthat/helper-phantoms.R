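# In-code fixtures and independent oracles shared across test files.

# internal helpers reached through the package namespace
roi_label <- function(schema, roi) rcmorph:::roi_label(schema, roi)
with_seed_local <- function(seed, code) rcmorph:::with_seed(seed, code)

# Build a label volume from axis-aligned blocks: each block is
# list(roi, slices, rows, cols), painted in order. Spacing in mm.
make_block_volume <- function(blocks, dim, spacing = c(2, 1, 1),
                              schema = default_roi_schema(),
                              laterality = "right") {
  arr <- array(0L, dim = dim)
  for (b in blocks)
    arr[b$slices, b$rows, b$cols] <- roi_label(schema, b$roi)
  label_volume(arr, spacing, schema = schema, laterality = laterality)
}

# Uniform coextensive prisms: scapula plus four muscles with constant
# cross-sections spanning `n_slices`, optionally with a fat sub-block.
make_prism_volume <- function(n_slices = 50, spacing = c(2, 1, 1),
                              scap_rows = 31:40, scap_cols = 11:20,
                              muscle_rows = list(supraspinatus = 1:10,
                                                 infraspinatus = 11:20,
                                                 teres_minor = 51:55,
                                                 subscapularis = 61:70),
                              muscle_cols = 11:30,
                              fat_cols = NULL) {
  blocks <- list(list(roi = "scapula", slices = 1:n_slices,
                      rows = scap_rows, cols = scap_cols))
  for (m in names(muscle_rows)) {
    blocks[[length(blocks) + 1L]] <- list(roi = m, slices = 1:n_slices,
                                          rows = muscle_rows[[m]],
                                          cols = muscle_cols)
    if (!is.null(fat_cols))
      blocks[[length(blocks) + 1L]] <- list(
        roi = paste0(m, "_fat"), slices = 1:n_slices,
        rows = muscle_rows[[m]], cols = fat_cols)
  }
  make_block_volume(blocks, dim = c(n_slices, 80, 40), spacing = spacing)
}

# Independent per-slice voxel-count oracle (direct loop; shares no code
# with the package's slice accumulation).
oracle_slice_counts <- function(vol, roi) {
  lab <- roi_label(vol$schema, roi)
  vapply(seq_len(dim(vol$voxels)[1]),
         function(i) sum(vol$voxels[i, , ] == lab), numeric(1))
}

# Oracle cumulative ml at slice boundaries measured from the scapular
# origin, folding any more-lateral ROI volume into the first slice.
oracle_boundary_ml <- function(vol, roi) {
  scap <- oracle_slice_counts(vol, "scapula")
  origin <- which(scap > 0)[1]
  cnt <- oracle_slice_counts(vol, roi)
  folded <- cnt[origin:length(cnt)]
  if (origin > 1) folded[1] <- folded[1] + sum(cnt[seq_len(origin - 1)])
  c(0, cumsum(folded)) * prod(vol$spacing) / 1000
}

# Closed-form balanced two-way ANOVA decomposition (textbook formulas).
balanced_anova_oracle <- function(y, A, B) {
  A <- as.factor(A); B <- as.factor(B)
  a <- nlevels(A); b <- nlevels(B)
  n <- length(y) / (a * b)
  g <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ss_a <- b * n * sum((mA - g)^2)
  ss_b <- a * n * sum((mB - g)^2)
  ss_ab <- n * sum((mAB - outer(mA - g, mB - g, `+`) - g)^2)
  ss_e <- sum((y - mAB[cbind(A, B)])^2)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1))
  df_e <- a * b * (n - 1)
  ss <- c(ss_a, ss_b, ss_ab)
  list(F = (ss / df) / (ss_e / df_e), df = df, df_e = df_e,
       partial_eta2 = ss / (ss + ss_e))
}

# A randomized phantom with slice-wise muscle-area noise ("random blob"),
# for voxel-count oracle checks.
random_blob_spec <- function(seed) {
  with_seed_local(seed, phantom_spec(
    length_mm = runif(1, 100, 160),
    peak_frac = runif(1, 0.2, 0.45),
    peak_csa_mm2 = runif(1, 450, 800),
    base_csa_mm2 = runif(1, 120, 250),
    end_csa_mm2 = runif(1, 40, 110),
    muscle_volumes_mm3 = c(supraspinatus = runif(1, 2e4, 5e4),
                           infraspinatus = runif(1, 3e4, 7e4),
                           teres_minor = runif(1, 0.8e4, 1.6e4),
                           subscapularis = runif(1, 3e4, 8e4)),
    fat_fractions = c(supraspinatus = runif(1, 0, 0.2),
                      infraspinatus = runif(1, 0, 0.2),
                      teres_minor = runif(1, 0, 0.2),
                      subscapularis = runif(1, 0, 0.2)),
    area_noise_sd = 0.3,
    seed = seed))
}

# Resample a fixed volume through the inverse of a known rigid transform,
# producing a "moving" volume whose registration ground truth is known.
make_moving_volume <- function(fixed, rotation_deg, translation_mm,
                               pad = c(10L, 15L, 15L)) {
  tr <- rigid_transform(euler_rotation(rotation_deg), translation_mm)
  tinv <- invert_rigid_transform(tr)
  shift <- pad * fixed$spacing
  tm <- rigid_transform(tinv$rotation, tinv$translation + shift)
  moving <- apply_transform(fixed, tm, dim = dim(fixed$voxels) + 2L * pad,
                            spacing = fixed$spacing)
  truth <- invert_rigid_transform(tm)  # maps moving -> fixed
  list(moving = moving, truth = truth)
}
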