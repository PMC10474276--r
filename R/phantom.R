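#' Specification of a synthetic shoulder phantom
#'
#' Parameterizes a geometric shoulder phantom with fully known ground
#' truth: a scapula whose per-slice cross-sectional area follows a
#' rise-to-peak-then-taper profile (the lateral peak the length regression
#' relies on), four disjoint muscle compartments of prescribed volume with
#' i.i.d.-assigned intramuscular fat voxels, optional bone blobs, and a
#' lateral truncation emulating partial clinical coverage.
#'
#' @param length_mm True sagittal scapula length (mm).
#' @param peak_frac Peak-CSA location as a fraction of length (default
#'   0.3; values > 0.5 give a pathological medial-peak phantom for probing
#'   the lateral search window).
#' @param peak_csa_mm2,base_csa_mm2,end_csa_mm2 CSA (mm^2) at the peak, at
#'   the lateral origin, and at the medial end; the profile is piecewise
#'   linear through these.
#' @param scapula_height_mm Vertical extent of the scapular cross-section
#'   (constant across slices); the horizontal extent carries the CSA
#'   variation.
#' @param muscle_volumes_mm3 Named vector (the four [rc_muscles()]) of
#'   target full-length compartment volumes (mm^3), fat included.
#' @param muscle_extent_frac Named vector: fraction of the scapular length
#'   each compartment spans from the lateral origin (default 1).
#' @param fat_fractions Named vector of per-muscle intramuscular fat
#'   fractions in `[0, 1)`.
#' @param area_noise_sd SD of multiplicative slice-wise noise on muscle
#'   cross-sections (default 0; used to build cohorts whose medial volume
#'   carries independent information).
#' @param coverage Captured fraction of the scapular extent in `(0, 1]`.
#' @param spacing Voxel spacing (sagittal, row, column) mm.
#' @param lateral_margin_slices Empty slices lateral to the scapular
#'   origin.
#' @param medial_margin_slices Captured empty slices medial to the scapula
#'   (only meaningful at full coverage).
#' @param include_bones Add small humerus and clavicle blobs so the full
#'   11-region schema is exercised.
#' @param seed RNG seed; generation is bit-reproducible given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(length_mm = 140,
                         peak_frac = 0.3,
                         peak_csa_mm2 = 650,
                         base_csa_mm2 = 200,
                         end_csa_mm2 = 80,
                         scapula_height_mm = 24,
                         muscle_volumes_mm3 = c(supraspinatus = 40000,
                                                infraspinatus = 55000,
                                                teres_minor = 12000,
                                                subscapularis = 60000),
                         muscle_extent_frac = c(supraspinatus = 1,
                                                infraspinatus = 1,
                                                teres_minor = 1,
                                                subscapularis = 1),
                         fat_fractions = c(supraspinatus = 0.05,
                                           infraspinatus = 0.05,
                                           teres_minor = 0.05,
                                           subscapularis = 0.05),
                         area_noise_sd = 0,
                         coverage = 1.0,
                         spacing = c(2, 1, 1),
                         lateral_margin_slices = 1L,
                         medial_margin_slices = 0L,
                         include_bones = TRUE,
                         seed = 1L) {
  muscles <- rc_muscles()
  muscle_volumes_mm3 <- muscle_volumes_mm3[muscles]
  muscle_extent_frac <- muscle_extent_frac[muscles]
  fat_fractions <- fat_fractions[muscles]
  if (anyNA(muscle_volumes_mm3) || anyNA(fat_fractions) ||
      anyNA(muscle_extent_frac))
    stop("muscle parameter vectors must name all four muscles", call. = FALSE)
  if (length_mm <= 0) stop("length_mm must be positive", call. = FALSE)
  if (coverage <= 0 || coverage > 1)
    stop("coverage must be in (0, 1]", call. = FALSE)
  if (any(fat_fractions < 0 | fat_fractions >= 1))
    stop("fat fractions must be in [0, 1)", call. = FALSE)
  if (peak_frac <= 0 || peak_frac >= 1)
    stop("peak_frac must be in (0, 1)", call. = FALSE)
  if (any(muscle_extent_frac <= 0 | muscle_extent_frac > 1))
    stop("muscle_extent_frac must be in (0, 1]", call. = FALSE)
  if (any(c(peak_csa_mm2, base_csa_mm2, end_csa_mm2, scapula_height_mm) <= 0))
    stop("CSA and height parameters must be positive", call. = FALSE)
  structure(as.list(environment())[c(
    "length_mm", "peak_frac", "peak_csa_mm2", "base_csa_mm2", "end_csa_mm2",
    "scapula_height_mm", "muscle_volumes_mm3", "muscle_extent_frac",
    "fat_fractions", "area_noise_sd", "coverage", "spacing",
    "lateral_margin_slices", "medial_margin_slices", "include_bones",
    "seed")], class = "phantom_spec")
}

# round a per-slice voxel-count series so the cumulative sum tracks the
# real-valued target (error-diffusion rounding: total error < 1 voxel)
cumulative_round <- function(x) {
  diff(c(0L, as.integer(round(cumsum(x)))))
}

# draw a centred horizontal run of `w` voxels within rows `rows` of slice i
paint_block <- function(arr, i, rows, width, ncol_plane, label) {
  if (width < 1L) return(arr)
  width <- min(width, ncol_plane)
  c0 <- floor((ncol_plane - width) / 2) + 1L
  arr[i, rows, c0:(c0 + width - 1L)] <- label
  arr
}

#' Generate a synthetic shoulder phantom with known ground truth
#'
#' Rasterizes a [phantom_spec()] into a labelled volume and a ground-truth
#' manifest. Structures occupy disjoint row bands of the image plane
#' (idealized geometry — the phantom reproduces the measurement problem,
#' not scapular anatomy). Scapular per-slice areas are realized by nearest
#' rounding (within one voxel row of the analytic target); muscle
#' compartments use error-diffusion rounding so total volume tracks the
#' target to well under 2%. Fat voxels are assigned i.i.d. within each
#' compartment at the specified fraction; finally the volume is truncated
#' to the requested coverage fraction of the scapular extent.
#'
#' @param spec A [phantom_spec()].
#' @param schema ROI schema used to label the structures.
#' @return List with elements `volume` (a [label_volume()], truncated) and
#'   `truth`: `true_length_mm` (rasterized scapular extent),
#'   `n_scapula_slices`, `full_volumes_ml` (per ROI, untruncated),
#'   `cumulative_ml` (100 x ROI matrix: untruncated cumulative volume at
#'   every 1% of true length), `fat_fraction_realized`,
#'   `captured_slices`, and the `spec`.
#' @export
generate_phantom <- function(spec, schema = default_roi_schema()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    sp <- spec$spacing
    n_scap <- max(3L, as.integer(round(spec$length_mm / sp[1])))
    true_length <- n_scap * sp[1]
    x_mid <- (seq_len(n_scap) - 0.5) * sp[1]
    csa <- stats::approx(x = c(0, spec$peak_frac * true_length, true_length),
                         y = c(spec$base_csa_mm2, spec$peak_csa_mm2,
                               spec$end_csa_mm2),
                         xout = x_mid, rule = 2)$y
    inplane_mm2 <- sp[2] * sp[3]
    scap_h <- max(2L, as.integer(round(spec$scapula_height_mm / sp[2])))
    scap_w <- pmax(1L, as.integer(round(csa / (scap_h * inplane_mm2))))

    muscles <- rc_muscles()
    mus_span <- pmax(1L, as.integer(round(spec$muscle_extent_frac * n_scap)))
    names(mus_span) <- muscles
    mus_area <- spec$muscle_volumes_mm3 / (mus_span * sp[1])  # mm^2 per slice
    mus_h <- pmax(2L, as.integer(round(sqrt(mus_area) / sp[2])))
    names(mus_h) <- muscles
    mus_w <- list()
    for (m in muscles) {
      a <- rep(mus_area[[m]], mus_span[[m]])
      if (spec$area_noise_sd > 0)
        a <- a * pmax(0, 1 + stats::rnorm(length(a), 0, spec$area_noise_sd))
      mus_w[[m]] <- cumulative_round(a / (mus_h[[m]] * inplane_mm2))
    }

    gap <- 2L
    bone_h <- if (spec$include_bones) 4L else 0L
    heights <- c(bone = bone_h, supraspinatus = mus_h[["supraspinatus"]],
                 infraspinatus = mus_h[["infraspinatus"]], scapula = scap_h,
                 teres_minor = mus_h[["teres_minor"]],
                 subscapularis = mus_h[["subscapularis"]])
    heights <- heights[heights > 0L]
    tops <- cumsum(c(2L, heights + gap))
    bands <- lapply(seq_along(heights), function(k)
      tops[k]:(tops[k] + heights[k] - 1L))
    names(bands) <- names(heights)
    n_rows <- tops[length(tops)] + 2L
    n_cols <- max(scap_w, vapply(mus_w, max, numeric(1)), 8L) + 4L
    n1_full <- spec$lateral_margin_slices + n_scap + spec$medial_margin_slices
    if (n_rows > 4096L || n_cols > 4096L)
      stop("phantom compartments cannot fit in the grid", call. = FALSE)

    arr <- array(0L, dim = c(n1_full, n_rows, n_cols))
    off <- spec$lateral_margin_slices
    for (i in seq_len(n_scap))
      arr <- paint_block(arr, off + i, bands$scapula, scap_w[i], n_cols,
                         roi_label(schema, "scapula"))
    for (m in muscles) {
      lab <- roi_label(schema, m)
      w <- mus_w[[m]]
      for (i in seq_len(mus_span[[m]]))
        arr <- paint_block(arr, off + i, bands[[m]], w[i], n_cols, lab)
    }
    if (spec$include_bones) {
      bw <- 4L
      hum_slices <- off + seq_len(min(3L, n_scap))
      arr[hum_slices, bands$bone, 3:(2L + bw)] <-
        roi_label(schema, "humerus")
      arr[hum_slices, bands$bone, (n_cols - bw - 1L):(n_cols - 2L)] <-
        roi_label(schema, "clavicle")
    }

    # fat assignment, i.i.d. within each compartment
    fat_real <- stats::setNames(numeric(length(muscles)), muscles)
    for (m in muscles) {
      f <- spec$fat_fractions[[m]]
      idx <- which(arr == roi_label(schema, m))
      if (f > 0 && length(idx)) {
        take <- stats::runif(length(idx)) < f
        arr[idx[take]] <- roi_label(schema, fat_roi_of(schema, m))
        fat_real[m] <- mean(take)
      } else fat_real[m] <- 0
    }

    # ground truth from the untruncated rasterization (voxel counting)
    voxml <- prod(sp) / 1000
    rois <- names(schema$labels)
    full_volumes <- vapply(rois, function(r)
      sum(arr == roi_label(schema, r)) * voxml, numeric(1))
    K <- n1_full - (off + 1L) + 1L
    depth <- (0:K) * sp[1]
    cum100 <- matrix(NA_real_, 100L, length(rois),
                     dimnames = list(1:100, rois))
    for (r in rois) {
      cnt <- vapply(seq_len(n1_full), function(i)
        sum(arr[i, , ] == roi_label(schema, r)), numeric(1))
      folded <- cnt[(off + 1L):n1_full]
      if (off > 0L) folded[1] <- folded[1] + sum(cnt[seq_len(off)])
      cum <- c(0, cumsum(folded)) * voxml
      cum100[, r] <- stats::approx(depth, cum, xout = (1:100) / 100 * true_length,
                                   rule = 2)$y
    }

    keep <- off + as.integer(ceiling(spec$coverage * n_scap))
    arr_cap <- arr[seq_len(keep), , , drop = FALSE]
    vol <- label_volume(arr_cap, sp, schema = schema, laterality = "right")
    list(volume = vol,
         truth = list(true_length_mm = true_length,
                      n_scapula_slices = n_scap,
                      full_volumes_ml = full_volumes,
                      cumulative_ml = cum100,
                      fat_fraction_realized = fat_real,
                      captured_slices = keep,
                      spec = spec))
  })
}

#' Specification of a synthetic cohort
#'
#' Parameterizes a demographically structured cohort of phantoms: per-cell
#' sample sizes over sex and the six age subgroups, generating
#' distributions for scapula size and muscle metrics, multiplicative age
#' and sex effects, a muscle-to-scapula volume coupling, and fat-fraction
#' effects — the knobs needed to emulate (or null out) cohort-level
#' structure with known truth.
#'
#' @param n_per_cell Scans per (sex x age-bin) cell (scalar or 2 x 6
#'   matrix).
#' @param scapula_length_mean_mm Named (`male`, `female`) mean lengths.
#' @param scapula_length_sd_mm SD of length within cell.
#' @param base_normalized_size Named per-muscle baseline normalized size
#'   (dimensionless, at the analysis coverage).
#' @param age_slope_size Named per-muscle fractional change in size per age
#'   bin step (e.g. -0.06 gives a 30% decline from bin 1 to bin 6).
#' @param sex_effect_size Named per-muscle multiplicative factor applied to
#'   females (1 = no effect).
#' @param base_fat_fraction Named per-muscle baseline fat fraction.
#' @param age_slope_fat Named per-muscle additive fat-fraction change per
#'   bin step.
#' @param sex_effect_fat Named per-muscle additive fat-fraction offset for
#'   females.
#' @param muscle_scapula_cor Coupling rho in `[0, 1]` between (log) muscle
#'   and scapula volumes: 1 gives exact proportionality, 0 independence.
#' @param size_noise_sd SD of the per-scan log-normal size noise.
#' @param fat_noise_sd SD of the per-scan fat-fraction noise.
#' @param coverage_range Range the per-scan captured coverage fraction is
#'   drawn from (uniform).
#' @param p_star Analysis coverage percent the metric truth refers to.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_cell = 14L,
                        scapula_length_mean_mm = c(male = 152, female = 140),
                        scapula_length_sd_mm = 12,
                        base_normalized_size = c(supraspinatus = 0.8,
                                                 infraspinatus = 1.0,
                                                 teres_minor = 0.25,
                                                 subscapularis = 1.1),
                        age_slope_size = c(supraspinatus = 0,
                                           infraspinatus = 0,
                                           teres_minor = 0,
                                           subscapularis = 0),
                        sex_effect_size = c(supraspinatus = 1,
                                            infraspinatus = 1,
                                            teres_minor = 1,
                                            subscapularis = 1),
                        base_fat_fraction = c(supraspinatus = 0.05,
                                              infraspinatus = 0.05,
                                              teres_minor = 0.05,
                                              subscapularis = 0.05),
                        age_slope_fat = c(supraspinatus = 0,
                                          infraspinatus = 0,
                                          teres_minor = 0,
                                          subscapularis = 0),
                        sex_effect_fat = c(supraspinatus = 0,
                                           infraspinatus = 0,
                                           teres_minor = 0,
                                           subscapularis = 0),
                        muscle_scapula_cor = 0.9,
                        size_noise_sd = 0.15,
                        fat_noise_sd = 0.01,
                        coverage_range = c(0.35, 0.6),
                        p_star = 30,
                        seed = 1L) {
  muscles <- rc_muscles()
  for (nm in c("base_normalized_size", "age_slope_size", "sex_effect_size",
               "base_fat_fraction", "age_slope_fat", "sex_effect_fat")) {
    v <- get(nm)[muscles]
    if (anyNA(v)) stop(nm, " must name all four muscles", call. = FALSE)
    assign(nm, v)
  }
  bins <- levels(rc_age_bin(20))
  n_per_cell <- if (length(n_per_cell) == 1L)
    matrix(as.integer(n_per_cell), 2L, 6L,
           dimnames = list(c("male", "female"), bins))
  else matrix(as.integer(n_per_cell), 2L, 6L,
              dimnames = list(c("male", "female"), bins))
  if (any(n_per_cell < 0L)) stop("n_per_cell must be >= 0", call. = FALSE)
  if (muscle_scapula_cor < 0 || muscle_scapula_cor > 1)
    stop("muscle_scapula_cor must be in [0, 1]", call. = FALSE)
  if (any(scapula_length_sd_mm < 0, size_noise_sd < 0, fat_noise_sd < 0))
    stop("SD parameters must be >= 0", call. = FALSE)
  structure(as.list(environment())[c(
    "n_per_cell", "scapula_length_mean_mm", "scapula_length_sd_mm",
    "base_normalized_size", "age_slope_size", "sex_effect_size",
    "base_fat_fraction", "age_slope_fat", "sex_effect_fat",
    "muscle_scapula_cor", "size_noise_sd", "fat_noise_sd",
    "coverage_range", "p_star", "seed")], class = "cohort_spec")
}

#' Generate a synthetic cohort with ground-truth tables
#'
#' Draws a demographically structured cohort from a [cohort_spec()]. For
#' every scan it generates a scapula length, cell-level metric truth
#' (normalized size, relative contribution and fat infiltration at the
#' analysis coverage, with age and sex effects and muscle-scapula
#' coupling applied), and a per-scan [phantom_spec()]. Statistical
#' simulations (ANOVA calibration, reference-database checks) can use the
#' metric truth directly; set `rasterize = TRUE` to also rasterize each
#' scan into a label volume for pipeline-level analyses.
#'
#' @param spec A [cohort_spec()].
#' @param rasterize Rasterize every scan into a [label_volume()]
#'   (default `FALSE`; intended for small cohorts).
#' @param retry_cap Resampling attempts for an infeasible per-scan draw
#'   before aborting (default 10).
#' @return List with `records` (scan_id, sex, age_years, age_bin,
#'   laterality), `truth` (long data frame: scan_id, muscle,
#'   scapula_volume_ml, muscle_volume_ml, normalized_size,
#'   relative_contribution, fat_infiltration at `p_star`), `specs`
#'   (per-scan `phantom_spec`s), and — when `rasterize` — `phantoms`
#'   (list of [generate_phantom()] results).
#' @export
generate_cohort <- function(spec, rasterize = FALSE, retry_cap = 10L) {
  stopifnot(inherits(spec, "cohort_spec"))
  muscles <- rc_muscles()
  bins <- colnames(spec$n_per_cell)
  bin_mid <- c(`15-29` = 22, `30-39` = 35, `40-49` = 45, `50-59` = 55,
               `60-69` = 65, `70-89` = 77)
  bin_half <- c(`15-29` = 7, `30-39` = 4.9, `40-49` = 4.9, `50-59` = 4.9,
                `60-69` = 4.9, `70-89` = 9.9)
  with_seed(spec$seed, {
    records <- list(); truth <- list(); specs <- list()
    id <- 0L
    for (sex in rownames(spec$n_per_cell)) for (b in bins) {
      n <- spec$n_per_cell[sex, b]
      if (n == 0L) next
      step <- match(b, bins) - 1L
      for (k in seq_len(n)) {
        id <- id + 1L
        sid <- sprintf("scan%03d", id)
        age <- stats::runif(1, bin_mid[[b]] - bin_half[[b]],
                            bin_mid[[b]] + bin_half[[b]])
        L <- max(90, stats::rnorm(1, spec$scapula_length_mean_mm[[sex]],
                                  spec$scapula_length_sd_mm))
        # scapula volume at the analysis coverage scales with length^3
        vs <- 0.06 * (L / 150)^3 * 1000  # ml at p_star, ~60 ml scale
        log_vs_dev <- log(vs / (0.06 * 1000))
        rho <- spec$muscle_scapula_cor
        ns <- fat <- stats::setNames(numeric(4), muscles)
        for (m in muscles) {
          base <- spec$base_normalized_size[[m]] *
            (1 + spec$age_slope_size[[m]] * step) *
            (if (sex == "female") spec$sex_effect_size[[m]] else 1)
          noise <- if (spec$size_noise_sd > 0)
            exp(sqrt(1 - rho^2) * spec$size_noise_sd * stats::rnorm(1)) else 1
          # muscle volume couples to scapula volume through rho
          vm <- base * vs^rho * (0.06 * 1000)^(1 - rho) * noise
          ns[m] <- vm / vs
          f <- spec$base_fat_fraction[[m]] + spec$age_slope_fat[[m]] * step +
            (if (sex == "female") spec$sex_effect_fat[[m]] else 0) +
            stats::rnorm(1, 0, spec$fat_noise_sd)
          fat[m] <- min(0.95, max(0, f))
        }
        vm_ml <- ns * vs
        rc <- vm_ml / sum(vm_ml) * 100
        truth[[id]] <- data.frame(
          scan_id = sid, muscle = muscles,
          scapula_volume_ml = vs, muscle_volume_ml = unname(vm_ml),
          normalized_size = unname(ns),
          relative_contribution = unname(rc),
          fat_infiltration = unname(fat * 100), row.names = NULL)
        records[[id]] <- data.frame(
          scan_id = sid, sex = sex, age_years = age, age_bin = b,
          laterality = sample(c("right", "left"), 1))
        # full-length compartment volumes, assuming the p_star fraction
        # holds the p_star/100 share of a uniform compartment
        full_vm_mm3 <- unname(vm_ml) * 1000 * 100 / spec$p_star
        specs[[id]] <- phantom_spec(
          length_mm = L,
          peak_csa_mm2 = 450 * (L / 150)^2,
          base_csa_mm2 = 150 * (L / 150)^2,
          end_csa_mm2 = 60 * (L / 150)^2,
          scapula_height_mm = 20 * (L / 150),
          muscle_volumes_mm3 = stats::setNames(full_vm_mm3, muscles),
          fat_fractions = stats::setNames(unname(fat), muscles),
          coverage = stats::runif(1, spec$coverage_range[1],
                                  spec$coverage_range[2]),
          seed = spec$seed * 1000L + id)
      }
    }
    if (!id) stop("cohort spec generates no scans", call. = FALSE)
    out <- list(records = do.call(rbind, records),
                truth = do.call(rbind, truth),
                specs = specs, p_star = spec$p_star)
    if (rasterize) {
      out$phantoms <- lapply(specs, function(ps) {
        for (attempt in seq_len(retry_cap)) {
          res <- tryCatch(generate_phantom(ps), error = function(e) e)
          if (!inherits(res, "error")) return(res)
          ps$seed <- ps$seed + 100000L
        }
        stop("phantom generation failed after ", retry_cap,
             " attempts: ", conditionMessage(res), call. = FALSE)
      })
    }
    out
  })
}
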