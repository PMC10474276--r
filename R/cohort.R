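#' Normality-gated correlation
#'
#' Correlates two numeric series, choosing the method by distributional
#' shape: Pearson's correlation when both series pass a Shapiro-Wilk
#' normality test (p > `alpha` for each), Spearman's rank correlation
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped); at least 4 complete pairs.
#' @param alpha Normality-gate level (default 0.05).
#' @return An object of class `correlation_result`: `method` ("pearson" or
#'   "spearman"), `r`, `p_value`, `n`, and the two `shapiro_p` values.
#' @export
correlation_gated <- function(x, y, alpha = 0.05) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs, got ", n, call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  sw <- c(x = stats::shapiro.test(x)$p.value,
          y = stats::shapiro.test(y)$p.value)
  method <- if (all(sw > alpha)) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  structure(list(method = method, r = unname(ct$estimate),
                 p_value = ct$p.value, n = n, shapiro_p = sw),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s r = %.3f (p = %.3g, n = %d)\n", x$method, x$r, x$p_value, x$n))
  invisible(x)
}

#' Partial- versus full-coverage metric correlations
#'
#' For a cohort of full-coverage scans, computes raw volume, normalized
#' volume, and relative contribution at each lateral truncation (percent
#' coverage) and at full coverage, then correlates truncated against full
#' values across scans with the normality-gated correlation. Raw volume is
#' reported for the scapula and the four muscles (with intramuscular fat);
#' normalized volume and relative contribution for the muscles only.
#'
#' @param curve_sets List of [build_volume_curves()] results, each with
#'   coverage effectively 100% (at least `max(coverages)` is required of
#'   every scan).
#' @param coverages Integer percent truncations (default 10, 20, 30, 40).
#' @param alpha Normality-gate level for [correlation_gated()].
#' @return Data frame with columns `region`, `metric`, `coverage_pct`,
#'   `method`, `r`, `p_value`, `n`. Rows whose truncated or full series is
#'   constant across the cohort (correlation undefined) are reported with
#'   `NA`.
#' @export
partial_vs_full_analysis <- function(curve_sets, coverages = c(10, 20, 30, 40),
                                     alpha = 0.05) {
  n <- length(curve_sets)
  if (n < 4L) stop("need a cohort of at least 4 scans, got ", n, call. = FALSE)
  ok <- vapply(curve_sets, function(cs)
    max(defined_percents(cs)) >= 100L, logical(1))
  if (!all(ok))
    stop("all scans must have full (100%) coverage; ",
         sum(!ok), " do not", call. = FALSE)
  value_of <- function(cs, region, metric, p) {
    switch(metric,
      raw_volume = if (region == "scapula") curve_at(cs, "scapula", p)
                   else boundary_at(cs, region, p),
      normalized_volume = as.numeric(normalized_muscle_size(cs, region, p)),
      relative_contribution = as.numeric(relative_contribution(cs, region, p)))
  }
  grid <- rbind(
    data.frame(region = "scapula", metric = "raw_volume"),
    expand.grid(region = rc_muscles(),
                metric = c("raw_volume", "normalized_volume",
                           "relative_contribution"),
                stringsAsFactors = FALSE))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    region <- grid$region[i]; metric <- grid$metric[i]
    full <- vapply(curve_sets, value_of, numeric(1),
                   region = region, metric = metric, p = 100L)
    for (cv in coverages) {
      part <- vapply(curve_sets, value_of, numeric(1),
                     region = region, metric = metric, p = as.integer(cv))
      cr <- tryCatch(correlation_gated(part, full, alpha = alpha),
                     error = function(e) NULL)
      # a constant series (e.g. identical relative contributions across
      # scans) has no defined correlation; report the row as missing
      out[[length(out) + 1L]] <- data.frame(
        region = region, metric = metric, coverage_pct = cv,
        method = if (is.null(cr)) NA_character_ else cr$method,
        r = if (is.null(cr)) NA_real_ else cr$r,
        p_value = if (is.null(cr)) NA_real_ else cr$p_value,
        n = n)
    }
  }
  do.call(rbind, out)
}

#' Scapula-versus-muscle volume correlation sweep
#'
#' Validates scapular volume as a patient-size normalizer: at each percent
#' location p, correlates cumulative scapula volume against each muscle's
#' cumulative volume across scans — overall and split by sex. To avoid
#' age-related atrophy confounding the size relationship, only scans below
#' `max_age` are used (default 40 years).
#'
#' @param curve_sets List of [build_volume_curves()] results.
#' @param records Data frame aligned with `curve_sets`, with columns `sex`
#'   (`"male"`/`"female"`) and `age_years`.
#' @param p_range Integer percent locations (default `30:40`).
#' @param strata Which strata to report (subset of
#'   `c("all", "male", "female")`).
#' @param max_age Upper age bound (exclusive) for inclusion.
#' @param alpha Normality-gate level.
#' @return Data frame with columns `p`, `muscle`, `stratum`, `method`, `r`,
#'   `p_value`, `n`.
#' @export
scapula_muscle_correlation_sweep <- function(curve_sets, records,
                                             p_range = 30:40,
                                             strata = c("all", "male", "female"),
                                             max_age = 40, alpha = 0.05) {
  stopifnot(length(curve_sets) == nrow(records))
  strata <- match.arg(strata, several.ok = TRUE)
  keep <- records$age_years < max_age
  curve_sets <- curve_sets[keep]
  records <- records[keep, , drop = FALSE]
  idx_of <- list(all = seq_along(curve_sets),
                 male = which(records$sex == "male"),
                 female = which(records$sex == "female"))
  out <- list()
  for (st in strata) {
    idx <- idx_of[[st]]
    if (length(idx) < 4L)
      stop("stratum '", st, "' has fewer than 4 eligible scans (",
           length(idx), ")", call. = FALSE)
    for (p in p_range) {
      scap <- vapply(curve_sets[idx], curve_at, numeric(1),
                     roi = "scapula", p = as.integer(p))
      for (m in rc_muscles()) {
        mus <- vapply(curve_sets[idx], boundary_at, numeric(1),
                      muscle = m, p = as.integer(p))
        cr <- correlation_gated(scap, mus, alpha = alpha)
        out[[length(out) + 1L]] <- data.frame(
          p = p, muscle = m, stratum = st, method = cr$method,
          r = cr$r, p_value = cr$p_value, n = cr$n)
      }
    }
  }
  do.call(rbind, out)
}

#' Two-way factorial ANOVA with partial eta-squared
#'
#' Sex-by-age-group factorial ANOVA with interaction, Type III sums of
#' squares (computed on sum-to-zero contrasts, the convention matching
#' mainstream statistical software on unbalanced designs), partial
#' eta-squared effect sizes, and Bonferroni-adjusted pairwise post-hoc
#' comparisons within each main effect.
#'
#' @param values Numeric response (one metric, e.g. normalized size of one
#'   muscle at a chosen coverage).
#' @param sex Factor or character, two levels.
#' @param age_bin Factor or character, the age subgroup of each scan.
#' @param type Sum-of-squares type, `"III"` (default) or `"II"`.
#' @param posthoc Run pairwise post-hoc tests (default `TRUE`).
#' @return An object of class `rc_anova`: `effects` data frame (`effect`,
#'   `df`, `df_residual`, `F`, `p_value`, `partial_eta2`) and `posthoc`
#'   (list of Bonferroni-adjusted pairwise p-value matrices per factor).
#' @export
two_way_anova <- function(values, sex, age_bin, type = c("III", "II"),
                          posthoc = TRUE) {
  type <- match.arg(type)
  sex <- droplevels(as.factor(sex))
  age_bin <- droplevels(as.factor(age_bin))
  if (nlevels(sex) < 2L || nlevels(age_bin) < 2L)
    stop("each factor needs at least 2 levels", call. = FALSE)
  if (length(values) != length(sex) || length(values) != length(age_bin))
    stop("values and factor labels must have equal length", call. = FALSE)
  cells <- table(sex, age_bin)
  if (any(cells == 0L))
    stop("empty design cell(s): ",
         paste(which(cells == 0L, arr.ind = TRUE), collapse = ", "),
         "; Type III effects are not estimable", call. = FALSE)
  d <- data.frame(y = values, sex = sex, age_bin = age_bin)
  fit <- stats::lm(y ~ sex * age_bin, data = d,
                   contrasts = list(sex = "contr.sum", age_bin = "contr.sum"))
  a <- car::Anova(fit, type = type)
  ss <- a[["Sum Sq"]]
  names(ss) <- rownames(a)
  ss_res <- ss[["Residuals"]]
  df_res <- a["Residuals", "Df"]
  eff_names <- setdiff(rownames(a), c("(Intercept)", "Residuals"))
  effects <- data.frame(
    effect = c("sex", "age", "sex:age"),
    df = a[eff_names, "Df"],
    df_residual = df_res,
    F = a[eff_names, "F value"],
    p_value = a[eff_names, "Pr(>F)"],
    partial_eta2 = ss[eff_names] / (ss[eff_names] + ss_res),
    row.names = NULL)
  ph <- NULL
  if (posthoc) {
    ph <- list(
      age = stats::pairwise.t.test(d$y, d$age_bin,
                                   p.adjust.method = "bonferroni")$p.value,
      sex = stats::pairwise.t.test(d$y, d$sex,
                                   p.adjust.method = "bonferroni")$p.value)
  }
  structure(list(effects = effects, posthoc = ph, cells = cells, type = type),
            class = "rc_anova")
}

#' @export
print.rc_anova <- function(x, ...) {
  cat("Two-way ANOVA (Type", x$type, "sums of squares)\n")
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-8s F(%d, %d) = %6.2f, p = %.4g, partial eta^2 = %.3f\n",
                e$effect[i], e$df[i], e$df_residual[i], e$F[i],
                e$p_value[i], e$partial_eta2[i]))
  invisible(x)
}

#' Age subgroup of an age in years
#'
#' Bins ages into the six normative subgroups 15-29, 30-39, 40-49, 50-59,
#' 60-69, 70-89. Ages outside `[15, 89]` yield `NA`.
#'
#' @param age_years Numeric vector of ages.
#' @return Factor with the six bin labels.
#' @export
rc_age_bin <- function(age_years) {
  cut(age_years, breaks = c(15, 30, 40, 50, 60, 70, 90),
      labels = c("15-29", "30-39", "40-49", "50-59", "60-69", "70-89"),
      right = FALSE)
}

#' Build a normative reference database
#'
#' Aggregates cohort metrics into per-cell (sex x age-bin x muscle x
#' metric) mean, SD and n at a chosen analysis coverage, the lookup table
#' against which an individual scan is z-scored. Cells with fewer than 2
#' scans are marked unusable.
#'
#' @param metrics Long data frame with columns `scan_id`, `sex`,
#'   `age_years`, `muscle`, `metric`, `value` — one row per scan, muscle
#'   and metric, with values already taken at the analysis coverage.
#' @param p_star Analysis coverage percent the values were taken at
#'   (default 30; recorded, and checked by [z_score()]).
#' @return An object of class `reference_database`: `cells` data frame
#'   (`sex`, `age_bin`, `muscle`, `metric`, `mean`, `sd`, `n`, `usable`)
#'   and `p_star`.
#' @export
build_reference_database <- function(metrics, p_star = 30) {
  need <- c("scan_id", "sex", "age_years", "muscle", "metric", "value")
  missing_cols <- setdiff(need, names(metrics))
  if (length(missing_cols))
    stop("metrics lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  metrics$age_bin <- rc_age_bin(metrics$age_years)
  metrics <- metrics[!is.na(metrics$age_bin) & !is.na(metrics$value), ]
  if (!nrow(metrics)) stop("no eligible scans", call. = FALSE)
  agg <- stats::aggregate(value ~ sex + age_bin + muscle + metric,
                          data = metrics, FUN = function(v)
                            c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  cells <- data.frame(sex = agg$sex, age_bin = agg$age_bin,
                      muscle = agg$muscle, metric = agg$metric,
                      mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                      n = as.integer(agg$value[, "n"]))
  cells$sd[cells$n < 2L] <- NA_real_
  cells$usable <- cells$n >= 2L
  structure(list(cells = cells, p_star = p_star),
            class = "reference_database")
}

#' @export
print.reference_database <- function(x, ...) {
  cat(sprintf("reference_database at %g%% coverage: %d cells (%d usable)\n",
              x$p_star, nrow(x$cells), sum(x$cells$usable)))
  cat(sprintf("  metrics: %s\n",
              paste(unique(x$cells$metric), collapse = ", ")))
  invisible(x)
}

#' Serialize a reference database to JSON (and back)
#'
#' @param db A [build_reference_database()] result.
#' @param path JSON file path.
#' @return `write_reference_database()` returns `path` invisibly;
#'   `read_reference_database()` returns a `reference_database`.
#' @export
write_reference_database <- function(db, path) {
  stopifnot(inherits(db, "reference_database"))
  jsonlite::write_json(list(p_star = db$p_star, cells = db$cells),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_reference_database
#' @export
read_reference_database <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- as.data.frame(x$cells)
  cells$age_bin <- factor(cells$age_bin,
                          levels = levels(rc_age_bin(20)))
  structure(list(cells = cells, p_star = x$p_star),
            class = "reference_database")
}

#' Z-score a scan metric against the normative database
#'
#' Relates one observed metric value to its demographic-matched reference
#' cell: `z = (value - cell mean) / cell SD`.
#'
#' @param db A [build_reference_database()] result.
#' @param value Observed metric value (at the database's coverage).
#' @param sex `"male"` or `"female"`.
#' @param age_years Age in years (must fall in a reference bin).
#' @param muscle,metric Which cell to score against.
#' @return The z-score (numeric scalar; vectorized over `value`).
#' @export
z_score <- function(db, value, sex, age_years, muscle, metric) {
  stopifnot(inherits(db, "reference_database"))
  bin <- rc_age_bin(age_years)
  if (is.na(bin))
    stop("age ", age_years, " outside the reference range [15, 89]",
         call. = FALSE)
  cells <- db$cells
  row <- cells[cells$sex == sex & cells$age_bin == bin &
               cells$muscle == muscle & cells$metric == metric, ]
  if (nrow(row) != 1L)
    stop("no reference cell for (", sex, ", ", bin, ", ", muscle, ", ",
         metric, ")", call. = FALSE)
  if (!row$usable || is.na(row$sd) || row$sd <= 0)
    stop("reference cell unusable (n = ", row$n, ", sd = ",
         format(row$sd), ")", call. = FALSE)
  (value - row$mean) / row$sd
}
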