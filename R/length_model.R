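#' Fit the scapula-length regression from lateral morphometrics
#'
#' Ordinary least squares regression of total scapula length on the four
#' lateral morphometric measures PD, PC, VB and HB (see
#' [measure_lateral_morphometrics()]). All four predictors are retained in
#' the deployed model regardless of individual significance; a reduced
#' PD + PC model is available via `predictors` for sensitivity analysis.
#'
#' @param data Data frame with columns `PD_mm`, `PC_mm2`, `VB_mm`, `HB_mm`
#'   and the response `length_mm` (total scapula length, mm).
#' @param predictors Character vector of predictor columns (default the
#'   four morphometrics).
#' @param response Name of the response column (default `"length_mm"`).
#' @return An object of class `scapula_length_model`: coefficients (with
#'   intercept), per-coefficient t and p values, overall correlation `r`
#'   between fitted and observed lengths, residual SD, training `n`, and
#'   Shapiro-Wilk normality p-values for each variable.
#' @details Requires `n >= length(predictors) + 2` and a full-rank design.
#' @examples
#' d <- data.frame(PD_mm = c(20, 25, 30, 35, 40, 45, 50),
#'                 PC_mm2 = c(500, 620, 540, 700, 660, 720, 800),
#'                 VB_mm = 30, HB_mm = 60)
#' d$length_mm <- 40 + 3 * d$PD_mm + 0.05 * d$PC_mm2
#' m <- fit_length_model(d)
#' coef(m)
#' @export
fit_length_model <- function(data,
                             predictors = c("PD_mm", "PC_mm2", "VB_mm", "HB_mm"),
                             response = "length_mm") {
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(predictors, response), names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n <- nrow(data)
  if (n < length(predictors) + 2L)
    stop("need at least ", length(predictors) + 2L,
         " training samples, got ", n, call. = FALSE)
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit)))
    stop("singular design matrix: predictors are collinear", call. = FALSE)
  sm <- summary(fit)
  shapiro_p <- vapply(c(predictors, response), function(v) {
    x <- data[[v]]
    if (stats::sd(x) == 0 || n < 3L) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  structure(list(
    coefficients = stats::coef(fit),
    predictors = predictors,
    response = response,
    n = n,
    r = sqrt(max(0, sm$r.squared)),
    sigma = sm$sigma,
    coef_table = sm$coefficients,
    shapiro_p = shapiro_p,
    fit = fit
  ), class = "scapula_length_model")
}

#' @export
coef.scapula_length_model <- function(object, ...) object$coefficients

#' @export
print.scapula_length_model <- function(x, ...) {
  cat(sprintf("Scapula-length model (OLS, n = %d, r = %.3f)\n", x$n, x$r))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.scapula_length_model <- function(object, ...) {
  cat(sprintf("Scapula-length model: %s ~ %s\n", object$response,
              paste(object$predictors, collapse = " + ")))
  cat(sprintf("n = %d, multiple r = %.3f, residual SD = %.2f mm\n",
              object$n, object$r, object$sigma))
  cat("\nCoefficients:\n")
  stats::printCoefmat(object$coef_table)
  cat("\nShapiro-Wilk normality p-values:\n")
  print(round(object$shapiro_p, 4))
  invisible(object)
}

#' Predict total scapula length
#'
#' Applies the fitted length regression to new morphometrics. A physical
#' constraint is enforced: predicted length cannot be shorter than the
#' captured scapular extent (coverage cannot exceed 100%), so predictions
#' below the extent are clamped up to it and flagged via the `"clamped"`
#' attribute.
#'
#' @param object A [fit_length_model()] result (or one read back with
#'   [read_length_model()]).
#' @param newdata A `lateral_morphometrics` object or data frame with the
#'   model's predictor columns; a `captured_extent_mm` column/field enables
#'   clamping.
#' @param ... Unused.
#' @return Numeric vector of predicted lengths (mm) with logical attribute
#'   `"clamped"` marking predictions raised to the captured extent.
#' @export
predict.scapula_length_model <- function(object, newdata, ...) {
  if (inherits(newdata, "lateral_morphometrics"))
    newdata <- as.data.frame(newdata)
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols))
    stop("newdata lacks predictors: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  X <- cbind(1, as.matrix(newdata[object$predictors]))
  pred <- drop(X %*% object$coefficients)
  clamped <- rep(FALSE, length(pred))
  if ("captured_extent_mm" %in% names(newdata)) {
    ext <- newdata$captured_extent_mm
    clamped <- !is.na(ext) & pred < ext
    pred[clamped] <- ext[clamped]
  }
  attr(pred, "clamped") <- clamped
  pred
}

#' Evaluate a length model on held-out scans
#'
#' Computes per-scan signed percent errors `(predicted - true)/true * 100`,
#' their mean absolute value (MAPE), the SD of the absolute errors, and the
#' signed error range.
#'
#' @param model A `scapula_length_model`.
#' @param test Data frame with the model's predictors and a true
#'   `length_mm` column (> 0).
#' @return An object of class `length_evaluation`: list with `mape_pct`,
#'   `sd_abs_pct`, `range_pct` (signed min/max) and `errors_pct`.
#' @export
evaluate_length_model <- function(model, test) {
  test <- as.data.frame(test)
  if (!nrow(test)) stop("empty test set", call. = FALSE)
  truth <- test[[model$response]]
  if (is.null(truth)) stop("test set lacks ", model$response, call. = FALSE)
  if (any(truth <= 0)) stop("true lengths must be positive", call. = FALSE)
  pred <- as.numeric(predict(model, test))
  err <- (pred - truth) / truth * 100
  structure(list(
    mape_pct = mean(abs(err)),
    sd_abs_pct = stats::sd(abs(err)),
    range_pct = range(err),
    errors_pct = err,
    n = length(err)
  ), class = "length_evaluation")
}

#' @export
print.length_evaluation <- function(x, ...) {
  cat(sprintf("Length-model evaluation (n = %d)\n", x$n))
  cat(sprintf("  mean absolute error: %.2f%% (SD %.2f%%)\n",
              x$mape_pct, x$sd_abs_pct))
  cat(sprintf("  signed error range: %.2f%% to %.2f%%\n",
              x$range_pct[1], x$range_pct[2]))
  invisible(x)
}

#' Serialize a length model to JSON (and back)
#'
#' Models are stored as plain JSON with units recorded, so a reference
#' model can ship with an analysis and be applied without refitting.
#'
#' @param model A `scapula_length_model`.
#' @param path JSON file path.
#' @return `write_length_model()` returns `path` invisibly;
#'   `read_length_model()` returns a `scapula_length_model` (without the
#'   internal `lm` fit; prediction and evaluation work as usual).
#' @export
write_length_model <- function(model, path) {
  stopifnot(inherits(model, "scapula_length_model"))
  units <- c("(Intercept)" = "mm", PD_mm = "mm/mm", PC_mm2 = "mm/mm2",
             VB_mm = "mm/mm", HB_mm = "mm/mm")
  jsonlite::write_json(list(
    model = "scapula_length_ols",
    response = model$response,
    predictors = model$predictors,
    coefficients = as.list(model$coefficients),
    coefficient_units = as.list(units[names(model$coefficients)]),
    n = model$n, r = model$r, sigma_mm = model$sigma
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_length_model
#' @export
read_length_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    coefficients = unlist(x$coefficients),
    predictors = x$predictors,
    response = x$response,
    n = x$n, r = x$r, sigma = x$sigma_mm,
    coef_table = NULL, shapiro_p = NULL, fit = NULL
  ), class = "scapula_length_model")
}
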