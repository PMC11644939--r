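# Baseline weight models (linear support-vector regression, density
# look-up), k-fold cross-validation with RMSE / MAPE / signed-error
# reporting, and per-configuration volume statistics.

#' Fit a linear epsilon-insensitive support-vector regression
#'
#' Baseline for foods whose volume-weight relation is essentially linear
#' (e.g. rice): `weight = a * volume + b`, fitted by the standard
#' epsilon-SVR convex program (via \pkg{e1071}) on internally standardised
#' volumes. Deterministic given its inputs.
#'
#' @param data A [volume_weight_set()] or data frame with `volume_mm3`,
#'   `weight_g`.
#' @param epsilon Insensitivity tube half-width in grams (default 0.1).
#' @param C Box constraint (default 1000; large values approach ordinary
#'   L1-insensitive least absolute deviation on the tube boundary).
#' @return An object of class `portionr_svr` with slope/intercept in natural
#'   units (g per mm^3, g).
#' @export
fit_linear_svr <- function(data, epsilon = 0.1, C = 1000) {
  x_raw <- data$volume_mm3; y <- data$weight_g
  if (length(x_raw) < 2L) stop("need at least 2 records")
  x_sd <- stats::sd(x_raw)
  if (x_sd == 0)
    stop("all volumes are identical; a linear volume-weight fit is degenerate")
  x_mean <- mean(x_raw)
  x <- (x_raw - x_mean) / x_sd
  fit <- e1071::svm(x = matrix(x, ncol = 1L), y = y,
                    type = "eps-regression", kernel = "linear",
                    cost = C, epsilon = epsilon, scale = FALSE)
  w_std <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  slope <- w_std / x_sd
  intercept <- b - w_std * x_mean / x_sd
  structure(list(slope_g_per_mm3 = slope, intercept_g = intercept,
                 epsilon = epsilon, C = C, svm = fit,
                 x_mean = x_mean, x_sd = x_sd),
            class = "portionr_svr")
}

#' @export
predict.portionr_svr <- function(object, newdata, ...) {
  v <- if (is.data.frame(newdata)) newdata$volume_mm3 else newdata
  object$slope_g_per_mm3 * as.numeric(v) + object$intercept_g
}

#' @export
print.portionr_svr <- function(x, ...) {
  cat(sprintf(
    "<portionr_svr> weight = %.6g * volume + %.4g g (eps = %g, C = %g)\n",
    x$slope_g_per_mm3, x$intercept_g, x$epsilon, x$C))
  invisible(x)
}

#' Density look-up table
#'
#' @param class_label Character vector of class names.
#' @param density_g_per_mm3 Mean densities, > 0.
#' @return A named numeric vector of class `density_table`.
#' @export
density_table <- function(class_label, density_g_per_mm3) {
  if (any(density_g_per_mm3 <= 0)) stop("densities must be > 0")
  structure(stats::setNames(as.numeric(density_g_per_mm3),
                            as.character(class_label)),
            class = "density_table")
}

#' Weight from volume via a density look-up
#'
#' `weight = density(class) * volume`; the simplest volume-to-weight model,
#' used when no per-class training table exists.
#'
#' @param volume Volume(s) in mm^3.
#' @param class_label Food class to look up.
#' @param table A [density_table()].
#' @return Weight(s) in grams.
#' @export
density_weight <- function(volume, class_label, table) {
  if (!class_label %in% names(table))
    stop(sprintf("unknown class '%s'; known classes: %s", class_label,
                 paste(names(table), collapse = ", ")))
  unname(table[[class_label]]) * as.numeric(volume)
}

#' Constant-mean baseline model
#'
#' Predicts every weight as the training mean; the natural null model for
#' judging whether a volume-based model adds information.
#'
#' @param data A [volume_weight_set()].
#' @return An object of class `portionr_meanmodel`.
#' @export
fit_mean_model <- function(data) {
  structure(list(mean_g = mean(data$weight_g)), class = "portionr_meanmodel")
}

#' @export
predict.portionr_meanmodel <- function(object, newdata, ...) {
  n <- if (is.data.frame(newdata)) nrow(newdata) else length(newdata)
  rep(object$mean_g, n)
}

fit_model_spec <- function(spec, data) {
  switch(spec$type,
         mean = fit_mean_model(data),
         gpr = fit_gpr(data,
                       form = if (is.null(spec$form)) "halfsq" else spec$form,
                       n_starts = if (is.null(spec$n_starts)) 6 else spec$n_starts,
                       maxit = if (is.null(spec$maxit)) 60 else spec$maxit),
         svr = fit_linear_svr(data,
                              epsilon = if (is.null(spec$epsilon)) 0.1 else spec$epsilon,
                              C = if (is.null(spec$C)) 1000 else spec$C),
         stop(sprintf("unknown model type '%s'", spec$type)))
}

#' k-fold cross-validation of a volume-weight model
#'
#' Shuffles the records into `k` folds (sizes differing by at most one)
#' under the given seed, fits the model on each k-1 fold complement and
#' predicts the held-out fold. Reports per-fold and pooled RMSE
#' (`sqrt(sum(e^2)/n)`), MAPE (`100/n * sum(|e_i| / w_i)`, the percentage
#' error statistic), and retains the signed errors (predicted - observed, g)
#' for error-distribution analysis.
#'
#' @param data A [volume_weight_set()].
#' @param model_spec A list such as `list(type = "gpr")`,
#'   `list(type = "svr", epsilon = 1)`; extra entries are passed to the
#'   fitting routine.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @return An object of class `cv_report` with `fold` assignment,
#'   `signed_errors_g`, `per_fold_rmse_g`, `rmse_g`, `mape_pct`.
#' @export
kfold_cv <- function(data, model_spec, k = 5, seed = 1) {
  n <- nrow(data)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop(sprintf("n = %d records but k = %d folds", n, k))
  set.seed(seed)
  shuffle <- sample.int(n)
  fold <- integer(n)
  fold[shuffle] <- rep_len(seq_len(k), n)
  errs <- numeric(n)
  preds <- numeric(n)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    test <- fold == f
    m <- fit_model_spec(model_spec, data[!test, , drop = FALSE])
    p <- predict(m, data[test, , drop = FALSE])
    e <- p - data$weight_g[test]
    preds[test] <- p
    errs[test] <- e
    per_fold[f] <- sqrt(mean(e^2))
  }
  structure(list(
    fold = fold,
    predicted_g = preds,
    signed_errors_g = errs,
    per_fold_rmse_g = per_fold,
    rmse_g = sqrt(mean(errs^2)),
    mape_pct = 100 * mean(abs(errs) / data$weight_g),
    k = k, seed = seed, model_spec = model_spec
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold (seed %s): RMSE %.3f g, MAPE %.2f%%\n",
              x$k, format(x$seed), x$rmse_g, x$mape_pct))
  invisible(x)
}

#' Per-configuration volume statistics
#'
#' For repeated measurements of the same item under different plate
#' configurations (e.g. progressively reduced accompaniment), reports each
#' configuration's mean volume and sample standard deviation (n-1
#' denominator). Values are reported in mm^3 and conventionally rounded to
#' the nearest integer when printed; groups with fewer than 2 records get a
#' missing standard deviation.
#'
#' @param volume_mm3 Numeric vector of volumes.
#' @param config_id Grouping vector (configuration labels).
#' @return A `data.frame` of class `config_stats` with `config_id`, `n`,
#'   `mean_mm3`, `std_mm3`, ordered by first appearance of each group.
#' @export
config_stats <- function(volume_mm3, config_id) {
  stopifnot(length(volume_mm3) == length(config_id))
  ids <- unique(config_id)
  out <- do.call(rbind, lapply(ids, function(g) {
    v <- volume_mm3[config_id == g]
    data.frame(config_id = g, n = length(v), mean_mm3 = mean(v),
               std_mm3 = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("config_stats", "data.frame")
  out
}

#' @export
print.config_stats <- function(x, ...) {
  y <- as.data.frame(x)
  y$mean_mm3 <- round(y$mean_mm3)
  y$std_mm3 <- round(y$std_mm3)
  print(y)
  invisible(x)
}

#' Read / write volume-weight training tables
#'
#' CSV with columns `class`, `config_id`, `volume_mm3`, `weight_g`
#' (extra columns preserved on read where present).
#'
#' @param path CSV file path.
#' @return A [volume_weight_set()] (read) or `path` (write).
#' @export
read_volume_weight_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("volume_mm3", "weight_g")
  if (!all(need %in% names(df)))
    stop(sprintf("training table must have columns %s",
                 paste(need, collapse = ", ")))
  volume_weight_set(df$volume_mm3, df$weight_g,
                    class_label = if ("class" %in% names(df)) df$class
                    else NA_character_,
                    config_id = if ("config_id" %in% names(df)) df$config_id
                    else NA_character_)
}

#' @rdname read_volume_weight_csv
#' @param data A [volume_weight_set()].
#' @export
write_volume_weight_csv <- function(data, path) {
  utils::write.csv(
    data.frame(class = data$class_label, config_id = data$config_id,
               volume_mm3 = data$volume_mm3, weight_g = data$weight_g),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a density table from CSV
#'
#' CSV with columns `class`, `density_g_per_mm3`.
#'
#' @param path CSV file path.
#' @return A [density_table()].
#' @export
read_density_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class", "density_g_per_mm3") %in% names(df)))
    stop("density table must have columns class, density_g_per_mm3")
  density_table(df$class, df$density_g_per_mm3)
}
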