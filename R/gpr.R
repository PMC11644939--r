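# Exponential-kernel Gaussian process regression mapping food volume (mm^3)
# to weight (g). Inputs are z-standardized and targets centred before kernel
# evaluation: raw volumes are O(1e5) mm^3 and would otherwise degenerate the
# length-scale optimisation. Hyperparameters maximise the exact log marginal
# likelihood via multi-start local optimisation under a fixed seed.

#' Exponential kernel parameters
#'
#' @param sigma_f2 Signal variance (g^2), > 0.
#' @param length_scale_l Length scale in the same units as the kernel input
#'   distance, > 0.
#' @param noise_var Observation noise variance (g^2), > 0.
#' @return An object of class `exp_gpr_params`.
#' @export
exp_gpr_params <- function(sigma_f2, length_scale_l, noise_var) {
  if (any(c(sigma_f2, length_scale_l, noise_var) <= 0))
    stop("sigma_f2, length_scale_l and noise_var must all be > 0")
  structure(list(sigma_f2 = sigma_f2, length_scale_l = length_scale_l,
                 noise_var = noise_var),
            class = "exp_gpr_params")
}

#' Exponential covariance kernel
#'
#' Two parameterisations of the exponential (Ornstein-Uhlenbeck-type)
#' covariance are supported. The default `"halfsq"` form is
#' `k(x, x') = sigma_f2 * exp(-|x - x'| / (2 l^2))`; the textbook
#' Ornstein-Uhlenbeck form `"ou"` is
#' `k(x, x') = sigma_f2 * exp(-|x - x'| / l)`. Both are symmetric with
#' `k(x, x) = sigma_f2` and differ only in how the decay rate is
#' parameterised.
#'
#' @param x,x_prime Numeric vectors of kernel inputs; a full cross-covariance
#'   matrix `length(x)` x `length(x_prime)` is returned.
#' @param p An [exp_gpr_params()].
#' @param form `"halfsq"` (default) or `"ou"`.
#' @return Covariance matrix in g^2.
#' @export
kernel_exponential <- function(x, x_prime, p, form = c("halfsq", "ou")) {
  stopifnot(inherits(p, "exp_gpr_params"))
  form <- match.arg(form)
  d <- abs(outer(as.numeric(x), as.numeric(x_prime), "-"))
  rate <- if (form == "halfsq") 2 * p$length_scale_l^2 else p$length_scale_l
  p$sigma_f2 * exp(-d / rate)
}

#' Volume-weight training set
#'
#' Validates a table of paired volume (mm^3) and weight (g) measurements,
#' e.g. scale-weighed portions matched to their measured volumes.
#'
#' @param volume_mm3 Numeric vector of volumes, > 0.
#' @param weight_g Numeric vector of weights, > 0, same length.
#' @param class_label Optional class per record.
#' @param config_id Optional experimental-configuration id per record.
#' @return A `data.frame` of class `volume_weight_set`.
#' @export
volume_weight_set <- function(volume_mm3, weight_g, class_label = NA_character_,
                              config_id = NA_character_) {
  if (length(volume_mm3) != length(weight_g))
    stop("volume and weight vectors must have equal length")
  if (any(volume_mm3 <= 0) || any(weight_g <= 0))
    stop("volumes and weights must be > 0")
  df <- data.frame(volume_mm3 = volume_mm3, weight_g = weight_g,
                   class_label = class_label, config_id = config_id,
                   stringsAsFactors = FALSE)
  class(df) <- c("volume_weight_set", "data.frame")
  df
}

# negative log marginal likelihood over log-parameters theta =
# (log sigma_f2, log l, log noise_var), with Cholesky jitter escalation
gpr_nll <- function(theta, x, y, form) {
  p <- exp_gpr_params(exp(theta[1L]), exp(theta[2L]), exp(theta[3L]))
  K <- kernel_exponential(x, x, p, form)
  n <- length(x)
  Kn <- K + diag(p$noise_var, n)
  L <- tryCatch(chol(Kn), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  a <- backsolve(L, forwardsolve(t(L), y))
  0.5 * sum(y * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
}

chol_with_jitter <- function(Kn, sigma_f2) {
  for (j in c(0, sigma_f2 * 10^seq(-10, -6, by = 2))) {
    L <- tryCatch(chol(Kn + diag(j, nrow(Kn))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop(sprintf(
    "kernel matrix not positive definite after jitter escalation (rcond ~ %.2e)",
    rcond(Kn)))
}

#' Fit an exponential-kernel GPR of weight on volume
#'
#' Standardises volumes to z-scores and centres weights, then either keeps
#' the supplied hyperparameters (`optimize = FALSE`) or maximises the exact
#' log marginal likelihood over `(sigma_f2, l, noise_var)` by L-BFGS-B in
#' log-parameter space from `n_starts` deterministic starting points
#' (length scales and noise levels spread over plausible decades around the
#' data scale). The Cholesky factor of `K + noise_var I` is cached for
#' prediction.
#'
#' @param data A [volume_weight_set()] (or data frame with `volume_mm3`,
#'   `weight_g`), n >= 2.
#' @param init Optional [exp_gpr_params()] in standardized-input units used
#'   as an extra start (and as the result when `optimize = FALSE`).
#' @param optimize Maximise the log marginal likelihood (default `TRUE`).
#' @param form Kernel form, see [kernel_exponential()].
#' @param n_starts Number of multi-start points (default 6).
#' @param maxit L-BFGS-B iteration cap per start (default 60).
#' @return An object of class `portionr_gpr` carrying the hyperparameters in
#'   standardized units (`params`) and natural units (`params_natural`:
#'   length scale in mm^3), the standardisation constants and the cached
#'   Cholesky factor.
#' @export
fit_gpr <- function(data, init = NULL, optimize = TRUE,
                    form = c("halfsq", "ou"), n_starts = 6, maxit = 60) {
  form <- match.arg(form)
  x_raw <- data$volume_mm3; y_raw <- data$weight_g
  n <- length(x_raw)
  if (n < 2L) stop("need at least 2 records to fit a GPR")
  x_mean <- mean(x_raw); x_sd <- stats::sd(x_raw)
  if (x_sd == 0) x_sd <- 1  # duplicate-input degenerate case
  y_mean <- mean(y_raw)
  x <- (x_raw - x_mean) / x_sd
  y <- y_raw - y_mean
  vy <- stats::var(y)
  if (vy == 0) vy <- 1
  if (is.null(init)) init <- exp_gpr_params(vy, 1, 0.1 * vy)

  if (optimize) {
    starts <- list(log(c(init$sigma_f2, init$length_scale_l, init$noise_var)))
    ls_grid <- c(0.2, 0.5, 1, 2, 4, 8)
    nv_grid <- c(0.05, 0.2, 0.05, 0.2, 0.05, 0.2)
    for (i in seq_len(max(0L, n_starts - 1L))) {
      j <- ((i - 1L) %% length(ls_grid)) + 1L
      starts[[length(starts) + 1L]] <-
        log(c(vy, ls_grid[j], nv_grid[j] * vy))
    }
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        stats::optim(s, gpr_nll, x = x, y = y, form = form,
                     method = "L-BFGS-B",
                     lower = log(c(vy * 1e-4, 1e-3, vy * 1e-6)),
                     upper = log(c(vy * 1e4, 1e3, vy * 1e2)),
                     control = list(maxit = maxit)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best)) stop("log-marginal-likelihood optimisation failed")
    params <- exp_gpr_params(exp(best$par[1L]), exp(best$par[2L]),
                             exp(best$par[3L]))
    lml <- -best$value
  } else {
    params <- init
    lml <- -gpr_nll(log(c(params$sigma_f2, params$length_scale_l,
                          params$noise_var)), x, y, form)
  }

  K <- kernel_exponential(x, x, params, form)
  L <- chol_with_jitter(K + diag(params$noise_var, n), params$sigma_f2)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  structure(list(
    params = params,
    params_natural = list(sigma_f2 = params$sigma_f2,
                          length_scale_mm3 = params$length_scale_l * x_sd,
                          noise_var = params$noise_var),
    form = form,
    x_train = x, y_train = y,
    x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
    L = L, alpha = alpha,
    log_marginal_likelihood = lml
  ), class = "portionr_gpr")
}

#' Predict weights from volumes with a fitted GPR
#'
#' Standard GP posterior under the exponential kernel, de-standardised back
#' to grams. The returned variance is predictive for a new observation
#' (posterior variance of the latent function plus the noise variance).
#'
#' @param model A fitted `portionr_gpr` from [fit_gpr()].
#' @param volumes Numeric vector of volumes in mm^3.
#' @return A `data.frame` with columns `volume_mm3`, `mean_g`, `variance_g2`.
#' @export
predict_gpr <- function(model, volumes) {
  if (!inherits(model, "portionr_gpr") || is.null(model$L))
    stop("model is not a fitted GPR")
  xs <- (as.numeric(volumes) - model$x_mean) / model$x_sd
  Ks <- kernel_exponential(model$x_train, xs, model$params, model$form)
  mean_g <- model$y_mean + drop(crossprod(Ks, model$alpha))
  v <- forwardsolve(t(model$L), Ks)
  var_latent <- pmax(model$params$sigma_f2 - colSums(v^2), 0)
  data.frame(volume_mm3 = as.numeric(volumes), mean_g = mean_g,
             variance_g2 = var_latent + model$params$noise_var)
}

#' @export
predict.portionr_gpr <- function(object, newdata, ...) {
  v <- if (is.data.frame(newdata)) newdata$volume_mm3 else newdata
  predict_gpr(object, v)$mean_g
}

#' @export
print.portionr_gpr <- function(x, ...) {
  cat(sprintf(
    "<portionr_gpr> %s kernel; sigma_f2 = %.3g g^2, l = %.3g (std) / %.3g mm^3, noise = %.3g g^2, lml = %.2f\n",
    x$form, x$params$sigma_f2, x$params$length_scale_l,
    x$params_natural$length_scale_mm3, x$params$noise_var,
    x$log_marginal_likelihood))
  invisible(x)
}

#' Save / load a fitted GPR as JSON
#'
#' Persists hyperparameters, standardisation constants and training pairs;
#' the Cholesky factor is rebuilt on load.
#'
#' @param model A fitted `portionr_gpr`.
#' @param path JSON file path.
#' @return `path` (write) or the restored model (read).
#' @export
write_gpr_json <- function(model, path) {
  stopifnot(inherits(model, "portionr_gpr"))
  obj <- list(kernel_form = model$form,
              params = unclass(model$params),
              x_mean = model$x_mean, x_sd = model$x_sd, y_mean = model$y_mean,
              x_train = model$x_train, y_train = model$y_train)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gpr_json
#' @export
read_gpr_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- exp_gpr_params(obj$params$sigma_f2, obj$params$length_scale_l,
                           obj$params$noise_var)
  x <- obj$x_train; y <- obj$y_train
  K <- kernel_exponential(x, x, params, obj$kernel_form)
  L <- chol_with_jitter(K + diag(params$noise_var, length(x)),
                        params$sigma_f2)
  structure(list(
    params = params,
    params_natural = list(sigma_f2 = params$sigma_f2,
                          length_scale_mm3 = params$length_scale_l * obj$x_sd,
                          noise_var = params$noise_var),
    form = obj$kernel_form,
    x_train = x, y_train = y,
    x_mean = obj$x_mean, x_sd = obj$x_sd, y_mean = obj$y_mean,
    L = L, alpha = backsolve(L, forwardsolve(t(L), y)),
    log_marginal_likelihood = NA_real_
  ), class = "portionr_gpr")
}
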