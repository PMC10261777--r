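# Least-squares estimation of the three rehydration models from a soaking
# curve, with the goodness-of-fit statistics used to rank them.

#' A rehydration soaking curve
#'
#' One condition's moisture-versus-time series: dry-basis moisture content
#' sampled while dried kernels soak in boiling water.
#'
#' @param times Soaking times, minutes, strictly increasing.
#' @param moistures Dry-basis moisture contents, g water / g dry matter,
#'   non-negative, same length as `times` (at least 4 points).
#' @param pretreatment Blanching pretreatment label, one of `"control"`,
#'   `"HB"` (hot water), `"SB"` (steam), `"MB"` (microwave).
#' @param temperature Drying air temperature, degrees C (55, 60, 65 or 70
#'   in the study design; any value is accepted).
#' @param Xw0 Initial dry-basis moisture, g/g. Defaults to the moisture at
#'   `t = 0` when the grid starts at zero; otherwise it must be supplied.
#' @return An object of class `rehydration_curve`.
#' @export
rehydration_curve <- function(times, moistures,
                              pretreatment = "control", temperature = NA_real_,
                              Xw0 = NULL) {
  stopifnot(is.numeric(times), is.numeric(moistures))
  if (length(times) != length(moistures))
    stop("times and moistures must have the same length", call. = FALSE)
  if (length(times) < 4)
    stop("a rehydration curve needs at least 4 time points", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(moistures)) || any(moistures < 0))
    stop("moistures must be finite and >= 0", call. = FALSE)
  if (is.null(Xw0)) {
    if (times[1] != 0)
      stop("supply Xw0 when the time grid does not start at t = 0", call. = FALSE)
    Xw0 <- moistures[1]
  }
  stopifnot(is.numeric(Xw0), length(Xw0) == 1, Xw0 >= 0)
  structure(list(times = as.numeric(times), moistures = as.numeric(moistures),
                 Xw0 = as.numeric(Xw0),
                 pretreatment = as.character(pretreatment),
                 temperature = as.numeric(temperature)),
            class = "rehydration_curve")
}

#' @export
print.rehydration_curve <- function(x, ...) {
  cat(sprintf("<rehydration_curve> %s @ %s degC: %d points, t = %g..%g min, Xw0 = %.3f g/g\n",
              x$pretreatment, format(x$temperature), length(x$times),
              min(x$times), max(x$times), x$Xw0))
  invisible(x)
}

condition_label <- function(curve) {
  sprintf("%s_%s", curve$pretreatment, format(curve$temperature))
}

#' Goodness-of-fit statistics for a rehydration model
#'
#' Computes the coefficient of determination, the root mean square error
#' `RMSE = sqrt(SSE / N)` and the reduced chi-square
#' `chi2 = SSE / (N - Z)`, where `SSE` is the residual sum of squares and
#' `Z` the number of fitted parameters. `R2 = 1 - SSE / SStot` about the
#' observed mean.
#'
#' @param observed,predicted Equal-length numeric vectors of moisture
#'   contents (or moisture ratios), length `N > Z`.
#' @param Z Number of fitted model parameters.
#' @return A `fit_stats` list with fields `R2`, `RMSE`, `chi2`, `N`, `Z`.
#' @export
#' @examples
#' goodness_of_fit(c(0.1, -0.1, 0.2), c(0, 0, 0), Z = 1)
goodness_of_fit <- function(observed, predicted, Z) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  N <- length(observed)
  if (length(predicted) != N)
    stop("observed and predicted must have the same length", call. = FALSE)
  if (N <= Z)
    stop(sprintf("degrees of freedom exhausted: N = %d points for Z = %d parameters",
                 N, Z), call. = FALSE)
  sse <- sum((observed - predicted)^2)
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0)
    stop("observed values have zero variance: R2 is undefined", call. = FALSE)
  structure(list(R2 = 1 - sse / sstot,
                 RMSE = sqrt(sse / N),
                 chi2 = sse / (N - Z),
                 N = N, Z = Z),
            class = "fit_stats")
}

# Residuals can be assessed on moisture content directly (default) or on the
# moisture ratio (X - Xeq)/(Xw0 - Xeq); the choice only rescales them.
to_residual_scale <- function(x, curve, Xeq, residual_on) {
  if (residual_on == "moisture") return(x)
  denom <- curve$Xw0 - Xeq
  if (!is.finite(denom) || denom == 0)
    stop("moisture-ratio residuals undefined: Xeq equals Xw0", call. = FALSE)
  (x - Xeq) / denom
}

new_model_fit <- function(model, params, Xeq_derived, curve, predicted,
                          observed, Z, converged, residual_on) {
  stats <- NULL
  if (converged) {
    obs <- to_residual_scale(observed, curve, Xeq_derived, residual_on)
    pred <- to_residual_scale(predicted, curve, Xeq_derived, residual_on)
    stats <- goodness_of_fit(obs, pred, Z)
    if (!all(is.finite(unlist(stats)))) converged <- FALSE
  }
  structure(list(model = model, params = params, Xeq_derived = Xeq_derived,
                 stats = if (converged) stats else NULL,
                 converged = converged,
                 condition = condition_label(curve),
                 residual_on = residual_on),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s model, condition %s\n", x$model, x$condition))
  cat("  parameters:", paste(sprintf("%s = %.5g", names(unclass(x$params)),
                                     unlist(x$params)), collapse = ", "), "\n")
  if (x$converged)
    cat(sprintf("  Xeq = %.4f g/g | R2 = %.4f, RMSE = %.4f, chi2 = %.5f (N = %d, Z = %d)\n",
                x$Xeq_derived, x$stats$R2, x$stats$RMSE, x$stats$chi2,
                x$stats$N, x$stats$Z))
  else cat("  fit did not converge; statistics withheld\n")
  invisible(x)
}

#' @export
coef.model_fit <- function(object, ...) unlist(unclass(object$params))

stop_degenerate <- function(curve) {
  stop(sprintf("degenerate curve (%s): moisture never rises above Xw0 = %g",
               condition_label(curve), curve$Xw0), call. = FALSE)
}

fit_nls <- function(formula, data, start, lower, upper) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxfev = 1000)
  tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower, upper = upper, control = ctrl),
    error = function(e) NULL)
}

#' Fit the Peleg model to a soaking curve
#'
#' Starting values come from the Peleg linearization
#' `t / (X - Xw0) = k1 + k2 t`, fitted by ordinary least squares over the
#' points with `X > Xw0`, and are refined by Levenberg-Marquardt nonlinear
#' least squares on the moisture residuals. `Xw0` is fixed at the measured
#' `t = 0` moisture, so `Z = 2`. The derived equilibrium moisture is
#' `Xw0 + 1/k2`.
#'
#' @param curve A [rehydration_curve()].
#' @param residual_on Residual variable for the fit statistics:
#'   `"moisture"` (dry-basis moisture content, default) or
#'   `"moisture_ratio"`.
#' @return A `model_fit` object.
#' @export
fit_peleg <- function(curve, residual_on = c("moisture", "moisture_ratio")) {
  stopifnot(inherits(curve, "rehydration_curve"))
  residual_on <- match.arg(residual_on)
  t <- curve$times; X <- curve$moistures; Xw0 <- curve$Xw0
  up <- t > 0 & X > Xw0
  if (!any(up)) stop_degenerate(curve)
  # linearized start: t/(X - Xw0) = k1 + k2 t
  y <- t[up] / (X[up] - Xw0)
  init <- coef(lm(y ~ t[up]))
  k1_0 <- max(init[[1]], 1e-3); k2_0 <- max(init[[2]], 1e-4)
  fit <- fit_nls(X ~ Xw0 + t / (k1 + k2 * t),
                 data = list(t = t, X = X, Xw0 = Xw0),
                 start = list(k1 = k1_0, k2 = k2_0),
                 lower = c(1e-8, 1e-8), upper = c(Inf, Inf))
  if (is.null(fit)) {
    params <- peleg_params(k1_0, k2_0)
    return(new_model_fit("peleg", params, peleg_equilibrium(Xw0, k2_0), curve,
                         predicted = NA_real_, observed = X, Z = 2,
                         converged = FALSE, residual_on = residual_on))
  }
  cf <- coef(fit)
  params <- peleg_params(cf[["k1"]], cf[["k2"]])
  new_model_fit("peleg", params, peleg_equilibrium(Xw0, params$k2), curve,
                predicted = peleg_moisture(t, Xw0, params), observed = X,
                Z = 2, converged = TRUE, residual_on = residual_on)
}

#' Fit the Weibull model to a soaking curve
#'
#' Fits `(alpha, beta, Xeq)` with `Xw0` fixed at the measured value
#' (`Z = 3`). Initialization: `alpha = 1`, `Xeq` at 1.05 times the maximum
#' observed moisture, and `beta` at the sampled time closest to the 63%
#' level of the initial total change. Box constraints keep
#' `alpha` in (0, 5], `beta > 0` and `Xeq` at or above half the maximum
#' observed moisture.
#'
#' @inheritParams fit_peleg
#' @return A `model_fit` object.
#' @export
fit_weibull <- function(curve, residual_on = c("moisture", "moisture_ratio")) {
  stopifnot(inherits(curve, "rehydration_curve"))
  residual_on <- match.arg(residual_on)
  t <- curve$times; X <- curve$moistures; Xw0 <- curve$Xw0
  if (max(X) <= Xw0) stop_degenerate(curve)
  Xeq0 <- max(X) * 1.05
  target <- Xw0 + (1 - exp(-1)) * (Xeq0 - Xw0)
  beta0 <- max(t[which.min(abs(X - target))], min(t[t > 0]))
  fit <- fit_nls(X ~ Xeq + (Xw0 - Xeq) * exp(-(t / beta)^alpha),
                 data = list(t = t, X = X, Xw0 = Xw0),
                 start = list(alpha = 1, beta = beta0, Xeq = Xeq0),
                 lower = c(1e-6, 1e-6, 0.5 * max(X)),
                 upper = c(5, Inf, Inf))
  if (is.null(fit)) {
    params <- weibull_params(1, beta0, Xeq0)
    return(new_model_fit("weibull", params, Xeq0, curve,
                         predicted = NA_real_, observed = X, Z = 3,
                         converged = FALSE, residual_on = residual_on))
  }
  cf <- coef(fit)
  params <- weibull_params(cf[["alpha"]], cf[["beta"]], cf[["Xeq"]])
  new_model_fit("weibull", params, params$Xeq, curve,
                predicted = weibull_moisture(t, Xw0, params), observed = X,
                Z = 3, converged = TRUE, residual_on = residual_on)
}

#' Fit the logarithmic model to a soaking curve
#'
#' The model `X = Xeq + (Xw0 - Xeq) ln(k t)` is linear in `ln t`, so the
#' least-squares solution is closed form: regressing `X` on `ln t` gives
#' intercept `a` and slope `b`, from which `Xeq = Xw0 - b` and
#' `k = exp((a - Xeq) / b)`. Points at `t = 0` are excluded (the logarithm
#' is singular there); `Z = 2`.
#'
#' @inheritParams fit_peleg
#' @return A `model_fit` object.
#' @export
fit_proposed <- function(curve, residual_on = c("moisture", "moisture_ratio")) {
  stopifnot(inherits(curve, "rehydration_curve"))
  residual_on <- match.arg(residual_on)
  keep <- curve$times > 0
  t <- curve$times[keep]; X <- curve$moistures[keep]; Xw0 <- curve$Xw0
  if (length(t) <= 2)
    stop("logarithmic model needs more than 2 points with t > 0", call. = FALSE)
  ols <- coef(lm(X ~ log(t)))
  a <- ols[[1]]; b <- ols[[2]]
  if (b == 0 || !is.finite(b))
    stop_degenerate(curve)
  Xeq <- Xw0 - b
  k <- exp((a - Xeq) / b)
  params <- proposed_params(k, Xeq)
  new_model_fit("proposed", params, Xeq, curve,
                predicted = proposed_moisture(t, Xw0, params), observed = X,
                Z = 2, converged = TRUE, residual_on = residual_on)
}

#' Fit all three rehydration models to one curve
#'
#' @inheritParams fit_peleg
#' @param models Character vector naming the models to fit.
#' @return A named list of `model_fit` objects; a model whose fit raises a
#'   degenerate-curve error is dropped with a warning.
#' @export
fit_rehydration_models <- function(curve,
                                   models = c("peleg", "weibull", "proposed"),
                                   residual_on = c("moisture", "moisture_ratio")) {
  residual_on <- match.arg(residual_on)
  models <- match.arg(models, several.ok = TRUE)
  fitters <- list(peleg = fit_peleg, weibull = fit_weibull,
                  proposed = fit_proposed)
  out <- list()
  for (m in models) {
    f <- tryCatch(fitters[[m]](curve, residual_on = residual_on),
                  error = function(e) {
                    warning(sprintf("%s fit failed for %s: %s", m,
                                    condition_label(curve), conditionMessage(e)),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(f)) out[[m]] <- f
  }
  out
}

#' Rank fitted models by goodness of fit
#'
#' Converged fits are ordered by R-squared (descending), breaking ties by
#' RMSE, then reduced chi-square (both ascending), then by fewer fitted
#' parameters; remaining ties keep the input order. Non-converged fits are
#' appended after all converged ones.
#'
#' @param fits A list of `model_fit` objects, at least one converged.
#' @return The same fits, reordered.
#' @export
rank_models <- function(fits) {
  if (length(fits) == 0) stop("no fits to rank", call. = FALSE)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stop("no converged fits to rank", call. = FALSE)
  ok <- fits[conv]
  key <- function(field) vapply(ok, function(f) f$stats[[field]], numeric(1))
  ord <- order(-key("R2"), key("RMSE"), key("chi2"), key("Z"))
  c(ok[ord], fits[!conv])
}
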