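# Forward evaluation of the three rehydration models. All moistures are
# dry basis (g water / g dry matter), all times in minutes.

check_time <- function(t, allow_zero = TRUE) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("soaking time must be finite and numeric", call. = FALSE)
  if (allow_zero) {
    if (any(t < 0)) stop("soaking time must be >= 0", call. = FALSE)
  } else {
    if (any(t <= 0)) stop("soaking time must be > 0 for the logarithmic model",
                          call. = FALSE)
  }
  invisible(t)
}

#' Peleg model parameters
#'
#' @param k1 Peleg rate constant, min·(g dry matter / g water). Lower values
#'   mean faster initial uptake.
#' @param k2 Peleg capacity constant, g dry matter / g water. Controls the
#'   asymptotic uptake: the equilibrium moisture is `Xw0 + 1/k2`.
#' @return An object of class `peleg_params`.
#' @export
peleg_params <- function(k1, k2) {
  stopifnot(is.numeric(k1), is.numeric(k2), length(k1) == 1, length(k2) == 1)
  if (!is.finite(k1) || k1 <= 0) stop("k1 must be a positive number", call. = FALSE)
  if (!is.finite(k2) || k2 <= 0) stop("k2 must be a positive number", call. = FALSE)
  structure(list(k1 = k1, k2 = k2), class = "peleg_params")
}

#' Weibull model parameters
#'
#' @param alpha Dimensionless shape factor; values below 1 give a steep
#'   initial uptake.
#' @param beta Scale factor in minutes: the soaking time at which 63%
#'   (1 - exp(-1)) of the total moisture change has occurred, for any shape.
#' @param Xeq Equilibrium moisture content, g water / g dry matter.
#' @return An object of class `weibull_params`.
#' @export
weibull_params <- function(alpha, beta, Xeq) {
  stopifnot(length(alpha) == 1, length(beta) == 1, length(Xeq) == 1)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (!is.finite(Xeq) || Xeq < 0) stop("Xeq must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, Xeq = Xeq), class = "weibull_params")
}

#' Logarithmic model parameters
#'
#' Parameters of the logarithmic rehydration model
#' `X(t) = Xeq + (Xw0 - Xeq) * ln(k * t)`, which is linear in `ln t` with
#' slope `Xw0 - Xeq`. For an increasing soaking curve the fitted `Xeq` falls
#' below `Xw0` and is reported as fitted, without reinterpretation.
#'
#' @param k Rehydration rate parameter, 1/min.
#' @param Xeq Fitted equilibrium moisture, g water / g dry matter. May be
#'   negative: it is the curve's value at `t = 1/k`, not a physical bound.
#' @return An object of class `proposed_params`.
#' @export
proposed_params <- function(k, Xeq) {
  stopifnot(length(k) == 1, length(Xeq) == 1)
  if (!is.finite(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  if (!is.finite(Xeq)) stop("Xeq must be finite", call. = FALSE)
  structure(list(k = k, Xeq = Xeq), class = "proposed_params")
}

#' Peleg moisture curve
#'
#' Evaluates the Peleg sorption model
#' `X(t) = Xw0 + t / (k1 + k2 * t)`:
#' strictly increasing in `t` and bounded above by `Xw0 + 1/k2`.
#'
#' @param t Soaking time(s), minutes, `>= 0`.
#' @param Xw0 Initial dry-basis moisture, g/g.
#' @param params A [peleg_params()] object.
#' @return Dry-basis moisture content(s), g/g.
#' @export
#' @examples
#' peleg_moisture(10, 0.10, peleg_params(k1 = 8.13, k2 = 0.146))
peleg_moisture <- function(t, Xw0, params) {
  stopifnot(inherits(params, "peleg_params"), is.numeric(Xw0), Xw0 >= 0)
  check_time(t)
  Xw0 + t / (params$k1 + params$k2 * t)
}

#' Peleg equilibrium moisture content
#'
#' The `t -> Inf` limit of the Peleg model: `Xeq = Xw0 + 1/k2`.
#'
#' @param Xw0 Initial dry-basis moisture, g/g.
#' @param k2 Peleg capacity constant, g dry matter / g water, `> 0`.
#' @return Equilibrium dry-basis moisture, g/g.
#' @export
#' @examples
#' peleg_equilibrium(0, 0.176)  # 5.682 g/g
peleg_equilibrium <- function(Xw0, k2) {
  stopifnot(is.numeric(Xw0), is.numeric(k2))
  if (any(!is.finite(k2)) || any(k2 <= 0)) stop("k2 must be > 0", call. = FALSE)
  Xw0 + 1 / k2
}

#' Weibull moisture curve
#'
#' Evaluates the stretched-exponential (Weibull) rehydration model
#' `X(t) = Xeq + (Xw0 - Xeq) * exp(-(t/beta)^alpha)`. The normalized
#' residual `(X(t) - Xeq)/(Xw0 - Xeq)` equals `exp(-1)` at `t = beta`
#' regardless of the shape `alpha` — the "63% of total uptake" time.
#'
#' @inheritParams peleg_moisture
#' @param params A [weibull_params()] object.
#' @return Dry-basis moisture content(s), g/g.
#' @export
weibull_moisture <- function(t, Xw0, params) {
  stopifnot(inherits(params, "weibull_params"), is.numeric(Xw0), Xw0 >= 0)
  check_time(t)
  params$Xeq + (Xw0 - params$Xeq) * exp(-(t / params$beta)^params$alpha)
}

#' Logarithmic moisture curve
#'
#' Evaluates `X(t) = Xeq + (Xw0 - Xeq) * ln(k * t)`. Undefined at `t = 0`
#' (the first soaking sample is taken at 5 min); non-positive times are an
#' error, never clipped. The curve passes through `Xeq` at `t = 1/k` and
#' through `Xw0` at `t = e/k`.
#'
#' @inheritParams peleg_moisture
#' @param params A [proposed_params()] object.
#' @return Dry-basis moisture content(s), g/g.
#' @export
proposed_moisture <- function(t, Xw0, params) {
  stopifnot(inherits(params, "proposed_params"), is.numeric(Xw0), Xw0 >= 0)
  check_time(t, allow_zero = FALSE)
  params$Xeq + (Xw0 - params$Xeq) * log(params$k * t)
}
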