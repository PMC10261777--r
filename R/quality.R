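# Physical, color and moisture-basis quality metrics for dried and
# rehydrated kernels.

#' Rehydration ratio
#'
#' Ratio of the mass of the rehydrated sample to the mass of the dried
#' sample.
#'
#' @param mass_rehydrated Mass of the rehydrated sample, g.
#' @param mass_dried Mass of the dried sample, g.
#' @return Dimensionless ratio (vectorized).
#' @export
rehydration_ratio <- function(mass_rehydrated, mass_dried) {
  stopifnot(is.numeric(mass_rehydrated), is.numeric(mass_dried))
  if (any(!is.finite(mass_rehydrated)) || any(mass_rehydrated <= 0) ||
      any(!is.finite(mass_dried)) || any(mass_dried <= 0))
    stop("masses must be positive", call. = FALSE)
  mass_rehydrated / mass_dried
}

#' Rehydration rate of a soaking curve
#'
#' Finite-difference water uptake rates. The instantaneous rate over
#' interval `i` is `(X[i+1] - X[i]) / (t[i+1] - t[i])`; the average rate is
#' the endpoint slope `(X[N] - X[1]) / (t[N] - t[1])`. Both are reported
#' because per-interval and whole-soak rates answer different questions.
#'
#' @param curve A [rehydration_curve()] (any object with at least two
#'   `times`/`moistures` pairs).
#' @return A list with `interval_rates` (length `N - 1`, labelled by
#'   interval midpoint time) and `average_rate`, both in
#'   g water / (g dry matter * min).
#' @export
rehydration_rate <- function(curve) {
  t <- curve$times; X <- curve$moistures
  if (length(t) < 2) stop("need at least two points for a rate", call. = FALSE)
  rates <- diff(X) / diff(t)
  names(rates) <- sprintf("t%.1f", (head(t, -1) + t[-1]) / 2)
  list(interval_rates = rates,
       average_rate = (X[length(X)] - X[1]) / (t[length(t)] - t[1]))
}

#' Geometric mean diameter of a kernel
#'
#' Cube root of the product of the three mutually normal dimensions:
#' length (the maximum dimension), width and thickness.
#'
#' @param L,W,T Kernel length, width, thickness in mm (vectorized).
#' @return Geometric mean diameter, mm.
#' @export
#' @examples
#' geometric_mean_diameter(9, 8, 6)  # 7.5595 mm
geometric_mean_diameter <- function(L, W, T) {
  stopifnot(is.numeric(L), is.numeric(W), is.numeric(T))
  if (any(!is.finite(c(L, W, T))) || any(c(L, W, T) <= 0))
    stop("kernel dimensions must be positive", call. = FALSE)
  (L * W * T)^(1 / 3)
}

#' Total color difference (CIE76 Delta E)
#'
#' Euclidean distance between two CIELAB triples; conventionally the
#' reference is the fresh kernel's color. Smaller values mean better color
#' retention. The original CIE76 form is used throughout.
#'
#' @param reference,sample Numeric length-3 vectors `c(L*, a*, b*)`, or
#'   data frames / matrices with columns in that order (rowwise distance).
#' @return Delta E in CIELAB units.
#' @export
#' @examples
#' total_color_difference(c(0, 0, 0), c(3, 4, 0))  # 5
total_color_difference <- function(reference, sample) {
  ref <- as_lab(reference); smp <- as_lab(sample)
  if (nrow(ref) == 1 && nrow(smp) > 1) ref <- ref[rep(1, nrow(smp)), , drop = FALSE]
  if (nrow(smp) == 1 && nrow(ref) > 1) smp <- smp[rep(1, nrow(ref)), , drop = FALSE]
  if (nrow(ref) != nrow(smp))
    stop("reference and sample must have matching rows", call. = FALSE)
  d <- sqrt(rowSums((ref - smp)^2))
  unname(d)
}

as_lab <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3) stop("a CIELAB color is a length-3 (L*, a*, b*) triple",
                             call. = FALSE)
    x <- matrix(x, nrow = 1)
  }
  if (ncol(x) != 3) stop("CIELAB input needs 3 columns (L*, a*, b*)", call. = FALSE)
  if (any(!is.finite(x))) stop("CIELAB values must be finite", call. = FALSE)
  if (any(x[, 1] < 0 | x[, 1] > 100))
    stop("L* must lie in [0, 100]", call. = FALSE)
  x
}

#' Convert moisture content between wet and dry basis
#'
#' Wet-basis moisture is water mass over total mass; dry basis is water
#' mass over bone-dry matter. `db = wb / (1 - wb)` and `wb = db / (1 + db)`.
#'
#' @param wb_fraction Wet-basis moisture as a fraction in `[0, 1)`.
#' @param db Dry-basis moisture, g water / g dry matter, `>= 0`.
#' @return The converted moisture (vectorized).
#' @export
#' @examples
#' moisture_wb_to_db(0.75)  # 3.0 g/g dry basis
moisture_wb_to_db <- function(wb_fraction) {
  stopifnot(is.numeric(wb_fraction))
  if (any(!is.finite(wb_fraction)) || any(wb_fraction < 0) || any(wb_fraction >= 1))
    stop("wet-basis moisture must lie in [0, 1)", call. = FALSE)
  wb_fraction / (1 - wb_fraction)
}

#' @rdname moisture_wb_to_db
#' @export
moisture_db_to_wb <- function(db) {
  stopifnot(is.numeric(db))
  if (any(!is.finite(db)) || any(db < 0))
    stop("dry-basis moisture must be >= 0", call. = FALSE)
  db / (1 + db)
}
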