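# Seeded synthetic data with the study's structure: 4 blanching
# pretreatments (control, hot water HB, steam SB, microwave MB) x 4 drying
# temperatures (55-70 degC), soaking sampled every 5 min up to 60 min.

PRETREATMENTS <- c("control", "HB", "SB", "MB")
TEMPERATURES <- c(55, 60, 65, 70)

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset * 9973) %% 2147483646L) + 1L
}

#' Reference Peleg parameters of the study design
#'
#' Per-condition Peleg rate (`k1`, min·g dm/g water) and capacity (`k2`,
#' g dm/g water) constants for the 16 pretreatment-by-temperature
#' conditions, used as the generating truth of the synthetic curves. These
#' are the only complete per-condition parameter sets reported for the
#' design, so the generator's curves are Peleg curves by default.
#'
#' @return A data frame with columns `pretreatment`, `temperature_C`,
#'   `k1`, `k2`.
#' @export
peleg_reference_params <- function() {
  data.frame(
    pretreatment = rep(PRETREATMENTS, each = 4),
    temperature_C = rep(TEMPERATURES, times = 4),
    k1 = c(8.13, 7.56, 9.30, 6.90,   # control
           7.86, 4.87, 5.34, 8.75,   # HB
           6.01, 6.20, 4.90, 6.20,   # SB
           5.20, 4.20, 3.40, 2.60),  # MB
    k2 = c(0.146, 0.176, 0.196, 0.208,
           0.196, 0.197, 0.211, 0.234,
           0.213, 0.246, 0.261, 0.277,
           0.286, 0.311, 0.321, 0.327))
}

lerp_by_temp <- function(at55, at70, temperature) {
  frac <- (temperature - 55) / 15
  at55 + frac * (at70 - at55)
}

#' Per-condition means of the treatment properties
#'
#' Cell means for the 16 conditions, chosen so each property's span per
#' pretreatment matches the study's reported ranges: rehydration ratio
#' (e.g. control 2.88-3.54), dried kernel mass (0.10-0.12 g), total color
#' difference (control 31.23-26.34 down to MB 15.23-11.12), total sugar
#' (5.21-7.41 g/100 g), ascorbic acid (4.24-6.01 mg/100 g) and sensory
#' score (maximum 8.62 at MB, 70 degC). Values vary linearly with drying
#' temperature inside each pretreatment's span.
#'
#' @return A data frame of 16 rows of property means plus a kernel
#'   swelling factor `dim_scale` applied to the fresh dimensions.
#' @export
default_property_means <- function() {
  spans <- list(  # per pretreatment: c(at 55 degC, at 70 degC)
    RR       = list(control = c(2.88, 3.54), HB = c(2.56, 3.46),
                    SB = c(2.23, 3.13), MB = c(2.56, 2.65)),
    deltaE   = list(control = c(31.23, 26.34), HB = c(27.63, 21.23),
                    SB = c(25.61, 19.36), MB = c(15.23, 11.12)),
    sugar    = list(control = c(5.21, 5.53), HB = c(6.13, 6.63),
                    SB = c(6.61, 7.26), MB = c(7.21, 7.41)),
    ascorbic = list(control = c(4.24, 4.61), HB = c(5.23, 5.51),
                    SB = c(5.46, 5.63), MB = c(5.83, 6.01)),
    sensory  = list(control = c(6.00, 6.90), HB = c(6.50, 7.40),
                    SB = c(6.80, 7.70), MB = c(7.80, 8.62)),
    dim_scale = list(control = c(1.02, 1.08), HB = c(1.03, 1.08),
                     SB = c(1.02, 1.07), MB = c(0.96, 0.94)))
  dried_mass <- c(control = 0.11, HB = 0.10, SB = 0.12, MB = 0.10)
  grid <- expand.grid(temperature_C = TEMPERATURES,
                      pretreatment = PRETREATMENTS,
                      stringsAsFactors = FALSE)[, 2:1]
  out <- grid
  for (prop in names(spans)) {
    out[[prop]] <- mapply(function(p, T) {
      s <- spans[[prop]][[p]]
      lerp_by_temp(s[1], s[2], T)
    }, grid$pretreatment, grid$temperature_C)
  }
  out$mass_dried_g <- dried_mass[grid$pretreatment]
  rownames(out) <- NULL
  out
}

#' Specification of a synthetic study
#'
#' Bundles everything the generator needs: the design (all 16 conditions by
#' default), the generating Peleg parameters, the soaking time grid, the
#' curve noise level, the treatment-property cell means, and the seed that
#' fixes all randomness.
#'
#' @param seed Integer seed; every random draw in the generator derives
#'   from it, so equal seeds give bitwise-identical output.
#' @param time_grid Soaking times in minutes, strictly increasing
#'   (default 0, 5, ..., 60).
#' @param noise_sd Additive Gaussian noise on the curve moistures,
#'   g/g (default 0.05); generated moistures are truncated below at 0.
#' @param Xw0 Initial dry-basis moisture of the dried kernels, g/g.
#' @param models Data frame of generating Peleg parameters per condition
#'   (defaults to [peleg_reference_params()]).
#' @param property_means Data frame of treatment-property cell means
#'   (defaults to [default_property_means()]).
#' @param property_sd Named list of noise SDs for the property table.
#' @param fresh_color Fresh-kernel CIELAB reference `c(L*, a*, b*)`.
#' @param fresh_mass_g,fresh_dims_mm Fresh kernel mass (g) and dimensions
#'   `c(L, W, T)` in mm.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           time_grid = seq(0, 60, by = 5),
                           noise_sd = 0.05,
                           Xw0 = 0.05,
                           models = peleg_reference_params(),
                           property_means = default_property_means(),
                           property_sd = list(mass = 0.003, RR = 0.04,
                                              dims = 0.08, lab = 0.3,
                                              sugar = 0.04, ascorbic = 0.04,
                                              sensory = 0.08),
                           fresh_color = c(72, 5, 48),
                           fresh_mass_g = 0.44,
                           fresh_dims_mm = c(9.5, 8.2, 6.0)) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            all(diff(time_grid) > 0), noise_sd >= 0, Xw0 >= 0)
  stopifnot(all(c("pretreatment", "temperature_C", "k1", "k2") %in% names(models)))
  structure(list(seed = as.integer(seed), time_grid = time_grid,
                 noise_sd = noise_sd, Xw0 = Xw0, models = models,
                 property_means = property_means, property_sd = property_sd,
                 fresh_color = fresh_color, fresh_mass_g = fresh_mass_g,
                 fresh_dims_mm = fresh_dims_mm),
            class = "synthetic_spec")
}

condition_index <- function(spec, pretreatment, temperature) {
  i <- which(spec$models$pretreatment == pretreatment &
             spec$models$temperature_C == temperature)
  if (length(i) != 1)
    stop(sprintf("unknown condition: %s at %s degC", pretreatment,
                 format(temperature)), call. = FALSE)
  i
}

#' Generate one synthetic soaking curve
#'
#' Evaluates the condition's generating Peleg model on the time grid and
#' adds seeded Gaussian noise (truncated below at zero moisture). With
#' `noise_sd = 0` the curve equals the model exactly. The same spec and
#' condition always produce the same curve, independent of generation
#' order.
#'
#' @param spec A [synthetic_spec()].
#' @param pretreatment,temperature Condition identifiers present in the
#'   spec's design.
#' @return A [rehydration_curve()].
#' @export
generate_curve <- function(spec, pretreatment, temperature) {
  stopifnot(inherits(spec, "synthetic_spec"))
  i <- condition_index(spec, pretreatment, temperature)
  row <- spec$models[i, ]
  clean <- peleg_moisture(spec$time_grid, spec$Xw0,
                          peleg_params(row$k1, row$k2))
  set.seed(derive_seed(spec$seed, i))
  noisy <- pmax(clean + rnorm(length(clean), 0, spec$noise_sd), 0)
  rehydration_curve(spec$time_grid, noisy,
                    pretreatment = pretreatment, temperature = temperature,
                    Xw0 = if (spec$time_grid[1] == 0) noisy[1] else spec$Xw0)
}

#' Generate the full design's soaking curves
#'
#' @param spec A [synthetic_spec()].
#' @return A named list of [rehydration_curve()]s, one per design
#'   condition, named `<pretreatment>_<temperature>`.
#' @export
generate_curves <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- lapply(seq_len(nrow(spec$models)), function(i) {
    generate_curve(spec, spec$models$pretreatment[i],
                   spec$models$temperature_C[i])
  })
  names(out) <- sprintf("%s_%s", spec$models$pretreatment,
                        spec$models$temperature_C)
  out
}

#' Generate a synthetic treatment-property table
#'
#' One record per design condition with masses, kernel dimensions, CIELAB
#' color, total sugar, ascorbic acid and sensory score drawn around the
#' spec's cell means. The sample color is placed at the configured total
#' color difference from the fresh reference along a fixed browning
#' direction (darker, redder, less yellow), so recomputing Delta E against
#' the fresh color recovers the configured mean. The rehydrated mass is
#' the dried mass times the condition's rehydration ratio, keeping the
#' mass ratio and the configured ratio consistent. Zero noise SDs
#' reproduce the configured means exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return A data frame of 16 treatment records.
#' @export
generate_treatment_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pm <- spec$property_means
  sdv <- spec$property_sd
  n <- nrow(pm)
  set.seed(derive_seed(spec$seed, 100))
  browning <- c(-2, 1, -1) / sqrt(6)
  mass_dried <- pmax(pm$mass_dried_g + rnorm(n, 0, sdv$mass), 1e-3)
  RR <- pmax(pm$RR + rnorm(n, 0, sdv$RR), 1)
  dE <- pmax(pm$deltaE + rnorm(n, 0, sdv$lab), 0)
  lab <- t(vapply(dE, function(d) spec$fresh_color + d * browning, numeric(3)))
  dims <- t(vapply(pm$dim_scale, function(s) spec$fresh_dims_mm * s, numeric(3)))
  dims <- dims + matrix(rnorm(3 * n, 0, sdv$dims), n, 3)
  data.frame(
    pretreatment = pm$pretreatment,
    temperature_C = pm$temperature_C,
    mass_fresh_g = spec$fresh_mass_g,
    mass_dried_g = mass_dried,
    mass_rehydrated_g = mass_dried * RR,
    L_mm = dims[, 1], W_mm = dims[, 2], T_mm = dims[, 3],
    Lstar = lab[, 1], astar = lab[, 2], bstar = lab[, 3],
    total_sugar_g_per_100g = pm$sugar + rnorm(n, 0, sdv$sugar),
    ascorbic_acid_mg_per_100g = pm$ascorbic + rnorm(n, 0, sdv$ascorbic),
    sensory_score = pmin(pm$sensory + rnorm(n, 0, sdv$sensory), 9))
}

#' Structured treatment matrix with controlled effect sizes
#'
#' Builds a 16-treatment feature matrix in which every property is an
#' additive combination of a drying-temperature effect and a pretreatment
#' effect with chosen magnitudes, plus seeded Gaussian noise. The
#' temperature response is threshold-like (scores -1, -0.6, 0.6, 1 for
#' 55-70 degC): structural damage to kernels accelerates above about
#' 60 degC, so properties shift more between 60 and 65 degC than within
#' either regime. With the temperature effect a few times the pretreatment
#' effect, the dendrogram's root split therefore separates the 55/60 degC
#' conditions from the 65/70 degC ones.
#'
#' @param temp_effect,pretreat_effect Effect magnitudes in SD units of the
#'   factor scores.
#' @param n_properties Number of property columns.
#' @param noise_sd Residual noise SD.
#' @param seed Integer seed.
#' @return A numeric matrix with rows named `<pretreatment>_<temperature>`.
#' @export
structured_treatment_matrix <- function(temp_effect = 3, pretreat_effect = 1,
                                        n_properties = 6, noise_sd = 0.1,
                                        seed = 1L) {
  grid <- expand.grid(temperature_C = TEMPERATURES,
                      pretreatment = PRETREATMENTS,
                      stringsAsFactors = FALSE)
  z_temp <- scale(c(-1, -0.6, 0.6, 1)[factor(grid$temperature_C)])[, 1]
  z_pret <- scale(as.numeric(factor(grid$pretreatment)))[, 1]
  set.seed(derive_seed(seed, 200))
  loadings_t <- runif(n_properties, 0.6, 1) * rep_len(c(1, -1), n_properties)
  loadings_p <- runif(n_properties, 0.6, 1) * rep_len(c(-1, 1), n_properties)
  m <- outer(z_temp, loadings_t) * temp_effect +
       outer(z_pret, loadings_p) * pretreat_effect +
       matrix(rnorm(16 * n_properties, 0, noise_sd), 16, n_properties)
  rownames(m) <- sprintf("%s_%s", grid$pretreatment, grid$temperature_C)
  colnames(m) <- sprintf("prop%d", seq_len(n_properties))
  m
}
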