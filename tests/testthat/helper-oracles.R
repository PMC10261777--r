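# Independent oracles used by the fitting and clustering tests. These stay
# deliberately naive (grids, O(n^3) agglomeration) so they share no code
# path with the package's implementations.

sse_peleg <- function(curve, k1, k2) {
  pred <- curve$Xw0 + curve$times / (k1 + k2 * curve$times)
  sum((curve$moistures - pred)^2)
}

sse_weibull <- function(curve, alpha, beta, Xeq) {
  pred <- Xeq + (curve$Xw0 - Xeq) * exp(-(curve$times / beta)^alpha)
  sum((curve$moistures - pred)^2)
}

sse_proposed <- function(curve, k, Xeq) {
  keep <- curve$times > 0
  pred <- Xeq + (curve$Xw0 - Xeq) * log(k * curve$times[keep])
  sum((curve$moistures[keep] - pred)^2)
}

# Exhaustive SSE minimum over a k1 x k2 grid.
grid_min_peleg <- function(curve, k1_range = c(0.5, 15),
                           k2_range = c(0.05, 0.5), n = 400) {
  k1s <- seq(k1_range[1], k1_range[2], length.out = n)
  k2s <- seq(k2_range[1], k2_range[2], length.out = n)
  acc <- matrix(0, n, n)
  for (i in seq_along(curve$times)) {
    t <- curve$times[i]
    pred <- curve$Xw0 + t / outer(k1s, k2s * t, "+")
    acc <- acc + (curve$moistures[i] - pred)^2
  }
  min(acc)
}

grid_min_weibull <- function(curve) {
  Xmax <- max(curve$moistures)
  grid <- expand.grid(alpha = seq(0.2, 1.5, length.out = 25),
                      beta = seq(3, 100, length.out = 30),
                      Xeq = seq(0.5 * Xmax, 1.8 * Xmax, length.out = 30))
  min(mapply(function(a, b, x) sse_weibull(curve, a, b, x),
             grid$alpha, grid$beta, grid$Xeq))
}

grid_min_proposed <- function(curve) {
  grid <- expand.grid(k = exp(seq(log(0.05), log(5), length.out = 200)),
                      Xeq = seq(-6, 0, length.out = 200))
  min(mapply(function(k, x) sse_proposed(curve, k, x), grid$k, grid$Xeq))
}

fit_sse <- function(fit, curve) {
  switch(fit$model,
         peleg = sse_peleg(curve, fit$params$k1, fit$params$k2),
         weibull = sse_weibull(curve, fit$params$alpha, fit$params$beta,
                               fit$params$Xeq),
         proposed = sse_proposed(curve, fit$params$k, fit$params$Xeq))
}

# Draws generating parameters from the study's reported ranges. The
# logarithmic model's parameters are drawn from the regime in which the
# curve stays non-negative over the 5-60 min grid.
draw_true_params <- function(model) {
  switch(model,
         peleg = list(k1 = runif(1, 2.6, 9.3), k2 = runif(1, 0.146, 0.327)),
         weibull = list(alpha = runif(1, 0.599, 0.926),
                        beta = runif(1, 10.42, 53.68),
                        Xeq = runif(1, 3.07, 6.85)),
         proposed = list(k = runif(1, 0.55, 0.85),
                         Xeq = runif(1, -1.8, -0.5)))
}

model_values <- function(model, t, Xw0, p) {
  switch(model,
         peleg = peleg_moisture(t, Xw0, peleg_params(p$k1, p$k2)),
         weibull = weibull_moisture(t, Xw0, weibull_params(p$alpha, p$beta, p$Xeq)),
         proposed = proposed_moisture(t[t > 0], Xw0, proposed_params(p$k, p$Xeq)))
}

# One synthetic curve for recovery studies. The logarithmic model is
# generated on the 5-60 min grid (its value at t = 0 is undefined); the
# t = 0 anchor point carries Xw0 exactly.
make_model_curve <- function(model, p, noise_sd = 0, Xw0 = 0.1,
                             times = seq(0, 60, by = 5)) {
  if (model == "proposed") {
    tt <- times[times > 0]
    X <- c(Xw0, model_values(model, tt, Xw0, p))
  } else {
    X <- model_values(model, times, Xw0, p)
  }
  X <- pmax(X + rnorm(length(X), 0, noise_sd), 0)
  X[1] <- max(X[1], 0)
  rehydration_curve(times, X, Xw0 = if (times[1] == 0) NULL else Xw0)
}

fitter_for <- function(model)
  switch(model, peleg = fit_peleg, weibull = fit_weibull,
         proposed = fit_proposed)

# Naive O(n^3) average-linkage agglomeration on a raw distance matrix;
# returns the sorted merge heights.
brute_average_heights <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  sort(heights)
}
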