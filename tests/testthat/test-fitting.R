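test_that("noise-free Peleg curves are recovered essentially exactly", {
  p <- list(k1 = 8.13, k2 = 0.146)
  curve <- make_model_curve("peleg", p, noise_sd = 0, Xw0 = 0.10,
                            times = seq(0, 60, by = 5))
  fit <- fit_peleg(curve)
  expect_true(fit$converged)
  expect_equal(fit$params$k1, p$k1, tolerance = 1e-6)
  expect_equal(fit$params$k2, p$k2, tolerance = 1e-6)
  expect_equal(fit$stats$R2, 1, tolerance = 1e-9)
  expect_lt(fit$stats$RMSE, 1e-7)
  expect_lt(fit$stats$chi2, 1e-12)
  expect_equal(fit$Xeq_derived, 0.10 + 1 / p$k2, tolerance = 1e-6)
})

test_that("noise-free Weibull curves are recovered essentially exactly", {
  p <- list(alpha = 0.78, beta = 23.18, Xeq = 3.1)
  curve <- make_model_curve("weibull", p, noise_sd = 0, Xw0 = 0.1)
  fit <- fit_weibull(curve)
  expect_true(fit$converged)
  expect_equal(fit$params$alpha, p$alpha, tolerance = 1e-5)
  expect_equal(fit$params$beta, p$beta, tolerance = 1e-5)
  expect_equal(fit$params$Xeq, p$Xeq, tolerance = 1e-5)
})

test_that("Weibull fits respect their parameter box and improve on the start", {
  set.seed(21)
  for (i in 1:10) {
    p <- draw_true_params("weibull")
    curve <- make_model_curve("weibull", p, noise_sd = 0.05)
    fit <- fit_weibull(curve)
    expect_true(fit$converged)
    expect_true(fit$params$alpha > 0 && fit$params$alpha <= 5)
    expect_gt(fit$params$beta, 0)
    # the optimizer can only improve on its own initialization
    Xeq0 <- max(curve$moistures) * 1.05
    target <- curve$Xw0 + (1 - exp(-1)) * (Xeq0 - curve$Xw0)
    beta0 <- max(curve$times[which.min(abs(curve$moistures - target))],
                 min(curve$times[curve$times > 0]))
    expect_lte(fit_sse(fit, curve),
               sse_weibull(curve, 1, beta0, Xeq0) + 1e-10)
  }
})

test_that("logarithmic fit matches its closed form and an NLS restart", {
  p <- list(k = 0.6, Xeq = -1.5)
  tt <- seq(5, 60, by = 5)
  X <- proposed_moisture(tt, 0.1, proposed_params(p$k, p$Xeq))
  curve <- rehydration_curve(c(0, tt), c(0.1, X), Xw0 = NULL)
  fit <- fit_proposed(curve)
  expect_equal(fit$params$k, p$k, tolerance = 1e-10)
  expect_equal(fit$params$Xeq, p$Xeq, tolerance = 1e-10)

  # self-consistency oracle: the problem is linear after reparameterization,
  # so NLS started from the closed form must not move
  set.seed(22)
  noisy <- rehydration_curve(c(0, tt), c(0.1, X + rnorm(length(X), 0, 0.05)),
                             Xw0 = NULL)
  nf <- fit_proposed(noisy)
  keep <- noisy$times > 0
  d <- list(t = noisy$times[keep], X = noisy$moistures[keep], Xw0 = noisy$Xw0)
  nls_fit <- minpack.lm::nlsLM(
    X ~ Xeq + (Xw0 - Xeq) * log(k * t), data = d,
    start = list(k = nf$params$k, Xeq = nf$params$Xeq),
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14))
  expect_equal(coef(nls_fit)[["k"]], nf$params$k, tolerance = 1e-8)
  expect_equal(coef(nls_fit)[["Xeq"]], nf$params$Xeq, tolerance = 1e-8)
})

test_that("degenerate and under-determined curves raise descriptive errors", {
  flat <- rehydration_curve(seq(0, 60, 5), rep(0.2, 13))
  expect_error(fit_peleg(flat), "degenerate")
  expect_error(fit_weibull(flat), "degenerate")
  expect_error(goodness_of_fit(rep(0.2, 13), rep(0.2, 13), Z = 2),
               "zero variance")
  # three positive-time points are the minimum for the 2-parameter log model
  expect_no_error(fit_proposed(rehydration_curve(c(0, 3, 6, 9),
                                                 c(0.1, 0.4, 0.6, 0.7))))
  expect_error(rehydration_curve(c(0, 0, 5, 10), c(0.1, 0.1, 0.5, 0.9)),
               "strictly increasing")
  expect_error(goodness_of_fit(1:3, c(1, 2, 3.5), Z = 3), "degrees of freedom")
})

test_that("goodness-of-fit statistics match hand arithmetic and scale correctly", {
  stats <- goodness_of_fit(c(0.1, -0.1, 0.2), c(0, 0, 0), Z = 1)
  expect_equal(stats$RMSE, sqrt(0.06 / 3), tolerance = 1e-12)
  expect_equal(stats$chi2, 0.06 / 2, tolerance = 1e-12)

  obs <- c(0.5, 1.2, 2.0, 2.4)
  perfect <- goodness_of_fit(obs, obs, Z = 2)
  expect_equal(perfect$R2, 1)
  expect_equal(perfect$RMSE, 0)
  expect_equal(perfect$chi2, 0)

  # doubling every residual doubles RMSE and quadruples chi2
  s1 <- goodness_of_fit(obs, obs - c(0.1, -0.2, 0.05, 0.1), Z = 2)
  s2 <- goodness_of_fit(obs, obs - 2 * c(0.1, -0.2, 0.05, 0.1), Z = 2)
  expect_equal(s2$RMSE, 2 * s1$RMSE, tolerance = 1e-12)
  expect_equal(s2$chi2, 4 * s1$chi2, tolerance = 1e-12)
})

test_that("chi2 and RMSE satisfy their algebraic identity on real fits", {
  set.seed(23)
  for (model in c("peleg", "weibull", "proposed")) {
    for (i in 1:5) {
      curve <- make_model_curve(model, draw_true_params(model), noise_sd = 0.05)
      fit <- fitter_for(model)(curve)
      s <- fit$stats
      expect_equal(s$chi2 * (s$N - s$Z), s$RMSE^2 * s$N, tolerance = 1e-12)
    }
  }
  # Peleg equilibrium moisture is monotone decreasing in k2 at fixed Xw0
  k2s <- seq(0.1, 0.4, by = 0.05)
  expect_true(all(diff(peleg_equilibrium(0.1, k2s)) < 0))
})

test_that("model ranking orders by R2 then RMSE, chi2 and parsimony", {
  stub <- function(model, R2, RMSE, chi2, Z)
    structure(list(model = model, converged = TRUE,
                   stats = list(R2 = R2, RMSE = RMSE, chi2 = chi2,
                                N = 13, Z = Z)),
              class = "model_fit")
  fits <- list(stub("peleg", 0.98, 0.09, 0.01, 2),
               stub("weibull", 0.994, 0.064, 0.005, 3),
               stub("proposed", 0.994, 0.07, 0.005, 2))
  ranked <- rank_models(fits)
  expect_equal(ranked[[1]]$stats$RMSE, 0.064)
  expect_equal(ranked[[1]]$model, "weibull")

  single <- rank_models(fits[2])
  expect_equal(single[[1]]$model, "weibull")

  tied <- list(stub("a", 0.99, 0.05, 0.01, 3), stub("b", 0.99, 0.05, 0.01, 2),
               stub("c", 0.99, 0.05, 0.01, 3))
  ranked_tied <- rank_models(tied)
  expect_equal(vapply(ranked_tied, `[[`, "", "model"), c("b", "a", "c"))
  expect_error(rank_models(list()), "no fits")
})
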