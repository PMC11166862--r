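test_that("g(t) and the edge model match hand-computed values", {
  p <- sde_params(c0 = 60, sigma = 1, gamma = 2.5, baseline = 0)
  expect_equal(sde_g(0, p), 16.979952, tolerance = 1e-6)
  # root of the numerator: u = -lambda / (gamma + sigma^2/2)
  t_root <- 50 + log(1e-13) / 3
  expect_equal(sde_g(t_root, p), 0, tolerance = 1e-10)
  expect_equal(sde_edge(t_root, p), 30)          # B + C0/2 at the g-root
  expect_equal(sde_edge(0, p), 60, tolerance = 1e-8)
  expect_lt(sde_edge(49.99, p), 1e-4)            # decays to baseline at T
  expect_error(sde_g(50, p), "T")
  expect_error(sde_g(-0.1, p), "T")
})

test_that("sde_params validates its domain", {
  expect_error(sde_params(60, sigma = 0, gamma = 1), "sigma")
  expect_error(sde_params(60, 1, 1, dt = 1.5), "dt")
  expect_error(sde_params(60, 1, 1, lambda = 1), "lambda")
})

test_that("per-pixel differences telescope and cap at one", {
  p <- params_with_half_at(60, sigma = 1.5, t_half = 22)
  d <- model_differential(p, eval_dt = 1)  # unit-spaced grid
  expect_equal(sum(d$diff_px),
               pnorm(sde_g(0, p)) - pnorm(sde_g(max(d$t) + 1, p)),
               tolerance = 1e-12)
  expect_true(all(d$diff_px <= 1 + 1e-15))

  # near-zero diffusion: the unit step falls inside one pixel
  sharp <- params_with_half_at(60, sigma = 1e-3, t_half = 22)
  expect_gt(max(model_differential(sharp)$diff_px), 0.999)
})

test_that("analytic derivative matches a fine central difference", {
  p <- params_with_half_at(60, sigma = 1, t_half = 20)
  t <- seq(0.5, 45, by = 0.1)  # the evaluation grid, away from t = T
  h <- 1e-5
  num <- (pnorm(sde_g(t + h, p)) - pnorm(sde_g(t - h, p))) / (2 * h)
  ana <- effcnr:::sde_dphi_dt(t, p)
  keep <- abs(num) > 1e-12
  expect_lt(max(abs(ana[keep] / num[keep] - 1)), 1e-6)
})

test_that("sharpness index is contrast-free, bounded and blur-monotone", {
  s1 <- sharpness_index(params_with_half_at(100, 1, 20))
  s2 <- sharpness_index(params_with_half_at(1, 1, 20))
  expect_equal(s1$sharpness_index, s2$sharpness_index)
  expect_gt(s1$sharpness_index, 0)
  expect_lte(s1$sharpness_index, 1)
  expect_true(s1$argmax_t > 0 && s1$argmax_t < 50)

  # larger diffusion at a fixed edge position spreads the unit mass
  idx <- vapply(c(0.5, 1, 2, 4), function(sig) {
    sharpness_index(params_with_half_at(60, sig, 20))$sharpness_index
  }, numeric(1))
  expect_true(all(diff(idx) < 0))
})

test_that("noiseless model profiles are recovered essentially exactly", {
  for (c0 in c(15, 60)) {
    for (sig in c(0.5, 1, 2)) {
      for (t_half in c(15, 25)) {
        truth <- params_with_half_at(c0, sig, t_half)
        fit <- fit_edge_model(model_profile(truth, t = 0:49))
        expect_true(fit$converged)
        expect_lt(abs(coef(fit)["c0"] / c0 - 1), 0.01)
        idx_true <- sharpness_index(truth)$sharpness_index
        idx_fit <- sharpness_index(fit)$sharpness_index
        expect_lt(abs(idx_fit / idx_true - 1), 0.02)
      }
    }
  }
})

test_that("contrast survives 2 HU profile noise on average", {
  truth <- params_with_half_at(60, 1, 20)
  clean <- sde_edge(0:49, truth)
  c0_hat <- vapply(1:10, function(s) {
    y <- clean + effcnr:::local_seed(s, rnorm(50, sd = 2))
    prof <- effcnr:::new_edge_profile(0:49, y, rep(1L, 50))
    unname(coef(fit_edge_model(prof))["c0"])
  }, numeric(1))
  expect_lt(abs(mean(c0_hat) / 60 - 1), 0.05)
})

test_that("degenerate profiles are rejected, non-convergence is flagged", {
  flat <- effcnr:::new_edge_profile(0:49, rep(10, 50), rep(1L, 50))
  expect_error(fit_edge_model(flat), "flat profile")
  short <- effcnr:::new_edge_profile(0:5, c(9, 8, 7, 3, 1, 0), rep(1L, 6))
  expect_error(fit_edge_model(short), "at least 10")
})

test_that("fit methods behave like a classed model object", {
  truth <- params_with_half_at(60, 1, 20, baseline = 12)
  fit <- fit_edge_model(model_profile(truth, t = 0:49))
  expect_named(coef(fit), c("c0", "sigma", "gamma", "baseline"))
  expect_equal(unname(coef(fit)["baseline"]), 12, tolerance = 0.05)
  expect_equal(fitted(fit) + residuals(fit), fit$profile$mean_hu)
  expect_equal(predict(fit, t = 0), sde_edge(0, fit$params))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(50L, 3L))
  expect_output(print(fit), "SDE edge-model fit")
  expect_output(print(summary(fit)), "Effective contrast")
})

test_that("effective contrast composes contrast and sharpness", {
  truth <- params_with_half_at(60, 1, 20)
  fit <- fit_edge_model(model_profile(truth, t = 0:49))
  idx_true <- sharpness_index(truth)$sharpness_index
  expect_equal(effective_contrast(fit), 60 * idx_true, tolerance = 0.02 * 60 * idx_true)
  bad <- fit; bad$converged <- FALSE
  expect_error(effective_contrast(bad), "non-converged")
})
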