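test_that("aggregation collapses trials into per-level binomial counts", {
  obs <- observer_params()
  agg <- sim_agg(obs, default_design("TOJ"), seed = 1)
  expect_equal(nrow(agg), 11)
  expect_true(all(agg$n == 20))
  expect_equal(sum(agg$n), 220)

  expect_error(aggregate_trials(tibble::tibble()), "aggregation error")

  all0 <- tibble::tibble(level = rep(c(0, 1), each = 5), response = 0L)
  expect_true(all(aggregate_trials(all0)$k == 0))

  mixed <- dplyr::bind_rows(
    simulate_trials(obs, default_design("TOJ"), "o1", 1),
    simulate_trials(obs, default_design("SJ"), "o1", 2))
  expect_error(aggregate_trials(mixed), "aggregation error")
})

test_that("model probabilities match their closed forms", {
  expect_equal(model_probability("toj4", c(0, 1, 0, 0), 0), 0.5)
  expect_equal(model_probability("sj3", c(0.9, 0.05, 0.1), 0.05), 0.9)
  expect_equal(model_probability("dur2", c(0.7, 0.1), 0.7), 0.5)
  expect_equal(model_probability("toj4", c(0, 0.05, 0.1, 0.2), 1e3), 0.8)
  expect_error(model_probability("toj4", c(0, -1, 0, 0), 0), "sigma")
  expect_error(model_probability("sj3", c(1.5, 0, 0.1), 0), "amplitude")
})

test_that("likelihood equals brute-force per-trial enumeration", {
  data <- aggregated_data(c(-0.1, 0, 0.1), k = c(2, 18, 3), n = c(20, 20, 20))
  params <- c(0.85, 0.01, 0.08)
  expect_equal(negative_log_likelihood("sj3", params, data),
               nll_by_enumeration("sj3", params, data), tolerance = 1e-10)

  data4 <- aggregated_data(seq(-0.2, 0.2, by = 0.1),
                           k = c(1, 5, 11, 16, 19), n = rep(20, 5))
  params4 <- c(0.01, 0.07, 0.04, 0.02)
  expect_equal(negative_log_likelihood("toj4", params4, data4),
               nll_by_enumeration("toj4", params4, data4), tolerance = 1e-10)
})

test_that("likelihood is bounded below by the saturated model", {
  agg <- sim_agg(observer_params(), default_design("TOJ"), seed = 2)
  f <- k <- agg$k / agg$n
  saturated <- -sum(ifelse(agg$k > 0, agg$k * log(f), 0) +
                      ifelse(agg$n - agg$k > 0, (agg$n - agg$k) * log(1 - f), 0))
  fit <- fit_psychometric(agg)
  expect_gte(fit$nll, saturated)

  # perfect separation with a step-like curve drives the NLL to ~0
  sep <- aggregated_data(c(-0.25, 0.25), k = c(0, 20), n = c(20, 20))
  expect_lt(negative_log_likelihood("dur2", c(0, 0.001), sep), 1e-6)
})

test_that("maximum likelihood recovers generating parameters at large n", {
  obs <- observer_params(delta_l = 0.05, sigma_toj = 0.06,
                         gamma_toj = 0.02, lambda_toj = 0.02)
  fit <- fit_psychometric(sim_agg(obs, default_design("TOJ", trials_per_level = 10000),
                                  seed = 21))
  expect_true(fit$converged)
  expect_equal(unname(fit$par["mu"]), 0.05, tolerance = 0.005 / 0.05)

  obs_sj <- observer_params(delta_l = 0.055, sigma_sj = 0.08, amp_sj = 0.95)
  fit_sj <- fit_psychometric(sim_agg(obs_sj, default_design("SJ", trials_per_level = 10000),
                                     seed = 22))
  expect_true(fit_sj$converged)
  expect_equal(unname(fit_sj$par["mu"]), 0.055, tolerance = 0.005 / 0.055)
  expect_equal(unname(fit_sj$par["amp"]), 0.95, tolerance = 0.02 / 0.95)
})

test_that("separation data put the fitted location between the jumps", {
  data <- aggregated_data(1:4, k = c(0, 0, 10, 10), n = rep(10, 4))
  fit <- fit_psychometric(data, family = "dur2")
  expect_gt(unname(fit$par["mu"]), 2)
  expect_lt(unname(fit$par["mu"]), 3)
})

test_that("too few levels is an error, not a bad fit", {
  expect_error(fit_psychometric(aggregated_data(c(0, 0.1), k = c(1, 9),
                                                n = c(10, 10)),
                                family = "toj4"),
               "fit error")
})

test_that("fitted NLL beats an exhaustive parameter grid on small data", {
  set.seed(31)
  for (family in c("dur2", "sj3")) {
    for (rep in 1:3) {
      truth <- if (family == "dur2") c(0.05, 0.1) else c(0.9, 0.02, 0.12)
      levels <- seq(-0.2, 0.2, by = 0.1)
      p <- model_probability(family, truth, levels)
      data <- aggregated_data(levels, k = rbinom(5, 25, pmin(pmax(p, 0), 1)),
                              n = rep(25, 5))
      fit <- fit_psychometric(data, family = family)
      expect_lte(fit$nll, grid_min_nll(family, data) + 1e-6)
    }
  }
})

test_that("PSE extraction follows the fitted family", {
  # symmetric lapses leave the 50% point at mu
  fit <- structure(list(family = "toj4",
                        par = c(mu = 0.045, sigma = 0.05, gamma = 0.1,
                                lambda = 0.1),
                        nll = 1, converged = TRUE),
                   class = "psychometric_fit")
  expect_equal(pse(fit), 0.045)

  # asymmetric lapse: root of gamma + (1-gamma-lambda) Phi((s-mu)/sigma) = 0.5,
  # checked against bisection on the model curve
  fit$par <- c(mu = 0, sigma = 0.05, gamma = 0.2, lambda = 0)
  root <- uniroot(function(s) model_probability("toj4", fit$par, s) - 0.5,
                  c(-1, 1), tol = 1e-12)$root
  expect_equal(pse(fit), root, tolerance = 1e-8)
  expect_equal(pse(fit), -0.01593, tolerance = 1e-3)

  fit$par <- c(mu = 0, sigma = 0.05, gamma = 0.5, lambda = 0)
  expect_error(pse(fit), "PSE undefined")

  fit_sj <- structure(list(family = "sj3",
                           par = c(amp = 0.9, mu = 0.055, sigma = 0.1),
                           nll = 1, converged = TRUE),
                      class = "psychometric_fit")
  expect_equal(pse(fit_sj), 0.055)
})

test_that("fits are deterministic and equivariant to shifts and scalings", {
  agg <- sim_agg(observer_params(), default_design("TOJ"), seed = 41)
  fit1 <- fit_psychometric(agg)
  fit2 <- fit_psychometric(agg)
  expect_identical(fit1$par, fit2$par)

  shift <- 0.13
  agg_shift <- aggregated_data(agg$level + shift, agg$k, agg$n)
  fit_shift <- fit_psychometric(agg_shift, family = "toj4")
  expect_equal(unname(fit_shift$par["mu"]), unname(fit1$par["mu"]) + shift,
               tolerance = 1e-4)
  expect_equal(pse(fit_shift), pse(fit1) + shift, tolerance = 1e-4)

  k <- 2.5
  agg_scale <- aggregated_data(agg$level * k, agg$k, agg$n)
  fit_scale <- fit_psychometric(agg_scale, family = "toj4")
  expect_equal(unname(fit_scale$par["mu"]), unname(fit1$par["mu"]) * k,
               tolerance = 1e-3)
  expect_equal(unname(fit_scale$par["sigma"]), unname(fit1$par["sigma"]) * k,
               tolerance = 1e-3)
})
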