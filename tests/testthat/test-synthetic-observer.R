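test_that("default designs reproduce the published stimulus grids", {
  toj <- default_design("TOJ")
  expect_equal(toj$levels, seq(-0.25, 0.25, by = 0.05))
  expect_length(toj$levels, 11)
  expect_equal(toj$trials_per_level, 20L)
  expect_equal(length(toj$levels) * toj$trials_per_level, 220L)

  sj <- default_design("SJ")
  expect_equal(sj$levels, toj$levels)

  d06 <- default_design("DURATION", condition = "AVVA", standard = 0.6)
  expect_equal(d06$levels, c(0.3, 0.4, 0.5, 0.6, 0.8))
  d12 <- default_design("DURATION", condition = "VAAV", standard = 1.2)
  expect_equal(d12$levels, c(1.0, 1.2, 1.6, 2.0, 2.4))
  expect_equal(d12$condition, "VAAV")

  expect_error(default_design("DURATION", condition = "AVVA", standard = 0.9),
               "invalid design")
  expect_error(default_design("DURATION"), "invalid design")
})

test_that("observer parameter invariants are enforced", {
  expect_error(observer_params(gamma_toj = 0.6, lambda_toj = 0.5), "lapse")
  expect_error(observer_params(amp_sj = 0), "amp_sj")
  expect_error(observer_params(sigma_sj = -1), "positive")
  expect_s3_class(observer_params(), "observer_params")
})

test_that("order-judgment curve matches the four-parameter cumulative normal", {
  obs <- observer_params(delta_l = 0, sigma_toj = 0.05,
                         gamma_toj = 0, lambda_toj = 0)
  expect_equal(toj_probability(obs, 0), 0.5)

  obs2 <- observer_params(delta_l = 0.03, gamma_toj = 0.1, lambda_toj = 0.2)
  expect_equal(toj_probability(obs2, 100), 0.8, tolerance = 1e-12)
  expect_equal(toj_probability(obs2, -100), 0.1, tolerance = 1e-12)

  # equal lapses average to (gamma + 1 - lambda)/2 = 0.5 at s = delta_l
  obs3 <- observer_params(delta_l = 0.02, sigma_toj = 0.05,
                          gamma_toj = 0.1, lambda_toj = 0.1)
  expect_equal(toj_probability(obs3, 0.02), 0.5)

  # monotone non-decreasing over a grid, for a spread of parameters
  grid <- seq(-0.4, 0.4, by = 0.01)
  for (obs in list(observer_params(), obs2, obs3,
                   observer_params(delta_l = -0.08, sigma_toj = 0.02,
                                   gamma_toj = 0.3, lambda_toj = 0.05))) {
    expect_true(all(diff(toj_probability(obs, grid)) >= 0))
  }
})

test_that("simultaneity curve is a scaled Gaussian centred on delta_l", {
  obs <- observer_params(delta_l = 0.055, sigma_sj = 0.1, amp_sj = 1)
  expect_equal(sj_probability(obs, 0.055), 1)
  obs2 <- observer_params(delta_l = 0, sigma_sj = 0.1, amp_sj = 0.8)
  expect_equal(sj_probability(obs2, 1e6), 0)
  expect_equal(sj_probability(obs2, 0.1), 0.8 * exp(-0.5), tolerance = 1e-12)
  # symmetry about the peak
  x <- seq(0, 0.5, by = 0.01)
  obs3 <- observer_params(delta_l = 0.04)
  expect_equal(sj_probability(obs3, 0.04 + x), sj_probability(obs3, 0.04 - x))
})

test_that("duration curve shifts the PSE by +/- twice the latency difference", {
  avva <- default_design("DURATION", condition = "AVVA", standard = 0.6)
  vaav <- default_design("DURATION", condition = "VAAV", standard = 0.6)

  obs0 <- observer_params(delta_l = 0, toe = 0)
  expect_equal(duration_probability(obs0, avva, 0.6), 0.5)

  obs <- observer_params(delta_l = 0.05, toe = 0, sigma_dur = 0.1)
  expect_equal(duration_probability(obs, avva, 0.7), 0.5)
  expect_equal(true_duration_pse(obs, avva), 0.7)

  obs_toe <- observer_params(delta_l = 0.05, toe = 0.03)
  expect_equal(true_duration_pse(obs_toe, vaav), 0.53)

  # symmetric deviations about the standard when toe = 0 and no order bias
  for (dl in c(-0.07, 0, 0.04)) {
    o <- observer_params(delta_l = dl, toe = 0, dur_order_bias = 0)
    expect_equal(true_duration_pse(o, avva) - 0.6, 0.6 - true_duration_pse(o, vaav))
  }
})

test_that("simulation is seed-deterministic and sized by the design", {
  obs <- observer_params()
  d <- default_design("TOJ")
  t1 <- simulate_trials(obs, d, "o1", seed = 7)
  t2 <- simulate_trials(obs, d, "o1", seed = 7)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 220)
  expect_false(identical(t1, simulate_trials(obs, d, "o1", seed = 8)))
})

test_that("a near-deterministic observer saturates the extreme level", {
  obs <- observer_params(delta_l = 0, sigma_toj = 1e-6,
                         gamma_toj = 0, lambda_toj = 0)
  tr <- simulate_trials(obs, default_design("TOJ"), "o1", seed = 3)
  expect_true(all(tr$response[tr$level == 0.25] == 1L))
  expect_true(all(tr$response[tr$level == -0.25] == 0L))
})

test_that("empirical frequencies converge to the true curve", {
  obs <- observer_params(delta_l = 0.05, gamma_toj = 0.03, lambda_toj = 0.08)
  d <- default_design("TOJ", trials_per_level = 10000)
  agg <- sim_agg(obs, d, seed = 11)
  expect_true(all(abs(agg$k / agg$n - toj_probability(obs, agg$level)) < 0.02))

  dsj <- default_design("SJ", trials_per_level = 10000)
  aggs <- sim_agg(observer_params(delta_l = -0.02, amp_sj = 0.9), dsj, seed = 12)
  expect_true(all(abs(aggs$k / aggs$n -
                        sj_probability(observer_params(delta_l = -0.02,
                                                       amp_sj = 0.9),
                                       aggs$level)) < 0.02))
})

test_that("cohort sampling is deterministic and respects the range", {
  cohort <- sample_cohort(7, delta_l_range = c(-0.1, 0.1), seed = 5)
  expect_length(cohort, 7)
  dls <- vapply(cohort, `[[`, numeric(1), "delta_l")
  expect_true(all(dls >= -0.1 & dls <= 0.1))
  expect_identical(dls,
                   vapply(sample_cohort(7, c(-0.1, 0.1), seed = 5),
                          `[[`, numeric(1), "delta_l"))
})
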