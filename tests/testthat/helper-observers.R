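# Shared fixtures: lapse-free observers make parameter recovery exact in the
# limit; distorted ones carry the biases the estimators must tolerate.

clean_observer <- function(delta_l = 0.05, ...) {
  observer_params(delta_l = delta_l, gamma_toj = 0, lambda_toj = 0,
                  amp_sj = 1, toe = 0, dur_order_bias = 0, ...)
}

# simulate + aggregate in one step
sim_agg <- function(obs, design, seed) {
  aggregate_trials(simulate_trials(obs, design, "obs", seed))
}

# both duration conditions for one standard -> duration_pair of fitted PSEs
fit_duration_pair <- function(obs, standard, trials_per_level, seed) {
  pses <- vapply(c("AVVA", "VAAV"), function(cond) {
    d <- default_design("DURATION", condition = cond, standard = standard,
                        trials_per_level = trials_per_level)
    pse(fit_psychometric(sim_agg(obs, d, seed + match(cond, c("AVVA", "VAAV")))))
  }, numeric(1))
  duration_pair(pses[["AVVA"]], pses[["VAAV"]], standard)
}

# brute-force NLL: per-trial Bernoulli log-probabilities summed one by one,
# independent of the vectorised likelihood under test
nll_by_enumeration <- function(family, params, data) {
  total <- 0
  for (i in seq_len(nrow(data))) {
    p <- model_probability(family, params, data$level[i])
    p <- min(max(p, 1e-9), 1 - 1e-9)
    for (t in seq_len(data$n[i])) {
      total <- total - if (t <= data$k[i]) log(p) else log(1 - p)
    }
  }
  total
}

# exhaustive grid minimum of the NLL (oracle for the optimiser)
grid_min_nll <- function(family, data, n_grid = 41) {
  rng <- diff(range(data$level))
  mu_g <- seq(min(data$level) - rng, max(data$level) + rng, length.out = n_grid)
  sig_g <- seq(rng / 1000, 10 * rng, length.out = n_grid)
  best <- Inf
  if (family == "dur2") {
    for (m in mu_g) for (s in sig_g) {
      best <- min(best, negative_log_likelihood(family, c(m, s), data))
    }
  } else if (family == "sj3") {
    amp_g <- seq(0.01, 1, length.out = n_grid)
    for (a in amp_g) for (m in mu_g) for (s in sig_g) {
      best <- min(best, negative_log_likelihood(family, c(a, m, s), data))
    }
  } else {
    lapse_g <- seq(0, 0.49, length.out = n_grid)
    gl <- expand.grid(g = lapse_g, l = lapse_g)
    for (m in mu_g) for (s in sig_g) {
      p_base <- pnorm((data$level - m) / s)
      p <- outer(1 - gl$g - gl$l, p_base) + gl$g  # combos x levels
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      nll <- -(log(p) %*% data$k + log1p(-p) %*% (data$n - data$k))
      best <- min(best, min(nll))
    }
  }
  best
}
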