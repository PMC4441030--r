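#' Aggregate trial-level data to per-level binomial counts
#'
#' Collapses a trial table (as produced by [simulate_trials()] or read by
#' [read_trials()]) into the per-level `(level, k, n)` triples that the
#' binomial likelihood needs: `k` is the number of positive responses and
#' `n` the number of trials at each stimulus level.  All trials must come
#' from a single task (and, for the duration task, a single condition and
#' standard); aggregating a mixture would silently average different
#' psychometric functions.
#'
#' @param trials A tibble/data frame with at least `level` and `response`
#'   columns; `task`, `condition`, `standard`, `observer_id` are carried as
#'   attributes when present.
#' @return A tibble of class `aggregated_data` with columns `level`, `k`,
#'   `n`, ordered by level.
#' @examples
#' trials <- simulate_trials(observer_params(), default_design("TOJ"),
#'                           "o1", seed = 1)
#' aggregate_trials(trials)
#' @export
aggregate_trials <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0) {
    stop("aggregation error: no trials to aggregate", call. = FALSE)
  }
  stopifnot(all(c("level", "response") %in% names(trials)))
  if (!all(trials$response %in% c(0L, 1L))) {
    stop("aggregation error: responses must be 0 or 1", call. = FALSE)
  }
  for (col in c("task", "condition", "standard", "observer_id")) {
    if (col %in% names(trials)) {
      vals <- unique(trials[[col]])
      if (length(vals[!is.na(vals)]) > 1 || length(vals) > 1) {
        stop("aggregation error: trials mix more than one `", col, "`",
             call. = FALSE)
      }
    }
  }
  agg <- dplyr::summarise(dplyr::group_by(trials, .data$level),
                          k = sum(.data$response), n = dplyr::n(),
                          .groups = "drop")
  agg <- dplyr::arrange(agg, .data$level)
  out <- tibble::new_tibble(agg, class = "aggregated_data")
  for (col in c("task", "condition", "standard", "observer_id")) {
    if (col %in% names(trials)) attr(out, col) <- trials[[col]][1]
  }
  out
}

#' Build aggregated data directly from counts
#'
#' @param level Strictly increasing stimulus levels (s).
#' @param k Positive-response counts per level.
#' @param n Trial counts per level.
#' @return An `aggregated_data` tibble.
#' @export
aggregated_data <- function(level, k, n) {
  stopifnot(length(level) == length(k), length(k) == length(n),
            !is.unsorted(level, strictly = TRUE),
            all(n >= 1), all(k >= 0), all(k <= n))
  tibble::new_tibble(
    tibble::tibble(level = as.numeric(level), k = as.integer(k),
                   n = as.integer(n)),
    class = "aggregated_data"
  )
}

family_names <- c("toj4", "sj3", "dur2")

param_names <- function(family) {
  switch(family,
         toj4 = c("mu", "sigma", "gamma", "lambda"),
         sj3 = c("amp", "mu", "sigma"),
         dur2 = c("mu", "sigma"))
}

check_params <- function(family, params) {
  np <- length(param_names(family))
  if (length(params) != np || any(!is.finite(params))) {
    stop("invalid parameters for family `", family, "`", call. = FALSE)
  }
  p <- as.list(stats::setNames(as.numeric(params), param_names(family)))
  if (p$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (family == "toj4" &&
      (p$gamma < 0 || p$lambda < 0 || p$gamma + p$lambda >= 1)) {
    stop("lapse rates must satisfy gamma, lambda >= 0 and gamma + lambda < 1",
         call. = FALSE)
  }
  if (family == "sj3" && (p$amp <= 0 || p$amp > 1)) {
    stop("amplitude must lie in (0, 1]", call. = FALSE)
  }
  p
}

#' Psychometric-function families
#'
#' Evaluates the model probability of a positive response at stimulus level
#' `x` for the three families used in the analysis:
#' * `"toj4"` — four-parameter cumulative normal
#'   `gamma + (1 - gamma - lambda) * pnorm((x - mu) / sigma)` (temporal
#'   order judgments with independent lapse rates on each side);
#' * `"sj3"` — three-parameter scaled Gaussian
#'   `amp * exp(-(x - mu)^2 / (2 sigma^2))` (simultaneity judgments);
#' * `"dur2"` — two-parameter cumulative normal `pnorm((x - mu) / sigma)`
#'   (duration comparisons).
#'
#' Returned values are the exact model probabilities; clamping away from 0
#' and 1 happens only inside the likelihood.
#'
#' @param family `"toj4"`, `"sj3"` or `"dur2"`.
#' @param params Parameter vector in the family's canonical order
#'   (`toj4`: mu, sigma, gamma, lambda; `sj3`: amp, mu, sigma; `dur2`: mu,
#'   sigma).
#' @param x Stimulus level(s) in seconds.
#' @return Probabilities, vectorised over `x`.
#' @examples
#' model_probability("toj4", c(0, 1, 0, 0), 0)     # 0.5
#' model_probability("sj3", c(0.9, 0.05, 0.1), 0.05)  # 0.9
#' @export
model_probability <- function(family, params, x) {
  family <- match.arg(family, family_names)
  p <- check_params(family, params)
  switch(family,
         toj4 = p$gamma + (1 - p$gamma - p$lambda) *
           stats::pnorm((x - p$mu) / p$sigma),
         sj3 = p$amp * exp(-(x - p$mu)^2 / (2 * p$sigma^2)),
         dur2 = stats::pnorm((x - p$mu) / p$sigma))
}

# probability clamp used inside the likelihood; part of the contract
.nll_eps <- 1e-9

# raw (unvalidated) model probability, for use inside the optimiser
model_prob_raw <- function(family, params, x) {
  if (family == "toj4") {
    params[3] + (1 - params[3] - params[4]) * stats::pnorm((x - params[1]) / params[2])
  } else if (family == "sj3") {
    params[1] * exp(-(x - params[2])^2 / (2 * params[3]^2))
  } else {
    stats::pnorm((x - params[1]) / params[2])
  }
}

nll_raw <- function(family, params, level, k, n) {
  p <- model_prob_raw(family, params, level)
  p <- pmin(pmax(p, .nll_eps), 1 - .nll_eps)
  -sum(k * log(p) + (n - k) * log1p(-p))
}

# analytic gradient of nll_raw; levels whose probability sits in the clamp
# region contribute zero, matching the (locally flat) clamped objective
nll_grad <- function(family, params, level, k, n) {
  p <- model_prob_raw(family, params, level)
  pc <- pmin(pmax(p, .nll_eps), 1 - .nll_eps)
  w <- (n * pc - k) / (pc * (1 - pc))
  w[p < .nll_eps | p > 1 - .nll_eps] <- 0
  if (family == "toj4") {
    z <- (level - params[1]) / params[2]
    span <- 1 - params[3] - params[4]
    phi <- stats::dnorm(z)
    Phi <- stats::pnorm(z)
    c(sum(w * (-span * phi / params[2])),
      sum(w * (-span * phi * z / params[2])),
      sum(w * (1 - Phi)),
      sum(w * (-Phi)))
  } else if (family == "sj3") {
    z <- (level - params[2]) / params[3]
    g <- exp(-z^2 / 2)
    c(sum(w * g),
      sum(w * params[1] * g * z / params[3]),
      sum(w * params[1] * g * z^2 / params[3]))
  } else {
    z <- (level - params[1]) / params[2]
    phi <- stats::dnorm(z)
    c(sum(w * (-phi / params[2])),
      sum(w * (-phi * z / params[2])))
  }
}

#' Binomial negative log-likelihood of a psychometric model
#'
#' `-sum(k * log(p) + (n - k) * log(1 - p))` over the levels of `data`,
#' with model probabilities clamped to `[1e-9, 1 - 1e-9]` so the value is
#' finite even at saturated levels.
#'
#' @inheritParams model_probability
#' @param data An `aggregated_data` tibble (or anything with `level`, `k`,
#'   `n` columns).
#' @return The negative log-likelihood (a non-negative scalar).
#' @export
negative_log_likelihood <- function(family, params, data) {
  family <- match.arg(family, family_names)
  check_params(family, params)
  nll_raw(family, as.numeric(params), data$level, data$k, data$n)
}

fit_bounds <- function(family, level) {
  rng <- diff(range(level))
  if (rng <= 0) stop("fit error: need at least two distinct levels", call. = FALSE)
  mu <- c(min(level) - rng, max(level) + rng)
  sigma <- c(rng / 1000, 10 * rng)
  switch(family,
         toj4 = list(lower = c(mu[1], sigma[1], 0, 0),
                     upper = c(mu[2], sigma[2], 0.49, 0.49)),
         sj3 = list(lower = c(0.01, mu[1], sigma[1]),
                    upper = c(1, mu[2], sigma[2])),
         dur2 = list(lower = c(mu[1], sigma[1]),
                     upper = c(mu[2], sigma[2])))
}

default_starts <- function(family, data) {
  rng <- diff(range(data$level))
  mus <- data$level
  sigmas <- rng * c(1 / 8, 1 / 3, 1)
  starts <- list()
  for (m in mus) for (s in sigmas) {
    if (family == "toj4") {
      for (lapse in c(0, 0.1)) {
        starts[[length(starts) + 1]] <- c(m, s, lapse, lapse)
      }
    } else if (family == "sj3") {
      for (a in c(0.6, 1)) {
        starts[[length(starts) + 1]] <- c(a, m, s)
      }
    } else {
      starts[[length(starts) + 1]] <- c(m, s)
    }
  }
  starts
}

#' Fit a psychometric function by maximum likelihood
#'
#' Minimises the binomial negative log-likelihood within box bounds
#' (location within the level range extended by one range on each side, SD
#' between range/1000 and 10 times the range, lapse rates in \[0, 0.49\],
#' amplitude in \[0.01, 1\]) by L-BFGS-B with analytic gradients, restarted
#' from a coarse grid of initial values (every observed level as a starting
#' location, three starting SDs, and for the order task lapse rates 0 and
#' 0.1) — four-parameter fits on a dozen binomial points have local optima,
#' and a single heuristic start is not reliable.
#'
#' @param data An `aggregated_data` tibble ([aggregate_trials()],
#'   [aggregated_data()]).
#' @param family `"toj4"`, `"sj3"` or `"dur2"`; defaults to the family
#'   matching the data's task attribute when present.
#' @param starts Optional list of starting parameter vectors replacing the
#'   default multi-start grid (used e.g. to warm-start bootstrap refits).
#' @return An object of class `psychometric_fit`: a list with `family`,
#'   named `par`, `nll`, `converged` and the `data` fitted.
#' @examples
#' trials <- simulate_trials(observer_params(delta_l = 0.05),
#'                           default_design("TOJ"), "o1", seed = 8)
#' fit <- fit_psychometric(aggregate_trials(trials))
#' pse(fit)
#' @export
fit_psychometric <- function(data, family = NULL, starts = NULL) {
  if (is.null(family)) {
    task <- attr(data, "task")
    if (is.null(task)) stop("fit error: supply `family` or data with a task attribute",
                            call. = FALSE)
    family <- c(TOJ = "toj4", SJ = "sj3", DURATION = "dur2")[[task]]
  }
  family <- match.arg(family, family_names)
  keep <- data$n > 0
  level <- data$level[keep]; k <- data$k[keep]; n <- data$n[keep]
  np <- length(param_names(family))
  if (length(unique(level)) < np) {
    stop("fit error: need at least ", np, " distinct levels with trials",
         call. = FALSE)
  }
  b <- fit_bounds(family, level)
  if (is.null(starts)) starts <- default_starts(family, data[keep, ])
  fn <- function(par) nll_raw(family, par, level, k, n)
  gr <- function(par) nll_grad(family, par, level, k, n)
  best <- NULL
  for (s0 in starts) {
    s0 <- pmin(pmax(s0, b$lower), b$upper)
    res <- tryCatch(
      stats::optim(s0, fn, gr, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("fit error: all optimisation starts failed", call. = FALSE)
  }
  # the saturated model bounds every NLL from below; attaining it (e.g. on
  # fully separated data, where sigma runs to its bound and the line search
  # aborts on the flat clamped objective) is global convergence regardless
  # of the optimiser's status code
  f_obs <- k / n
  saturated <- -sum(ifelse(k > 0, k * log(f_obs), 0) +
                      ifelse(n - k > 0, (n - k) * log1p(-f_obs), 0))
  converged <- best$convergence == 0 || best$value <= saturated + 1e-6
  if (!converged) {
    # near-degenerate curves can abort the line search at the optimum;
    # restart from the stopping point and accept stationarity when the
    # restart cannot improve the objective
    res2 <- tryCatch(
      stats::optim(best$par, fn, gr, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(res2)) {
      improvement <- best$value - res2$value
      if (res2$value < best$value) best <- res2
      converged <- res2$convergence == 0 || improvement < 1e-6
    }
  }
  structure(
    list(family = family,
         par = stats::setNames(best$par, param_names(family)),
         nll = best$value,
         converged = converged,
         data = aggregated_data(level, k, n)),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric fit (", x$family, ")\n", sep = "")
  print(round(x$par, 5))
  cat("  NLL:", format(x$nll), " converged:", x$converged, "\n")
  invisible(x)
}

#' Point of subjective equality of a fitted curve
#'
#' For the four-parameter order-judgment curve, the stimulus level at which
#' the positive-response probability crosses 0.5,
#' `mu + sigma * qnorm((0.5 - gamma) / (1 - gamma - lambda))`; the crossing
#' exists only when both asymptotes straddle 0.5 (`gamma < 0.5` and
#' `lambda < 0.5`).  For the scaled-Gaussian simultaneity curve and the
#' two-parameter duration curve the PSE is the fitted location `mu`.
#'
#' @param fit A `psychometric_fit`.
#' @return The PSE in seconds.
#' @export
pse <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  p <- as.list(fit$par)
  switch(fit$family,
         toj4 = {
           if (p$gamma >= 0.5 || p$lambda >= 0.5) {
             stop("PSE undefined: the fitted curve never attains 0.5",
                  call. = FALSE)
           }
           p$mu + p$sigma * stats::qnorm((0.5 - p$gamma) / (1 - p$gamma - p$lambda))
         },
         sj3 = p$mu,
         dur2 = p$mu)
}
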