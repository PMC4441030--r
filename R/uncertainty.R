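#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact interval obtained by inverting binomial tail tests, computed
#' through the beta-quantile characterisation: the lower bound is
#' `qbeta(alpha/2, k, n - k + 1)` (0 when `k = 0`) and the upper bound
#' `qbeta(1 - alpha/2, k + 1, n - k)` (1 when `k = n`).  The interval
#' always contains the observed proportion `k/n` and its coverage is at
#' least the nominal level for every true probability.
#'
#' @param k Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A named numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(10, 20)  # approx (0.272, 0.728)
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (!is.numeric(k) || !is.numeric(n) || length(k) != 1 || length(n) != 1 ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("k must be an integer in 0..n with n >= 1", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Parametric bootstrap of a psychometric fit
#'
#' For each of `n_boot` replicates, simulates new per-level counts
#' `k* ~ Binomial(n_i, p_hat_i)` from the fitted curve at the original
#' levels, refits the same family, and records the refitted parameters and
#' a derived quantity (by default the [pse()]).  Refits warm-start from the
#' original maximum-likelihood solution: bootstrap data are drawn from that
#' very curve, so the original optimum is an excellent start and the full
#' multi-start grid is redundant.
#' Replicates whose refit does not converge are dropped (not retried —
#' retrying would bias the bootstrap distribution) and counted in
#' `n_failed`; a warning is raised when more than 5% fail.
#'
#' Per-replicate seeds are drawn up front from the master `seed`
#' (`sample.int(2^31 - 2, n_boot)` under `seed`), so replicate `b` is
#' reproducible in isolation and results do not depend on execution order.
#'
#' @param fit A converged `psychometric_fit`.
#' @param n_boot Number of bootstrap replicates (study convention: 1,000).
#' @param seed Master integer seed.
#' @param derived_fn Function of a `psychometric_fit` returning a scalar;
#'   default [pse()].
#' @return An object of class `bootstrap_result`: list with `samples` (one
#'   row of refitted parameters per successful replicate), `derived`
#'   (numeric vector), `n_boot`, `n_failed`, `seed`.
#' @export
parametric_bootstrap <- function(fit, n_boot = 1000, seed, derived_fn = pse) {
  stopifnot(inherits(fit, "psychometric_fit"), n_boot >= 1)
  if (!fit$converged) stop("cannot bootstrap a fit that did not converge",
                           call. = FALSE)
  level <- fit$data$level
  n <- fit$data$n
  p_hat <- model_prob_raw(fit$family, fit$par, level)
  p_hat <- pmin(pmax(p_hat, 0), 1)
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(2147483646L, n_boot))
  par0 <- unname(fit$par)
  starts <- list(par0)
  samples <- matrix(NA_real_, n_boot, length(par0),
                    dimnames = list(NULL, param_names(fit$family)))
  derived <- rep(NA_real_, n_boot)
  ok <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    k_star <- withr::with_seed(sub_seeds[b],
                               stats::rbinom(length(level), n, p_hat))
    refit <- tryCatch(
      fit_psychometric(aggregated_data(level, k_star, n),
                       family = fit$family, starts = starts),
      error = function(e) NULL)
    if (is.null(refit) || !refit$converged) next
    d <- tryCatch(derived_fn(refit), error = function(e) NA_real_)
    if (!is.finite(d)) next
    samples[b, ] <- refit$par
    derived[b] <- d
    ok[b] <- TRUE
  }
  n_failed <- sum(!ok)
  if (n_failed / n_boot > 0.05) {
    warning(sprintf("%d of %d bootstrap refits failed to converge",
                    n_failed, n_boot), call. = FALSE)
  }
  structure(list(samples = samples[ok, , drop = FALSE],
                 derived = derived[ok],
                 n_boot = n_boot, n_failed = n_failed,
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' Percentile bootstrap confidence interval
#'
#' The `(1 - level)/2` and `1 - (1 - level)/2` empirical percentiles of the
#' bootstrap distribution of the derived quantity, with linear
#' interpolation between order statistics.
#'
#' @param result A [parametric_bootstrap()] result (or any numeric vector).
#' @param level Confidence level; default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
percentile_ci <- function(result, level = 0.95) {
  x <- if (inherits(result, "bootstrap_result")) result$derived else result
  if (length(x) < 2) {
    stop("interval error: need at least 2 successful bootstrap samples",
         call. = FALSE)
  }
  alpha <- 1 - level
  q <- stats::quantile(x, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Bootstrap interval for the duration-based latency difference
#'
#' Combines the bootstrap PSE distributions of the two duration conditions:
#' samples are paired by index (truncating to the shorter vector — the two
#' fits are independent, so any pairing is valid and index pairing keeps
#' the computation deterministic), each pair mapped to
#' `(pse_avva* - pse_vaav*) / 4`, and the percentile interval of those
#' differences returned.
#'
#' @param boot_avva,boot_vaav [parametric_bootstrap()] results whose
#'   `derived` values are the condition PSEs.
#' @param level Confidence level; default 0.95.
#' @return Named numeric vector `c(lower, upper)` in seconds.
#' @export
duration_delta_l_ci <- function(boot_avva, boot_vaav, level = 0.95) {
  stopifnot(inherits(boot_avva, "bootstrap_result"),
            inherits(boot_vaav, "bootstrap_result"))
  m <- min(length(boot_avva$derived), length(boot_vaav$derived))
  if (m < 2) {
    stop("interval error: need at least 2 successful bootstrap samples",
         call. = FALSE)
  }
  diffs <- (boot_avva$derived[seq_len(m)] - boot_vaav$derived[seq_len(m)]) / 4
  percentile_ci(diffs, level)
}
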