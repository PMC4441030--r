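#' Latency-difference estimators
#'
#' Convert fitted psychometric curves into estimates of the perceptual
#' latency difference `delta_l = L_V - L_A` (seconds; positive = visual
#' latency longer).
#'
#' * `delta_l_from_toj()` — the asynchrony at which "V first" reports reach
#'   50%, i.e. the [pse()] of a four-parameter order-judgment fit.
#' * `delta_l_from_sj()` — the centre of the fitted simultaneity window
#'   (the point of subjective simultaneity).
#' * `delta_l_from_duration()` — the duration-based estimator
#'   `(pse_avva - pse_vaav) / 4`: with reversed-order variable intervals
#'   each condition shifts the matching duration by twice the latency
#'   difference in opposite directions, and any constant bias common to
#'   both conditions — in particular a time-order error from the standard
#'   always being presented first — cancels in the difference.
#' * `asymmetry_statistic()` — `(pse_avva - d) - (d - pse_vaav)`, the
#'   discrepancy between the two conditions' deviations from the standard
#'   `d`; zero when only a latency difference is at work, `2 * toe` under a
#'   pure time-order error.
#'
#' @param fit A converged `psychometric_fit` of the appropriate family.
#' @param pair A [duration_pair()].
#' @return Seconds.
#' @examples
#' delta_l_from_duration(duration_pair(0.7, 0.5, 0.6))  # 0.05
#' asymmetry_statistic(duration_pair(0.72, 0.54, 0.6))  # 0.06
#' @export
delta_l_from_toj <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"), fit$family == "toj4")
  pse(fit)
}

#' @rdname delta_l_from_toj
#' @export
delta_l_from_sj <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"), fit$family == "sj3")
  unname(fit$par["mu"])
}

#' The two duration-task points of subjective equality
#'
#' @param pse_avva PSE (s) of the AVVA condition (variable VA interval
#'   matching the AV standard).
#' @param pse_vaav PSE (s) of the VAAV condition.
#' @param standard The standard duration `d` in seconds.
#' @return An object of class `duration_pair`.
#' @export
duration_pair <- function(pse_avva, pse_vaav, standard) {
  stopifnot(is.finite(pse_avva), is.finite(pse_vaav),
            is.numeric(standard), standard > 0)
  structure(list(pse_avva = pse_avva, pse_vaav = pse_vaav,
                 standard = standard),
            class = "duration_pair")
}

#' @rdname delta_l_from_toj
#' @export
delta_l_from_duration <- function(pair) {
  stopifnot(inherits(pair, "duration_pair"))
  (pair$pse_avva - pair$pse_vaav) / 4
}

#' @rdname delta_l_from_toj
#' @export
asymmetry_statistic <- function(pair) {
  stopifnot(inherits(pair, "duration_pair"))
  (pair$pse_avva - pair$standard) - (pair$standard - pair$pse_vaav)
}

#' A latency-difference estimate with its confidence interval
#'
#' @param observer_id Observer label.
#' @param task_label One of `"TOJ"`, `"SJ"`, `"DUR_0.6"`, `"DUR_1.2"`.
#' @param delta_l Point estimate (s).
#' @param ci_low,ci_high 95% confidence bounds (s).
#' @return An object of class `latency_estimate`.
#' @export
latency_estimate <- function(observer_id, task_label, delta_l,
                             ci_low = NA_real_, ci_high = NA_real_) {
  task_label <- match.arg(task_label, c("TOJ", "SJ", "DUR_0.6", "DUR_1.2"))
  if (!is.na(ci_low) && !is.na(ci_high) &&
      !(ci_low <= delta_l && delta_l <= ci_high)) {
    stop("confidence interval must bracket the estimate", call. = FALSE)
  }
  structure(list(observer_id = observer_id, task_label = task_label,
                 delta_l = delta_l, ci_low = ci_low, ci_high = ci_high),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("%s %s: delta_l = %.1f ms [%.1f, %.1f]\n",
              x$observer_id, x$task_label, 1000 * x$delta_l,
              1000 * x$ci_low, 1000 * x$ci_high))
  invisible(x)
}
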