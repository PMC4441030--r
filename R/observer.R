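#' Ground-truth parameters of a synthetic observer
#'
#' Bundles the generative parameters of a simulated observer for the three
#' timing tasks.  The central quantity is `delta_l`, the true difference in
#' perceptual latency between the visual and the auditory stimulus
#' (`delta_l = L_V - L_A`, in seconds; positive means the visual stimulus is
#' perceived with the longer latency).  The same `delta_l` drives all three
#' tasks, so cross-task agreement holds by construction unless a
#' task-specific distortion (`toe`, `dur_order_bias`, lapses, reduced SJ
#' amplitude) is injected.
#'
#' @param delta_l True latency difference `L_V - L_A` in seconds.
#' @param sigma_toj SD (s) of the decision noise behind the temporal order
#'   judgment, i.e. the slope parameter of the cumulative normal.
#' @param gamma_toj Lower asymptote (lapse rate on the "A first" side) of the
#'   TOJ curve.
#' @param lambda_toj One minus the upper asymptote (lapse rate on the
#'   "V first" side).
#' @param sigma_sj SD (s) of the Gaussian simultaneity window.
#' @param amp_sj Peak probability of reporting "simultaneous".
#' @param sigma_dur SD (s) of the duration-comparison noise.
#' @param toe Time-order error in seconds: a constant perceived shortening
#'   (negative) or lengthening (positive) applied to the first of the two
#'   compared intervals.  Because the standard interval is always presented
#'   first, `toe` shifts both duration conditions equally and cancels in the
#'   duration-based latency estimator.
#' @param dur_order_bias Slope (s per s of standard duration) making the
#'   effective latency difference in the duration task depend on the
#'   standard's duration; `0` (the default) is the assumption under which the
#'   duration estimator is unbiased, nonzero values emulate a duration order
#'   bias.
#'
#' @return An object of class `observer_params`.
#' @examples
#' obs <- observer_params(delta_l = 0.05)
#' toj_probability(obs, 0.05)
#' @export
observer_params <- function(delta_l = 0.05,
                            sigma_toj = 0.07,
                            gamma_toj = 0.05,
                            lambda_toj = 0.05,
                            sigma_sj = 0.12,
                            amp_sj = 0.95,
                            sigma_dur = 0.1,
                            toe = 0,
                            dur_order_bias = 0) {
  obs <- list(
    delta_l = delta_l, sigma_toj = sigma_toj,
    gamma_toj = gamma_toj, lambda_toj = lambda_toj,
    sigma_sj = sigma_sj, amp_sj = amp_sj,
    sigma_dur = sigma_dur, toe = toe,
    dur_order_bias = dur_order_bias
  )
  for (nm in names(obs)) {
    if (!is.numeric(obs[[nm]]) || length(obs[[nm]]) != 1 || !is.finite(obs[[nm]])) {
      stop("observer parameter `", nm, "` must be a finite number", call. = FALSE)
    }
  }
  if (obs$gamma_toj < 0 || obs$lambda_toj < 0 ||
      obs$gamma_toj + obs$lambda_toj >= 1) {
    stop("lapse rates must satisfy gamma >= 0, lambda >= 0, gamma + lambda < 1",
         call. = FALSE)
  }
  if (obs$amp_sj <= 0 || obs$amp_sj > 1) {
    stop("amp_sj must lie in (0, 1]", call. = FALSE)
  }
  if (obs$sigma_toj <= 0 || obs$sigma_sj <= 0 || obs$sigma_dur <= 0) {
    stop("all sigma parameters must be positive", call. = FALSE)
  }
  structure(obs, class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Synthetic observer (delta_l =", format(x$delta_l), "s)\n")
  cat("  TOJ: sigma =", format(x$sigma_toj),
      " gamma =", format(x$gamma_toj), " lambda =", format(x$lambda_toj), "\n")
  cat("  SJ:  sigma =", format(x$sigma_sj), " amplitude =", format(x$amp_sj), "\n")
  cat("  DUR: sigma =", format(x$sigma_dur), " toe =", format(x$toe),
      " order bias =", format(x$dur_order_bias), "\n")
  invisible(x)
}

#' Published method-of-constant-stimuli designs
#'
#' Returns the stimulus grid used in the audiovisual study the package
#' emulates: 11 audiovisual asynchronies from -0.25 to 0.25 s in 0.05 s
#' steps with 20 trials per level (220 trials) for the order and
#' simultaneity tasks, and five variable durations per standard for the
#' duration task (standard 0.6 s: 0.3, 0.4, 0.5, 0.6, 0.8 s; standard
#' 1.2 s: 1.0, 1.2, 1.6, 2.0, 2.4 s).
#'
#' @param task One of `"TOJ"`, `"SJ"`, `"DURATION"`.
#' @param condition For the duration task, the interval order: `"AVVA"`
#'   (standard is auditory-then-visual) or `"VAAV"`.
#' @param standard For the duration task, the standard duration in seconds
#'   (0.6 or 1.2).
#' @param trials_per_level Trials at each stimulus level.
#'
#' @return An object of class `design_spec`: a list with `task`, `levels`,
#'   `trials_per_level` and, for the duration task, `condition` and
#'   `standard`.
#' @examples
#' default_design("TOJ")
#' default_design("DURATION", condition = "VAAV", standard = 1.2)
#' @export
default_design <- function(task = c("TOJ", "SJ", "DURATION"),
                           condition = NULL, standard = NULL,
                           trials_per_level = 20) {
  task <- match.arg(task)
  stopifnot(is.numeric(trials_per_level), length(trials_per_level) == 1,
            trials_per_level >= 1)
  trials_per_level <- as.integer(trials_per_level)
  if (task %in% c("TOJ", "SJ")) {
    return(new_design(task, seq(-0.25, 0.25, by = 0.05), trials_per_level))
  }
  if (is.null(condition) || is.null(standard)) {
    stop("invalid design: the duration task needs a condition and a standard",
         call. = FALSE)
  }
  condition <- match.arg(condition, c("AVVA", "VAAV"))
  levels <- if (isTRUE(all.equal(standard, 0.6))) {
    c(0.3, 0.4, 0.5, 0.6, 0.8)
  } else if (isTRUE(all.equal(standard, 1.2))) {
    c(1.0, 1.2, 1.6, 2.0, 2.4)
  } else {
    stop("invalid design: unsupported standard duration ", standard,
         " (use 0.6 or 1.2)", call. = FALSE)
  }
  new_design("DURATION", levels, trials_per_level,
             condition = condition, standard = standard)
}

#' Construct a design specification
#'
#' Lower-level constructor behind [default_design()], for non-default
#' stimulus grids.
#'
#' @param task Task name.
#' @param levels Strictly increasing stimulus levels in seconds
#'   (asynchronies for TOJ/SJ, variable durations for the duration task).
#' @param trials_per_level Trials per level (>= 1).
#' @param condition,standard Duration-task interval order and standard
#'   duration; must be given for `task = "DURATION"` and omitted otherwise.
#' @return A `design_spec` object.
#' @export
new_design <- function(task, levels, trials_per_level,
                       condition = NULL, standard = NULL) {
  task <- match.arg(task, c("TOJ", "SJ", "DURATION"))
  stopifnot(is.numeric(levels), length(levels) >= 1, !is.unsorted(levels, strictly = TRUE),
            trials_per_level >= 1)
  if (task == "DURATION") {
    if (is.null(condition) || is.null(standard) || standard <= 0) {
      stop("invalid design: duration designs carry one condition and one positive standard",
           call. = FALSE)
    }
    condition <- match.arg(condition, c("AVVA", "VAAV"))
  } else if (!is.null(condition) || !is.null(standard)) {
    stop("invalid design: condition/standard only apply to the duration task",
         call. = FALSE)
  }
  structure(
    list(task = task, levels = as.numeric(levels),
         trials_per_level = as.integer(trials_per_level),
         condition = condition, standard = standard),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design:", x$task)
  if (x$task == "DURATION") {
    cat(" (", x$condition, ", standard ", format(x$standard), " s)", sep = "")
  }
  cat("\n  levels (s):", paste(format(x$levels), collapse = ", "),
      "\n  trials per level:", x$trials_per_level, "\n")
  invisible(x)
}

#' True response probabilities of a synthetic observer
#'
#' `toj_probability()` gives the probability of reporting "V first" at
#' asynchrony `s = onset(A) - onset(V)` (so `s > 0` means the auditory
#' stimulus was presented after the visual one):
#' `gamma + (1 - gamma - lambda) * pnorm((s - delta_l) / sigma_toj)`.
#' `sj_probability()` gives the probability of reporting "simultaneous":
#' `amp_sj * exp(-(s - delta_l)^2 / (2 * sigma_sj^2))`, a scaled Gaussian
#' peaking at the true latency difference.
#' `duration_probability()` gives the probability of reporting the variable
#' interval longer than the standard, `pnorm((d_var - pse) / sigma_dur)`,
#' where the true point of subjective equality is
#' `standard + toe + 2 * delta_l_eff` for AVVA trials and
#' `standard + toe - 2 * delta_l_eff` for VAAV trials, with
#' `delta_l_eff = delta_l + dur_order_bias * standard`.  The factor 2
#' reflects the reversed-order variable interval: the latency difference
#' lengthens the perceived standard and shortens the perceived variable (or
#' vice versa), doubling the shift of the matching duration.
#'
#' @param obs An [observer_params()] object.
#' @param s Asynchrony/ies in seconds, `onset(A) - onset(V)`.
#' @param design A duration-task `design_spec` (for the condition and
#'   standard).
#' @param d_var Variable-interval duration(s) in seconds.
#' @return Probabilities, vectorised over `s` / `d_var`.
#' @examples
#' obs <- observer_params(delta_l = 0.05, toe = 0.03)
#' sj_probability(obs, c(-0.1, 0.05, 0.2))
#' d <- default_design("DURATION", condition = "AVVA", standard = 0.6)
#' duration_probability(obs, d, 0.73)  # 0.5: PSE = 0.6 + 0.03 + 0.1
#' @export
toj_probability <- function(obs, s) {
  stopifnot(inherits(obs, "observer_params"))
  obs$gamma_toj + (1 - obs$gamma_toj - obs$lambda_toj) *
    stats::pnorm((s - obs$delta_l) / obs$sigma_toj)
}

#' @rdname toj_probability
#' @export
sj_probability <- function(obs, s) {
  stopifnot(inherits(obs, "observer_params"))
  obs$amp_sj * exp(-(s - obs$delta_l)^2 / (2 * obs$sigma_sj^2))
}

#' @rdname toj_probability
#' @export
duration_probability <- function(obs, design, d_var) {
  stopifnot(inherits(obs, "observer_params"), inherits(design, "design_spec"),
            design$task == "DURATION")
  stats::pnorm((d_var - true_duration_pse(obs, design)) / obs$sigma_dur)
}

#' True PSE of the duration task under the generative model
#'
#' @inheritParams duration_probability
#' @return The variable duration perceived equal to the standard, in seconds.
#' @export
true_duration_pse <- function(obs, design) {
  stopifnot(inherits(obs, "observer_params"), inherits(design, "design_spec"),
            design$task == "DURATION")
  d <- design$standard
  delta_eff <- obs$delta_l + obs$dur_order_bias * d
  sign <- if (design$condition == "AVVA") 1 else -1
  d + obs$toe + sign * 2 * delta_eff
}

level_probability <- function(obs, design, levels) {
  switch(design$task,
         TOJ = toj_probability(obs, levels),
         SJ = sj_probability(obs, levels),
         DURATION = duration_probability(obs, design, levels))
}

#' Simulate trial-level responses
#'
#' Draws independent Bernoulli responses from the observer's true response
#' curve at every level of the design, `trials_per_level` trials each, and
#' shuffles the trial order (the behavioural sessions randomised
#' presentation order; downstream fits are order-free, but files look like
#' real sessions).  Identical inputs and seed reproduce the identical trial
#' table.
#'
#' @param obs An [observer_params()] object.
#' @param design A [default_design()] / [new_design()] object.
#' @param observer_id Observer label written into the table.
#' @param seed Integer seed for this simulation.
#' @return A tibble with one row per trial and columns `observer_id`,
#'   `task`, `condition`, `standard`, `level`, `response` (response coding:
#'   TOJ 1 = "V first", SJ 1 = "simultaneous", DURATION 1 = "variable
#'   longer").
#' @examples
#' trials <- simulate_trials(observer_params(), default_design("TOJ"),
#'                           "o1", seed = 1)
#' nrow(trials)  # 220
#' @export
simulate_trials <- function(obs, design, observer_id, seed) {
  stopifnot(inherits(obs, "observer_params"), inherits(design, "design_spec"),
            is.character(observer_id), length(observer_id) == 1)
  p <- level_probability(obs, design, design$levels)
  n_lev <- length(design$levels)
  m <- design$trials_per_level
  withr::with_seed(as.integer(seed), {
    resp <- stats::rbinom(n_lev * m, size = 1, prob = rep(p, each = m))
    ord <- sample.int(n_lev * m)
  })
  out <- tibble::tibble(
    observer_id = observer_id,
    task = design$task,
    condition = if (is.null(design$condition)) NA_character_ else design$condition,
    standard = if (is.null(design$standard)) NA_real_ else design$standard,
    level = rep(design$levels, each = m),
    response = as.integer(resp)
  )
  out[ord, ]
}

#' Draw a cohort of synthetic observers
#'
#' Samples `n` observers whose true latency differences are uniform on
#' `delta_l_range`; all other generative parameters are shared and taken
#' from `...` (passed to [observer_params()]).
#'
#' @param n Number of observers.
#' @param delta_l_range Range (s) of the uniform distribution of true
#'   latency differences across observers.
#' @param seed Integer seed.
#' @param ... Further arguments to [observer_params()].
#' @return A named list of `observer_params`, names `"obs01"`, `"obs02"`, ...
#' @export
sample_cohort <- function(n, delta_l_range = c(-0.1, 0.1), seed, ...) {
  stopifnot(n >= 1, length(delta_l_range) == 2)
  dl <- withr::with_seed(as.integer(seed),
                         stats::runif(n, delta_l_range[1], delta_l_range[2]))
  obs <- lapply(dl, function(d) observer_params(delta_l = d, ...))
  names(obs) <- sprintf("obs%02d", seq_len(n))
  obs
}
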