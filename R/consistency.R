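#' Pearson correlation with a bootstrap confidence interval
#'
#' Sample Pearson correlation between per-observer estimates, with a
#' percentile bootstrap confidence interval from resampling observer
#' indices with replacement, and a classical two-sided p value from the t
#' transform `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df (small-sample
#' studies in this literature report both: the t-based p and the bootstrap
#' interval).
#'
#' @param x,y Equal-length numeric vectors (>= 3, non-constant).
#' @param n_boot Bootstrap resamples; default 1000.
#' @param seed Integer seed.
#' @param level Confidence level; default 0.95.
#' @return List with `r`, `ci` (`c(lower, upper)`), `t`, `df`, `p`.
#' @examples
#' pearson_r_boot(c(1, 2, 3, 4), c(1, 3, 2, 4), n_boot = 200, seed = 1)$r  # 0.8
#' @export
pearson_r_boot <- function(x, y, n_boot = 1000, seed, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: an input vector is constant", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  n <- length(x)
  rs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) NA_real_
      else stats::cor(x[idx], y[idx])
    }, numeric(1))
  })
  rs <- rs[is.finite(rs)]
  list(r = unname(ct$estimate),
       ci = percentile_ci(rs, level),
       t = unname(ct$statistic),
       df = n - 2L,
       p = ct$p.value)
}

#' One-sample and paired t tests on latency estimates
#'
#' Thin wrappers around [stats::t.test()] returning the two-sided statistic,
#' degrees of freedom and p value.  `paired_t(a, b)` is the one-sample test
#' of the differences `a - b` against zero.
#'
#' @param values Numeric vector (length >= 2, non-degenerate).
#' @param mu0 Null value; default 0.
#' @param a,b Paired vectors of equal length.
#' @return List with `t`, `df`, `p`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  stopifnot(length(values) >= 2)
  if (stats::sd(values) == 0) {
    stop("degenerate test: sample has zero variance", call. = FALSE)
  }
  tt <- stats::t.test(values, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' @rdname one_sample_t
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  one_sample_t(a - b, mu0 = 0)
}

#' Confidence-interval non-overlap criterion
#'
#' Declares two estimates different when their 95% confidence intervals are
#' disjoint; touching endpoints count as overlap.  For two independent 95%
#' intervals this is a conservative test (roughly p < .006).
#'
#' @param e1,e2 [latency_estimate()] objects with finite CI bounds.
#' @return `TRUE` iff the intervals do not intersect.
#' @export
ci_nonoverlap <- function(e1, e2) {
  stopifnot(inherits(e1, "latency_estimate"), inherits(e2, "latency_estimate"),
            is.finite(e1$ci_low), is.finite(e1$ci_high),
            is.finite(e2$ci_low), is.finite(e2$ci_high))
  e1$ci_high < e2$ci_low || e2$ci_high < e1$ci_low
}

#' Cross-task consistency battery
#'
#' The cross-observer comparison of latency-difference estimates: for every
#' unordered pair of task labels present, the Pearson correlation with
#' bootstrap CI and t-based p value, plus the count of observers whose 95%
#' intervals for the two tasks do not overlap; for every task, the
#' one-sample t test of the estimates against zero; and, when both duration
#' standards are present, the paired t test across standards.  Observers
#' missing an estimate for a task are excluded per comparison (pairwise, not
#' listwise) and listed in `excluded`.
#'
#' No multiple-testing correction is applied; `n_comparisons` is reported so
#' users can correct post hoc.
#'
#' @param estimates A tibble with columns `observer_id`, `task_label`,
#'   `delta_l`, `ci_low`, `ci_high` (seconds), one row per observer x task —
#'   see [estimates_table()].
#' @param n_boot Bootstrap resamples for correlation CIs; default 1000.
#' @param seed Integer seed.
#' @return A list of class `consistency_report` with tibbles `pairwise`
#'   (`pair_label`, `r`, `r_ci_low`, `r_ci_high`, `t`, `df`, `p`,
#'   `n_disagree`, `n_observers`, `excluded`), `task_tests` (one-sample t vs
#'   0 per task) and `paired_standards` (paired t across duration
#'   standards, when available), plus `n_comparisons`.
#' @export
consistency_battery <- function(estimates, n_boot = 1000, seed) {
  stopifnot(all(c("observer_id", "task_label", "delta_l", "ci_low", "ci_high")
                %in% names(estimates)))
  tasks <- intersect(c("TOJ", "SJ", "DUR_0.6", "DUR_1.2"),
                     unique(estimates$task_label))
  get_task <- function(tl) estimates[estimates$task_label == tl, ]
  pairs <- utils::combn(tasks, 2, simplify = FALSE)
  pairwise <- lapply(seq_along(pairs), function(i) {
    t1 <- get_task(pairs[[i]][1]); t2 <- get_task(pairs[[i]][2])
    common <- intersect(t1$observer_id, t2$observer_id)
    excluded <- setdiff(union(t1$observer_id, t2$observer_id), common)
    t1 <- t1[match(common, t1$observer_id), ]
    t2 <- t2[match(common, t2$observer_id), ]
    if (length(common) < 3) {
      stop("consistency error: need >= 3 observers with estimates for ",
           pairs[[i]][1], " and ", pairs[[i]][2], call. = FALSE)
    }
    pr <- pearson_r_boot(t1$delta_l, t2$delta_l, n_boot = n_boot,
                         seed = as.integer(seed) + i)
    n_disagree <- sum(vapply(seq_along(common), function(j) {
      ci_nonoverlap(
        latency_estimate(common[j], pairs[[i]][1], t1$delta_l[j],
                         t1$ci_low[j], t1$ci_high[j]),
        latency_estimate(common[j], pairs[[i]][2], t2$delta_l[j],
                         t2$ci_low[j], t2$ci_high[j]))
    }, logical(1)))
    tibble::tibble(
      pair_label = paste0(pairs[[i]][1], "-vs-", pairs[[i]][2]),
      r = pr$r, r_ci_low = pr$ci[1], r_ci_high = pr$ci[2],
      t = pr$t, df = pr$df, p = pr$p,
      n_disagree = n_disagree, n_observers = length(common),
      excluded = paste(excluded, collapse = ";"))
  })
  task_tests <- lapply(tasks, function(tl) {
    v <- get_task(tl)$delta_l
    tt <- one_sample_t(v, 0)
    tibble::tibble(task_label = tl, mean_delta_l = mean(v),
                   t = tt$t, df = tt$df, p = tt$p, n_observers = length(v))
  })
  paired_standards <- NULL
  if (all(c("DUR_0.6", "DUR_1.2") %in% tasks)) {
    a <- get_task("DUR_0.6"); b <- get_task("DUR_1.2")
    common <- intersect(a$observer_id, b$observer_id)
    if (length(common) >= 2) {
      tt <- paired_t(a$delta_l[match(common, a$observer_id)],
                     b$delta_l[match(common, b$observer_id)])
      paired_standards <- tibble::tibble(
        pair_label = "DUR_0.6-vs-DUR_1.2-paired",
        t = tt$t, df = tt$df, p = tt$p, n_observers = length(common))
    }
  }
  structure(
    list(pairwise = dplyr::bind_rows(pairwise),
         task_tests = dplyr::bind_rows(task_tests),
         paired_standards = paired_standards,
         n_comparisons = length(pairs) + length(tasks) +
           as.integer(!is.null(paired_standards))),
    class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("Cross-task consistency (", x$n_comparisons, " comparisons)\n", sep = "")
  print(x$pairwise)
  print(x$task_tests)
  if (!is.null(x$paired_standards)) print(x$paired_standards)
  invisible(x)
}

#' Assemble an estimates table from latency_estimate objects
#'
#' @param estimates A list of [latency_estimate()] objects.
#' @return A tibble with columns `observer_id`, `task_label`, `delta_l`,
#'   `ci_low`, `ci_high`.
#' @export
estimates_table <- function(estimates) {
  stopifnot(all(vapply(estimates, inherits, logical(1), "latency_estimate")))
  dplyr::bind_rows(lapply(estimates, function(e) {
    tibble::tibble(observer_id = e$observer_id, task_label = e$task_label,
                   delta_l = e$delta_l, ci_low = e$ci_low, ci_high = e$ci_high)
  }))
}
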