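#' Read and write trial-level CSV files
#'
#' The on-disk trial format is a CSV with header
#' `observer_id,task,condition,standard,level,response`; `condition` and
#' `standard` are empty for the order and simultaneity tasks, levels are in
#' seconds, responses are 0/1.  `read_trials()` validates every row and
#' reports the first offending line by number; when a `design` is supplied
#' it additionally rejects levels absent from that design's grid.
#'
#' @param path File path.
#' @param design Optional `design_spec` to validate levels against.
#' @param trials A trial tibble ([simulate_trials()]).
#' @return `read_trials()`: a trial tibble; `write_trials()`: `path`,
#'   invisibly.
#' @export
read_trials <- function(path, design = NULL) {
  if (!file.exists(path)) stop("parse error: file not found: ", path, call. = FALSE)
  expected <- c("observer_id", "task", "condition", "standard", "level",
                "response")
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("parse error: empty file: ", path, call. = FALSE)
  header <- strsplit(first, ",")[[1]]
  if (!identical(header, expected)) {
    stop("parse error: header must be `", paste(expected, collapse = ","), "`",
         call. = FALSE)
  }
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      observer_id = readr::col_character(),
      task = readr::col_character(),
      condition = readr::col_character(),
      standard = readr::col_double(),
      level = readr::col_double(),
      response = readr::col_integer()
    ))
  if (nrow(trials) == 0) stop("parse error: no trial rows in ", path, call. = FALSE)
  line <- function(i) i + 1L  # header occupies line 1
  bad <- which(!trials$task %in% c("TOJ", "SJ", "DURATION"))
  if (length(bad)) stop("parse error: unknown task at line ", line(bad[1]),
                        call. = FALSE)
  bad <- which(!trials$response %in% c(0L, 1L) | is.na(trials$response))
  if (length(bad)) stop("parse error: response must be 0 or 1 at line ",
                        line(bad[1]), call. = FALSE)
  bad <- which(!is.finite(trials$level))
  if (length(bad)) stop("parse error: missing level at line ", line(bad[1]),
                        call. = FALSE)
  bad <- which(trials$task == "DURATION" &
                 (is.na(trials$condition) | is.na(trials$standard)))
  if (length(bad)) stop("parse error: duration trial without condition/standard at line ",
                        line(bad[1]), call. = FALSE)
  bad <- which(!is.na(trials$condition) & !trials$condition %in% c("AVVA", "VAAV"))
  if (length(bad)) stop("parse error: unknown condition at line ", line(bad[1]),
                        call. = FALSE)
  if (!is.null(design)) {
    stopifnot(inherits(design, "design_spec"))
    ok <- vapply(trials$level,
                 function(l) any(abs(l - design$levels) < 1e-9), logical(1))
    if (any(!ok)) stop("parse error: level not in the declared design at line ",
                       line(which(!ok)[1]), call. = FALSE)
  }
  trials
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(c("observer_id", "task", "condition", "standard", "level",
                  "response") %in% names(trials)))
  readr::write_csv(trials[, c("observer_id", "task", "condition", "standard",
                              "level", "response")], path)
  invisible(path)
}
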