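#' Two-arm survival dataset
#'
#' Construct a validated two-arm time-to-event dataset. This is the container
#' every other operation in the package consumes: one row per subject with an
#' observed follow-up time, an event indicator (1 = death/event observed,
#' 0 = censored) and an arm label (`"experimental"` or `"control"`).
#'
#' Row order is preserved and meaningful: deterministic tie-breaking in
#' survivor selection (see [best_survivor_index()]) falls back on original
#' row position.
#'
#' @param time Numeric vector of nonnegative follow-up times (months or
#'   abstract time units).
#' @param event Event indicator; logical or 0/1 numeric. 1/`TRUE` means the
#'   event was observed, 0/`FALSE` means the subject was censored.
#' @param arm Character or factor with values `"experimental"` / `"control"`.
#' @param label Free-text label for the dataset (trial name etc.).
#' @return An object of class `survival_dataset`: a `data.frame` with columns
#'   `time`, `event`, `arm` and an attribute `label`.
#' @examples
#' d <- survival_dataset(c(1, 2, 3), c(1, 0, 1),
#'                       c("experimental", "control", "control"))
#' summary(d)
#' @export
survival_dataset <- function(time, event, arm, label = "") {
  time <- as.numeric(time)
  if (is.logical(event)) event <- as.integer(event)
  event <- as.integer(event)
  arm <- as.character(arm)
  n <- length(time)
  if (length(event) != n || length(arm) != n)
    stop("time, event and arm must have equal length")
  bad <- which(is.na(time) | time < 0)
  if (length(bad))
    stop("negative or missing follow-up time in row(s): ",
         paste(bad, collapse = ", "))
  if (!all(event %in% c(0L, 1L)))
    stop("event must be coded 0/1 (or FALSE/TRUE)")
  if (!all(arm %in% c("experimental", "control")))
    stop("arm must be 'experimental' or 'control'; use read_ipd() to map ",
         "trial-specific labels")
  out <- data.frame(time = time, event = event, arm = arm,
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_dataset", "data.frame")
  attr(out, "label") <- as.character(label)
  out
}

#' @export
print.survival_dataset <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Two-arm survival dataset",
      if (nzchar(lab)) paste0(" '", lab, "'"), "\n", sep = "")
  for (a in c("experimental", "control")) {
    sel <- x$arm == a
    cat(sprintf("  %-12s n = %4d, events = %4d, censored = %4d\n",
                a, sum(sel), sum(x$event[sel]), sum(sel) - sum(x$event[sel])))
  }
  invisible(x)
}

#' @export
summary.survival_dataset <- function(object, ...) {
  print(object)
  cat(sprintf("  follow-up: median %.3g, max %.3g\n",
              stats::median(object$time), max(object$time)))
  invisible(object)
}

# Both arms populated: required before any log-rank based operation.
assert_testable <- function(data) {
  stopifnot(inherits(data, "survival_dataset") || is.data.frame(data))
  if (!all(c("time", "event", "arm") %in% names(data)))
    stop("dataset must have columns time, event, arm")
  if (!any(data$arm == "experimental") || !any(data$arm == "control"))
    stop("both arms must be non-empty")
  invisible(data)
}

#' Read individual patient data from a delimited text file
#'
#' Reads a CSV (or other delimited) file with one row per subject and maps its
#' columns onto the `time` / `event` / `arm` schema. Event status is parsed
#' from `{0, 1, TRUE, FALSE}` (case-insensitive). Arm labels are arbitrary;
#' when they are not already `"experimental"` / `"control"`, the
#' `experimental` argument names which label is the experimental arm and the
#' other is mapped to control.
#'
#' @param path Path to the file.
#' @param columns Named list mapping the roles `time`, `event`, `arm` to
#'   column names in the file. Defaults to identity.
#' @param experimental Optional: the arm label (as written in the file) to be
#'   treated as the experimental arm.
#' @param sep Field separator (default comma).
#' @param label Dataset label; defaults to the file name.
#' @return A [survival_dataset()].
#' @export
read_ipd <- function(path,
                     columns = list(time = "time", event = "event",
                                    arm = "arm"),
                     experimental = NULL, sep = ",", label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (role in c("time", "event", "arm")) {
    cn <- columns[[role]]
    if (is.null(cn) || !cn %in% names(raw))
      stop("format error: missing column for '", role, "' (expected '",
           if (is.null(cn)) role else cn, "')")
  }
  time <- raw[[columns$time]]
  ev_raw <- tolower(trimws(as.character(raw[[columns$event]])))
  ev_map <- c("0" = 0L, "1" = 1L, "false" = 0L, "true" = 1L)
  if (!all(ev_raw %in% names(ev_map)))
    stop("format error: event values must be in {0, 1, TRUE, FALSE}")
  event <- unname(ev_map[ev_raw])
  arm <- as.character(raw[[columns$arm]])
  labels <- unique(arm)
  if (length(labels) > 2)
    stop("more than two arm labels found: ", paste(labels, collapse = ", "))
  if (!all(labels %in% c("experimental", "control"))) {
    if (is.null(experimental))
      stop("arm labels ", paste(sQuote(labels), collapse = ", "),
           " are not 'experimental'/'control'; pass `experimental=` to map")
    if (!experimental %in% labels)
      stop("experimental label '", experimental, "' not present in file")
    arm <- ifelse(arm == experimental, "experimental", "control")
  }
  survival_dataset(time, event, arm,
                   label = if (is.null(label)) basename(path) else label)
}

#' Write individual patient data to CSV
#'
#' Writes the dataset as UTF-8 CSV with header `time,event,arm` and full
#' floating-point precision, so that `read_ipd(write_ipd(d))` round-trips
#' exactly.
#'
#' @param data A [survival_dataset()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ipd <- function(data, path) {
  assert_ipd_columns(data)
  for (a in c("experimental", "control"))
    if (!any(data$arm == a))
      warning("arm '", a, "' is empty; file written anyway")
  out <- data.frame(time = sprintf("%.17g", data$time),
                    event = data$event, arm = data$arm)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

assert_ipd_columns <- function(data) {
  if (!all(c("time", "event", "arm") %in% names(data)))
    stop("dataset must have columns time, event, arm")
  invisible(data)
}
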