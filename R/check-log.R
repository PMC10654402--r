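#' @title Specification check log
#' @description A check log is an ordered record of the outcomes of the
#'   SWC specification checks. Each entry carries the check identifier,
#'   a severity (\code{"error"}, \code{"warning"} or \code{"info"}), a
#'   human-readable message, the affected data-line numbers, and whether
#'   the entry records a correction that altered file content.
#' @name check_log
NULL

#' Names of the specification checks, in execution order
#'
#' The eleven checks of the standardization battery, in the order in which
#' they are executed. Two additional identifiers (\code{"File Encoding"},
#' \code{"Comment Placement"}) are used by the reader for conditions that
#' arise before the battery proper starts.
#'
#' @return Character vector of check identifiers.
#' @export
swc_check_ids <- function() {
  c("Missing Field",
    "Number of Lines",
    "Number of Soma Samples",
    "Invalid Parent",
    "Index/Parent Integer",
    "XYZ Double",
    "Radius Positive Double",
    "Non-Standard Type",
    "Sequential Index",
    "Sorted Order",
    "Soma Contours")
}

.log_extra_ids <- c("File Encoding", "Comment Placement")

#' Create an empty check log
#'
#' @return An object of class \code{swc_check_log}: a data frame with
#'   columns \code{check_id}, \code{severity}, \code{message},
#'   \code{lines} (a list column of integer vectors) and
#'   \code{corrective} (logical; \code{TRUE} when the entry records a
#'   change to file content).
#' @export
check_log <- function() {
  structure(
    data.frame(check_id = character(0), severity = character(0),
               message = character(0), corrective = logical(0),
               stringsAsFactors = FALSE),
    lines = list(),
    class = c("swc_check_log", "data.frame")
  )
}

# internal: append one entry; `lines` are data-line numbers in the source
log_add <- function(log, check_id, severity, message,
                    lines = integer(0), corrective = FALSE) {
  stopifnot(check_id %in% c(swc_check_ids(), .log_extra_ids),
            severity %in% c("error", "warning", "info"))
  entry <- data.frame(check_id = check_id, severity = severity,
                      message = message, corrective = corrective,
                      stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(log), entry)
  attr(out, "lines") <- c(attr(log, "lines"), list(as.integer(lines)))
  class(out) <- c("swc_check_log", "data.frame")
  out
}

# internal: concatenate two logs preserving order
log_cat <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  attr(out, "lines") <- c(attr(a, "lines"), attr(b, "lines"))
  class(out) <- c("swc_check_log", "data.frame")
  out
}

#' Does a check log contain errors?
#' @param log An \code{swc_check_log}.
#' @return Logical scalar.
#' @export
has_errors <- function(log) any(log$severity == "error")

# internal: did any entry alter file content?
has_corrections <- function(log) any(log$corrective)

# internal: a "Missing Field"/"Number of Lines" error aborts the battery
is_terminal <- function(log) {
  any(log$severity == "error" &
        log$check_id %in% c("Missing Field", "Number of Lines"))
}

#' Format a check log as text lines
#'
#' One line per entry: \code{[severity] check id: message (lines ...)}.
#' This is the per-file log emitted by the command-line interface.
#'
#' @param log An \code{swc_check_log}.
#' @return Character vector, one element per entry.
#' @export
format_check_log <- function(log) {
  if (nrow(log) == 0) return("all checks passed")
  lns <- attr(log, "lines")
  vapply(seq_len(nrow(log)), function(i) {
    suffix <- if (length(lns[[i]]) > 0)
      paste0(" (lines ", paste(lns[[i]], collapse = ","), ")") else ""
    sprintf("[%s] %s: %s%s", log$severity[i], log$check_id[i],
            log$message[i], suffix)
  }, character(1))
}

#' @export
print.swc_check_log <- function(x, ...) {
  cat(format_check_log(x), sep = "\n")
  invisible(x)
}
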