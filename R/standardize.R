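#' @title SWC standardization battery
#'
#' @description The standardization battery runs an ordered sequence of
#'   specification checks over a morphology and, in repair mode, applies
#'   the corresponding corrections: shape checks (column count, line
#'   count, presence of soma samples), invalid-parent repair,
#'   index/parent integer coercion, coordinate and radius coercion, type
#'   normalization, topological re-sorting with renumbering, and soma
#'   contour replacement. The order is fixed; a "Missing Field" or
#'   "Number of Lines" error is terminal and aborts the battery.
#' @name standardize-battery
NULL

.int_rx <- "^[+-]?[0-9]+$"

# internal: note appended to the footer when a default value is inserted
footer_note <- function(field, line, value) {
  sprintf("# swcforge-note: %s at original line %d set to %s",
          field, line, value)
}

# internal: original data-line number of row i (for log messages)
row_line <- function(m, i) {
  if (!is.null(m$raw_lines) && length(m$raw_lines) >= i) m$raw_lines[i]
  else i
}

#' Shape checks: column count, line count, soma presence
#'
#' Errors if any raw data row does not have exactly seven fields
#' (terminal: all further checks are omitted) or if there are no data
#' rows at all; warns if there are fewer than 20 data rows or if no soma
#' (type 1) samples are present. Never mutates.
#'
#' @param m An \code{swc_morphology} as returned by \code{\link{read_swc}}.
#' @return A list \code{(morphology, log)}.
#' @export
check_shape <- function(m) {
  log <- check_log()
  nrows <- n_samples(m)
  if (nrows == 0) {
    log <- log_add(log, "Number of Lines", "error", "no samples detected")
    return(list(morphology = m, log = log))
  }
  if (!is.null(m$raw)) {
    lens <- lengths(m$raw)
    bad <- which(lens != 7L)
    if (length(bad) > 0) {
      log <- log_add(log, "Missing Field", "error",
                     sprintf("%d row(s) do not have seven fields", length(bad)),
                     lines = vapply(bad, function(i) row_line(m, i), numeric(1)))
      return(list(morphology = m, log = log))
    }
  }
  if (nrows < 20)
    log <- log_add(log, "Number of Lines", "warning",
                   sprintf("fewer than 20 lines (%d); check file integrity",
                           nrows))
  types <- suppressWarnings(as.numeric(token_matrix(m)[, 2]))
  if (!any(!is.na(types) & types == 1))
    log <- log_add(log, "Number of Soma Samples", "warning",
                   "no soma samples detected")
  list(morphology = m, log = log)
}

#' Repair parents that point to nonexistent indices
#'
#' Every parent field referencing an index value that does not exist in
#' the file (including a sample naming itself as parent) is rewritten to
#' \code{-1}, turning that sample into a root, with one warning per
#' affected line.
#'
#' @param m An \code{swc_morphology}.
#' @return A list \code{(morphology, log)}.
#' @export
fix_invalid_parents <- function(m) {
  log <- check_log()
  mat <- token_matrix(m)
  if (nrow(mat) == 0) return(list(morphology = m, log = log))
  idx <- suppressWarnings(as.numeric(mat[, 1]))
  par <- suppressWarnings(as.numeric(mat[, 7]))
  known <- idx[!is.na(idx)]
  bad <- which(!is.na(par) & par != -1 &
                 (!(par %in% known) | (!is.na(idx) & par == idx)))
  for (i in bad) {
    log <- log_add(log, "Invalid Parent", "warning",
                   sprintf("parent %s does not exist; sample made a root point",
                           mat[i, 7]),
                   lines = row_line(m, i), corrective = TRUE)
    mat[i, 7] <- "-1"
  }
  if (length(bad) > 0) m <- set_tokens(m, mat)
  list(morphology = m, log = log)
}

#' Coerce index and parent fields to integer format
#'
#' Float-formatted integers such as \code{"1.00"} are reformatted as
#' integers (informational). Non-integer values (\code{"1.34"}) or
#' non-numerical entries (\code{"abc"}) generate an error; such files are
#' not repairable at the row level.
#'
#' @param m An \code{swc_morphology}.
#' @return A list \code{(morphology, log)}.
#' @export
coerce_index_parent <- function(m) {
  log <- check_log()
  mat <- token_matrix(m)
  changed <- FALSE
  for (col in c(1L, 7L)) {
    field <- if (col == 1L) "index" else "parent"
    for (i in seq_len(nrow(mat))) {
      tok <- mat[i, col]
      if (grepl(.int_rx, tok)) next
      v <- suppressWarnings(as.numeric(tok))
      if (!is.na(v) && is.finite(v) && v == round(v)) {
        mat[i, col] <- fmt_swc_int(v)
        changed <- TRUE
        log <- log_add(log, "Index/Parent Integer", "info",
                       sprintf("float-formatted %s '%s' reformatted as integer",
                               field, tok),
                       lines = row_line(m, i), corrective = TRUE)
      } else {
        log <- log_add(log, "Index/Parent Integer", "error",
                       sprintf("%s field '%s' is not an integer", field, tok),
                       lines = row_line(m, i))
      }
    }
  }
  if (changed) m <- set_tokens(m, mat)
  list(morphology = m, log = log)
}

#' Coerce x, y, z coordinates to numeric, defaulting NaN/NA to 0.0
#'
#' Any coordinate field that does not parse as a finite number (NaN, NA
#' in any capitalization, or a non-numeric token) is set to \code{0.0}
#' with a warning, and a footer note records the inserted value.
#'
#' @param m An \code{swc_morphology}.
#' @return A list \code{(morphology, log)}.
#' @export
coerce_coordinates <- function(m) {
  log <- check_log()
  mat <- token_matrix(m)
  fields <- c("x", "y", "z")
  changed <- FALSE
  for (k in 1:3) {
    col <- 2L + k
    v <- suppressWarnings(as.numeric(mat[, col]))
    bad <- which(is.na(v) | is.nan(v))
    for (i in bad) {
      log <- log_add(log, "XYZ Double", "warning",
                     sprintf("%s value '%s' treated as 0.0; check file integrity",
                             fields[k], mat[i, col]),
                     lines = row_line(m, i), corrective = TRUE)
      m$footer <- c(m$footer, footer_note(fields[k], row_line(m, i), "0.0"))
      mat[i, col] <- "0.0"
      changed <- TRUE
    }
  }
  if (changed) m <- set_tokens(m, mat)
  list(morphology = m, log = log)
}

#' Coerce the radius field to a positive double, defaulting to 0.5
#'
#' A radius that is negative, zero, NaN, NA or non-numeric is set to
#' \code{0.5} with a warning, and a footer note records the inserted
#' value.
#'
#' @param m An \code{swc_morphology}.
#' @return A list \code{(morphology, log)}.
#' @export
coerce_radius <- function(m) {
  log <- check_log()
  mat <- token_matrix(m)
  v <- suppressWarnings(as.numeric(mat[, 6]))
  bad <- which(is.na(v) | is.nan(v) | !is.finite(v) | v <= 0)
  changed <- FALSE
  for (i in bad) {
    log <- log_add(log, "Radius Positive Double", "warning",
                   sprintf("radius '%s' set to 0.5; check file integrity",
                           mat[i, 6]),
                   lines = row_line(m, i), corrective = TRUE)
    m$footer <- c(m$footer, footer_note("radius", row_line(m, i), "0.5"))
    mat[i, 6] <- "0.5"
    changed <- TRUE
  }
  if (changed) m <- set_tokens(m, mat)
  list(morphology = m, log = log)
}

#' Normalize the type field
#'
#' Float-formatted integer types are reformatted (informational);
#' non-integer or non-numerical types become type 0, "undefined"
#' (warning). At bifurcation and terminal points, types 5 and 6 -- used
#' by some tracing software as topology markers rather than structural
#' domains -- are replaced by the parent's type. Custom types above 7 are
#' treated as standard and left untouched with an informational note.
#'
#' @param m An \code{swc_morphology} with valid index/parent fields.
#' @return A list \code{(morphology, log)}.
#' @export
normalize_types <- function(m) {
  log <- check_log()
  mat <- token_matrix(m)
  changed <- FALSE
  for (i in seq_len(nrow(mat))) {
    tok <- mat[i, 2]
    if (grepl(.int_rx, tok)) next
    v <- suppressWarnings(as.numeric(tok))
    if (!is.na(v) && is.finite(v) && v == round(v)) {
      mat[i, 2] <- fmt_swc_int(v)
      log <- log_add(log, "Non-Standard Type", "info",
                     sprintf("float-formatted type '%s' reformatted as integer",
                             tok),
                     lines = row_line(m, i), corrective = TRUE)
    } else {
      mat[i, 2] <- "0"
      log <- log_add(log, "Non-Standard Type", "warning",
                     sprintf("type '%s' changed to 0 ('undefined')", tok),
                     lines = row_line(m, i), corrective = TRUE)
    }
    changed <- TRUE
  }

  # topology-marker repair needs resolvable parents
  idx <- suppressWarnings(as.numeric(mat[, 1]))
  par <- suppressWarnings(as.numeric(mat[, 7]))
  typ <- suppressWarnings(as.numeric(mat[, 2]))
  if (!any(is.na(idx)) && !any(is.na(par))) {
    ppos <- match(par, idx)
    kids <- tabulate(ppos[!is.na(ppos) & par != -1], nbins = nrow(mat))
    for (i in seq_len(nrow(mat))) {
      at_bif_or_term <- kids[i] >= 2 || kids[i] == 0
      if (!at_bif_or_term || is.na(typ[i]) || !(typ[i] %in% c(5, 6))) next
      if (par[i] == -1 || is.na(ppos[i])) next
      ptype <- mat[ppos[i], 2]
      if (ptype != mat[i, 2]) {
        log <- log_add(log, "Non-Standard Type", "warning",
                       sprintf("type %s at %s reset to parent type %s",
                               mat[i, 2],
                               if (kids[i] == 0) "terminal" else "bifurcation",
                               ptype),
                       lines = row_line(m, i), corrective = TRUE)
        mat[i, 2] <- ptype
        changed <- TRUE
      }
    }
    big <- which(!is.na(typ) & typ > 7)
    if (length(big) > 0)
      log <- log_add(log, "Non-Standard Type", "info",
                     "custom types above 7 present; retained as user-defined",
                     lines = vapply(big, function(i) row_line(m, i),
                                    numeric(1)))
  }
  if (changed) m <- set_tokens(m, mat)
  list(morphology = m, log = log)
}

# ---- sorting / renumbering --------------------------------------------

# internal: deterministic pre-order resort of a numeric sample table.
# Children are visited in original row order; roots in original row
# order. Returns list(samples, order, seq_bad, order_bad, cycle_rows).
resort_samples <- function(s) {
  n <- nrow(s)
  ppos <- match(s$parent, s$index)
  roots <- which(s$parent == -1)
  seq_bad <- !all(s$index == seq_len(n))
  # standard order: first row is a root, every parent in an earlier row
  order_bad <- s$parent[1] != -1
  nonroot <- which(s$parent != -1)
  if (any(ppos[nonroot] >= nonroot, na.rm = TRUE)) order_bad <- TRUE

  children <- vector("list", n)
  for (i in nonroot) {
    p <- ppos[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  visit_order <- integer(0)
  visited <- logical(n)
  dfs_from <- function(start, visit_order) {
    stack <- start
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (visited[cur]) next
      visited[cur] <<- TRUE
      visit_order <- c(visit_order, cur)
      kids <- children[[cur]]
      if (length(kids) > 0) stack <- c(stack, rev(kids))
    }
    visit_order
  }
  for (r in roots) visit_order <- dfs_from(r, visit_order)
  cycle_rows <- integer(0)
  while (any(!visited)) {
    # rows unreachable from any root form parent cycles; break the cycle
    # at the first unvisited row (it becomes a root)
    first <- which(!visited)[1]
    cycle_rows <- c(cycle_rows, first)
    s$parent[first] <- -1
    visit_order <- dfs_from(first, visit_order)
  }
  new_index <- integer(n)
  new_index[visit_order] <- seq_len(n)
  out <- s[visit_order, , drop = FALSE]
  out$index <- seq_len(n)
  out$parent <- ifelse(out$parent == -1, -1,
                       new_index[ppos[visit_order]])
  rownames(out) <- NULL
  list(samples = out, order = visit_order, seq_bad = seq_bad,
       order_bad = order_bad, cycle_rows = cycle_rows)
}

#' Re-sort rows and renumber index/parent fields
#'
#' Guarantees that after repair (i) the first sample is a root, (ii)
#' indices run 1..N sequentially, and (iii) every parent appears before
#' its children, while preserving the parent-child tree structure. The
#' re-sort is a deterministic pre-order traversal from each root, with
#' children visited in original file order and multiple roots kept in
#' file order. A file without any root point is an unrepairable error.
#'
#' @param m An \code{swc_morphology} with numeric index/parent fields.
#' @return A list \code{(morphology, log)}.
#' @export
resequence_and_sort <- function(m) {
  log <- check_log()
  s <- m$samples
  if (is.null(s) || any(is.na(s$index)) || any(is.na(s$parent)))
    stop("resequence_and_sort requires numeric index and parent fields")
  if (!any(s$parent == -1)) {
    log <- log_add(log, "Sorted Order", "error",
                   "no sample point is a root; cannot sort")
    return(list(morphology = m, log = log))
  }
  if (sum(s$parent == -1) > 1)
    log <- log_add(log, "Sorted Order", "info",
                   sprintf("%d root points present (multi-tree file)",
                           sum(s$parent == -1)))
  res <- resort_samples(s)
  if (length(res$cycle_rows) > 0)
    log <- log_add(log, "Invalid Parent", "warning",
                   "cyclic parentage detected; cycle broken by creating a root",
                   lines = vapply(res$cycle_rows,
                                  function(i) row_line(m, i), numeric(1)),
                   corrective = TRUE)
  if (res$seq_bad)
    log <- log_add(log, "Sequential Index", "warning",
                   "index values not in sequential order starting from 1; renumbered",
                   corrective = TRUE)
  if (res$order_bad)
    log <- log_add(log, "Sorted Order", "warning",
                   "rows sorted so that the first sample is a root and parents precede children",
                   corrective = TRUE)
  if (res$seq_bad || res$order_bad || length(res$cycle_rows) > 0) {
    m$samples <- res$samples
    m$raw <- NULL
    m$raw_lines <- NULL
    m <- set_tokens(m, token_matrix(m))
  }
  list(morphology = m, log = log)
}

# ---- driver ------------------------------------------------------------

#' Run the full standardization battery
#'
#' Executes, in order: shape checks, invalid-parent repair, index/parent
#' integer coercion, coordinate coercion, radius coercion, type
#' normalization, re-sorting/renumbering, and soma contour replacement.
#' In check-only mode (\code{repair = FALSE}) the input is never mutated
#' and no repaired morphology is returned; the log alone reports what a
#' repair pass would change.
#'
#' @param m An \code{swc_morphology} (parsed or built in memory).
#' @param repair If \code{TRUE} (default) apply corrections and return
#'   the repaired morphology; if \code{FALSE}, only log.
#' @return An object of class \code{swc_standardization}: a list with
#'   \code{morphology} (repaired morphology, or \code{NULL} in check-only
#'   mode or when an unrepairable error occurred), \code{log} (an
#'   \code{swc_check_log}) and \code{is_standard} (\code{TRUE} iff the
#'   input had zero errors and required zero corrections).
#' @export
standardize <- function(m, repair = TRUE) {
  stopifnot(inherits(m, "swc_morphology"))
  log <- check_log()
  work <- m
  failed <- FALSE

  step <- function(f) {
    res <- f(work)
    log <<- log_cat(log, res$log)
    work <<- res$morphology
    invisible(res)
  }

  res <- step(check_shape)
  if (is_terminal(log)) failed <- TRUE

  if (!failed) {
    step(fix_invalid_parents)
    step(coerce_index_parent)
    if (has_errors(log)) failed <- TRUE   # unrepairable index/parent rows
  }
  if (!failed) {
    step(coerce_coordinates)
    step(coerce_radius)
    step(normalize_types)
    res <- step(resequence_and_sort)
    if (has_errors(res$log)) failed <- TRUE  # no root: unrepairable
  }
  if (!failed) {
    step(replace_soma_contours)
  }

  is_standard <- !has_errors(log) && !has_corrections(log)
  out_m <- if (repair && !failed) work else NULL
  structure(list(morphology = out_m, log = log, is_standard = is_standard),
            class = "swc_standardization")
}

#' @export
print.swc_standardization <- function(x, ...) {
  cat(sprintf("<swc_standardization> is_standard: %s; %d log entries\n",
              x$is_standard, nrow(x$log)))
  print(x$log)
  invisible(x)
}
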