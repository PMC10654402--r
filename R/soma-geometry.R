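#' @title Soma contour detection and collapse
#'
#' @description A soma section is a run of three or more contiguous soma
#'   sample points (type 1) whose first point is a root (parent -1) and
#'   whose last point is either a bifurcation or a terminal. Writing the
#'   section points as A, P1, ..., Pn-2, C, the "remote" point B is the
#'   interior sample maximizing the summed Euclidean distances
#'   ||A - Pi|| + ||C - Pi||, and the curvature angle of the section is
#'   the angle at vertex B of the triangle A-B-C. An acute angle
#'   (theta < 90 degrees) marks the section as a closed contour tracing
#'   of the cell-body perimeter, which is replaced by a single point at
#'   the contour centroid with radius equal to the mean distance of the
#'   contour points from that centroid. An obtuse or right angle
#'   (theta >= 90 degrees) marks a stack of frustums along the cell-body
#'   axis, which is retained as is.
#' @name soma-geometry
NULL

# internal: constructor for a soma section
soma_section <- function(coords, swc_indices, rows, terminal_kind,
                         testable) {
  structure(list(coords = coords, swc_indices = swc_indices, rows = rows,
                 n = nrow(coords), first_is_root = TRUE,
                 terminal_kind = terminal_kind, testable = testable),
            class = "soma_section")
}

#' @export
print.soma_section <- function(x, ...) {
  cat(sprintf("<soma_section> %d point(s), ends at %s, %s\n", x$n,
              if (is.na(x$terminal_kind)) "continuation" else x$terminal_kind,
              if (x$testable) "curvature-testable" else "exempt"))
  invisible(x)
}

#' Extract all soma sections of a morphology
#'
#' Walks from every soma-typed root down through single-child soma
#' points until the first bifurcation or terminal, which closes the
#' section. Runs shorter than three points, and runs that end because
#' the chain continues into a non-soma point rather than at a
#' bifurcation/terminal, are returned flagged as exempt from the
#' curvature test.
#'
#' @param m An \code{swc_morphology} with numeric samples and resolvable
#'   parents.
#' @return List of \code{soma_section} objects (possibly empty).
#' @export
extract_soma_sections <- function(m) {
  s <- m$samples
  if (is.null(s) || nrow(s) == 0) return(list())
  kids <- child_counts(s)
  children_of <- function(row) which(match(s$parent, s$index) == row &
                                       s$parent != -1)
  sections <- list()
  for (r in which(s$parent == -1 & s$type == 1)) {
    rows <- r
    terminal_kind <- NA_character_
    cur <- r
    repeat {
      if (kids[cur] == 0) { terminal_kind <- "terminal"; break }
      if (kids[cur] >= 2) {
        terminal_kind <- if (cur == r) NA_character_ else "bifurcation"
        break
      }
      child <- children_of(cur)
      if (s$type[child] != 1) break   # soma run ends mid-chain
      cur <- child
      rows <- c(rows, cur)
    }
    testable <- !is.na(terminal_kind) && length(rows) >= 3
    coords <- as.matrix(s[rows, c("x", "y", "z")])
    rownames(coords) <- NULL
    sections[[length(sections) + 1]] <-
      soma_section(coords, s$index[rows], rows, terminal_kind, testable)
  }
  sections
}

#' The remote point B of a soma section
#'
#' Returns the interior point (excluding the first and last section
#' points) with the largest sum of Euclidean distances from the first
#' and last points; ties are broken by the lowest interior position.
#'
#' @param section A \code{soma_section} with at least three points.
#' @return List with \code{position} (interior position, 1-based over
#'   P1..Pn-2), \code{row} (row within the section) and \code{coords}.
#' @export
remote_point <- function(section) {
  n <- section$n
  if (n < 3) stop("remote point requires a section of at least 3 points")
  A <- section$coords[1, ]; C <- section$coords[n, ]
  interior <- section$coords[2:(n - 1), , drop = FALSE]
  d <- sqrt(rowSums(sweep(interior, 2, A)^2)) +
    sqrt(rowSums(sweep(interior, 2, C)^2))
  i <- which.max(d)   # which.max returns the first (lowest-i) maximum
  list(position = i, row = i + 1L, coords = interior[i, ])
}

#' Curvature angle of a soma section
#'
#' The angle, in degrees within [0, 180], at the remote point B between
#' the rays B->A and B->C, computed from the clamped normalized dot
#' product in double precision.
#'
#' @param section A \code{soma_section} with at least three points.
#' @return Numeric scalar in degrees.
#' @export
curvature_angle <- function(section) {
  n <- section$n
  if (n < 3) stop("curvature angle requires a section of at least 3 points")
  B <- remote_point(section)$coords
  BA <- section$coords[1, ] - B
  BC <- section$coords[n, ] - B
  na <- sqrt(sum(BA^2)); nc <- sqrt(sum(BC^2))
  if (na == 0 || nc == 0)
    stop("degenerate soma section: remote point coincides with an endpoint; flagged for manual review")
  cosang <- sum(BA * BC) / (na * nc)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Is a soma section a contour?
#'
#' \code{TRUE} iff the section is curvature-testable (three or more
#' points, root-anchored, ending at a bifurcation or terminal) and its
#' curvature angle is strictly below 90 degrees. Sections at exactly 90
#' degrees are retained as frustum stacks; degenerate sections are
#' retained for manual review.
#'
#' @param section A \code{soma_section}.
#' @return Logical scalar.
#' @export
is_contour <- function(section) {
  if (!isTRUE(section$testable) || section$n < 3) return(FALSE)
  ang <- tryCatch(curvature_angle(section), error = function(e) NA_real_)
  !is.na(ang) && ang < 90
}

#' Collapse a contour section to a single point
#'
#' The replacement point sits at the arithmetic mean of all contour
#' points; its radius is the mean Euclidean distance of the contour
#' points from that center.
#'
#' @param section A \code{soma_section} for which \code{is_contour} is
#'   \code{TRUE} (not enforced, so the geometry can be inspected for any
#'   section).
#' @return An object of class \code{contour_collapse}: list with
#'   \code{center} (length-3 numeric), \code{radius} and
#'   \code{replaced_indices} (the SWC indices of the contour points).
#' @export
collapse_contour <- function(section) {
  center <- colMeans(section$coords)
  radius <- mean(sqrt(rowSums(sweep(section$coords, 2, center)^2)))
  structure(list(center = center, radius = radius,
                 replaced_indices = section$swc_indices),
            class = "contour_collapse")
}

#' Detect and replace all soma contours of a morphology
#'
#' Every curvature-testable soma section with an acute curvature angle
#' is replaced by its single collapsed point. With multiple contours the
#' collapsed points form a chain in original file order: the first is a
#' root, each subsequent point's parent is the previous one. Neurites
#' that were attached to any replaced contour point are re-parented to
#' that contour's collapsed point, and the file is re-sequenced.
#' Frustum-style sections (angle >= 90 degrees) and exempt sections are
#' left untouched.
#'
#' @param m An otherwise-standardized \code{swc_morphology}.
#' @return A list \code{(morphology, log)}.
#' @export
replace_soma_contours <- function(m) {
  log <- check_log()
  s <- m$samples
  if (is.null(s) || nrow(s) == 0) return(list(morphology = m, log = log))

  sections <- extract_soma_sections(m)
  in_section <- unlist(lapply(sections, function(x) x$rows))
  deep_soma <- which(s$type == 1 & !(seq_len(nrow(s)) %in% in_section))
  if (length(deep_soma) > 0)
    log <- log_add(log, "Soma Contours", "info",
                   "soma samples deeper in the tree are not curvature-tested",
                   lines = vapply(deep_soma, function(i) row_line(m, i),
                                  numeric(1)))
  contours <- Filter(is_contour, sections)
  if (length(contours) == 0) return(list(morphology = m, log = log))

  removed_rows <- integer(0)
  contour_of_row <- integer(nrow(s))   # 0 = kept
  collapses <- vector("list", length(contours))
  for (k in seq_along(contours)) {
    collapses[[k]] <- collapse_contour(contours[[k]])
    removed_rows <- c(removed_rows, contours[[k]]$rows)
    contour_of_row[contours[[k]]$rows] <- k
    log <- log_add(log, "Soma Contours", "warning",
                   sprintf("soma contour of %d points replaced with a single point",
                           contours[[k]]$n),
                   lines = vapply(contours[[k]]$rows,
                                  function(i) row_line(m, i), numeric(1)),
                   corrective = TRUE)
  }

  # new single points, chained in contour file order
  k <- length(contours)
  max_idx <- max(s$index)
  new_idx <- max_idx + seq_len(k)
  new_rows <- data.frame(
    index = new_idx, type = 1,
    x = vapply(collapses, function(cc) cc$center[1], numeric(1)),
    y = vapply(collapses, function(cc) cc$center[2], numeric(1)),
    z = vapply(collapses, function(cc) cc$center[3], numeric(1)),
    radius = vapply(collapses, function(cc) cc$radius, numeric(1)),
    parent = c(-1, new_idx[-k])[seq_len(k)])
  zero_r <- which(new_rows$radius <= 0)
  if (length(zero_r) > 0) {
    new_rows$radius[zero_r] <- 0.5
    log <- log_add(log, "Radius Positive Double", "warning",
                   "collapsed contour radius was zero; set to 0.5",
                   corrective = TRUE)
  }

  kept <- s[-removed_rows, , drop = FALSE]
  # re-parent survivors that pointed into a replaced contour
  if (nrow(kept) > 0) {
    pmap <- match(kept$parent, s$index)
    for (i in seq_len(nrow(kept))) {
      p <- pmap[i]
      if (!is.na(p) && contour_of_row[p] > 0)
        kept$parent[i] <- new_idx[contour_of_row[p]]
    }
  }
  merged <- rbind(new_rows, kept)
  res <- resort_samples(merged)
  m$samples <- res$samples
  m$raw <- NULL
  m$raw_lines <- NULL
  m <- set_tokens(m, token_matrix(m))
  list(morphology = m, log = log)
}
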