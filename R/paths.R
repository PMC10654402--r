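#' @title Segment paths: the converter intermediate representation
#'
#' @description Non-SWC reconstruction dialects describe morphology as
#'   hierarchies of unbranched polylines ("paths", "sections",
#'   "tracings"). A \code{segment_path} is one such polyline: an ordered
#'   run of points with optional per-point radius, a structural-domain
#'   code, and an optional attachment to a point of a parent path. A
#'   forest of segment paths is flattened to an SWC morphology by
#'   depth-first emission, merging duplicated junction points and
#'   inserting default values for fields the source format lacks.
#' @name segment-paths
NULL

#' Construct a segment path
#'
#' @param points Data frame (or matrix) with columns \code{x}, \code{y},
#'   \code{z} and optionally \code{radius} (\code{NA} where the source
#'   stores none).
#' @param domain Structural-domain type code (0-7 or above); \code{NA}
#'   for undefined.
#' @param path_id Unique identifier for the path.
#' @param parent_path \code{NA} for a root path, else the
#'   \code{path_id} of the parent.
#' @param attach_pos Position (1-based) of the attachment point within
#'   the parent path; \code{NA} means the parent's last point.
#' @return An object of class \code{segment_path}.
#' @export
segment_path <- function(points, domain = NA_integer_, path_id,
                         parent_path = NA_character_,
                         attach_pos = NA_integer_) {
  points <- as.data.frame(points)
  if (!"radius" %in% names(points)) points$radius <- NA_real_
  stopifnot(all(c("x", "y", "z") %in% names(points)), nrow(points) >= 1)
  structure(list(path_id = as.character(path_id),
                 points = points[, c("x", "y", "z", "radius")],
                 domain = domain,
                 parent_path = as.character(parent_path),
                 attach_pos = attach_pos),
            class = "segment_path")
}

#' Flatten a forest of segment paths to a morphology
#'
#' Paths are emitted depth-first, roots and children in list order. A
#' child path whose first point coincides (within \code{tol}) with its
#' attachment point on the parent is merged at the junction so the point
#' is not duplicated. Missing radii default to 0.5 and missing domains
#' to type 0 so that no emitted sample has an unset field.
#'
#' @param paths List of \code{segment_path} objects forming a forest.
#' @param source_format Tag recorded on the morphology.
#' @param tol Junction-merge tolerance (Euclidean distance).
#' @return An \code{swc_morphology}.
#' @export
paths_to_morphology <- function(paths, source_format = "paths",
                                tol = 1e-6) {
  if (length(paths) == 0)
    return(morphology(samples = data.frame(index = numeric(0),
                                           type = numeric(0), x = numeric(0),
                                           y = numeric(0), z = numeric(0),
                                           radius = numeric(0),
                                           parent = numeric(0)),
                      source_format = source_format))
  ids <- vapply(paths, function(p) p$path_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate path ids")
  parent_ids <- vapply(paths, function(p) p$parent_path, character(1))
  unknown <- !is.na(parent_ids) & !(parent_ids %in% ids)
  if (any(unknown))
    stop(sprintf("parent path '%s' not declared", parent_ids[unknown][1]))

  # cycle check: walk up from every path
  for (i in seq_along(paths)) {
    seen <- character(0); cur <- ids[i]
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cyclic path graph")
      seen <- c(seen, cur)
      cur <- parent_ids[match(cur, ids)]
    }
  }

  children <- lapply(ids, function(id) which(!is.na(parent_ids) &
                                               parent_ids == id))
  names(children) <- ids
  roots <- which(is.na(parent_ids))

  rows <- list()
  counter <- 0L
  sample_ids_of <- vector("list", length(paths))   # position -> sample idx

  emit_path <- function(i) {
    p <- paths[[i]]
    pts <- p$points
    np <- nrow(pts)
    domain <- if (is.na(p$domain)) 0 else p$domain
    if (is.na(p$parent_path)) {
      attach_sample <- -1L
    } else {
      pp <- match(p$parent_path, ids)
      pos <- if (is.na(p$attach_pos)) length(sample_ids_of[[pp]])
             else p$attach_pos
      pos <- max(1L, min(pos, length(sample_ids_of[[pp]])))
      attach_sample <- sample_ids_of[[pp]][pos]
    }
    path_samples <- integer(np)
    start <- 1L
    prev <- attach_sample
    if (attach_sample != -1L && np >= 1) {
      ap <- rows[[attach_sample]]
      d <- sqrt((pts$x[1] - ap$x)^2 + (pts$y[1] - ap$y)^2 +
                  (pts$z[1] - ap$z)^2)
      if (d <= tol && np > 1) {           # duplicated junction point
        path_samples[1] <- attach_sample
        start <- 2L
      }
    }
    for (j in start:np) {
      counter <<- counter + 1L
      r <- pts$radius[j]
      rows[[counter]] <<- data.frame(
        index = counter, type = domain, x = pts$x[j], y = pts$y[j],
        z = pts$z[j], radius = if (is.na(r)) 0.5 else r, parent = prev)
      path_samples[j] <- counter
      prev <- counter
    }
    sample_ids_of[[i]] <<- path_samples
    for (ch in children[[i]]) emit_path(ch)
  }
  for (r in roots) emit_path(r)

  samples <- do.call(rbind, rows)
  morphology(samples = samples, source_format = source_format)
}

# ---- morphology -> paths (used by the fixture renderers) ---------------

# internal: decompose a morphology into unbranched paths. Each non-root
# path starts AT the branch point (duplicating it as its first point, as
# hierarchical formats do) and runs through continuations until the next
# bifurcation or terminal. Root paths start at a root sample.
morphology_to_paths <- function(m) {
  s <- m$samples
  if (is.null(s) || nrow(s) == 0) return(list())
  kids <- child_counts(s)
  children_of <- function(row) which(match(s$parent, s$index) == row &
                                       s$parent != -1)
  paths <- list()
  counter <- 0

  walk <- function(start_row, first_rows, parent_id, attach_pos) {
    rows <- first_rows
    cur <- start_row
    repeat {
      rows <- c(rows, cur)
      if (kids[cur] != 1) break
      cur <- children_of(cur)
    }
    counter <<- counter + 1
    id <- sprintf("p%03d", counter)
    pts <- data.frame(x = s$x[rows], y = s$y[rows], z = s$z[rows],
                      radius = s$radius[rows])
    paths[[length(paths) + 1]] <<- segment_path(
      pts, domain = s$type[start_row], path_id = id,
      parent_path = if (is.null(parent_id)) NA_character_ else parent_id,
      attach_pos = if (is.null(parent_id)) NA_integer_ else attach_pos)
    end <- rows[length(rows)]
    npts <- length(rows)
    if (kids[end] >= 2)
      for (ch in children_of(end)) walk(ch, end, id, npts)
    invisible(NULL)
  }
  for (r in which(s$parent == -1)) walk(r, integer(0), NULL, NA)
  paths
}
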