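#' @title Deterministic synthetic morphology fixtures
#'
#' @description The fixture generator produces valid morphologies with a
#'   chosen soma style (single point, frustum stack, one contour, or
#'   multiple contours), renders them in the pinned dialect of every
#'   supported source format, and seeds specific specification defects
#'   into otherwise-standard SWC text. The same specification and seed
#'   always produce byte-identical output: randomness is drawn from R's
#'   Mersenne-Twister generator with inversion-based normal deviates,
#'   explicitly pinned so fixtures are stable across platforms.
#' @name fixtures
NULL

#' Describe a synthetic morphology fixture
#'
#' @param n_branch_points Number of bifurcations per neurite tree.
#' @param depth Maximum bifurcation depth per tree.
#' @param soma_style One of \code{"single_point"},
#'   \code{"frustum_stack"}, \code{"contour"}, \code{"multi_contour"}.
#' @param domains Type codes of the neurite trees to grow (one tree per
#'   entry; e.g. \code{c(2, 3)} for an axon and a basal dendrite).
#' @param seed Integer seed; same spec + seed gives identical bytes.
#' @param noise_sd Standard deviation of the per-point positional
#'   jitter, in the same units as the coordinates (micrometers by
#'   convention).
#' @param attach If \code{TRUE}, neurite trees are attached to the last
#'   soma point; if \code{FALSE} they are separate roots, as in
#'   contour-bearing source formats. Default: attached for point/frustum
#'   somata, detached for contour somata.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_branch_points = 2, depth = 3,
                         soma_style = c("single_point", "frustum_stack",
                                        "contour", "multi_contour"),
                         domains = c(2, 3), seed = 1, noise_sd = 0.1,
                         attach = NULL) {
  soma_style <- match.arg(soma_style)
  if (is.null(attach))
    attach <- soma_style %in% c("single_point", "frustum_stack")
  stopifnot(n_branch_points >= 0, depth >= 0, noise_sd >= 0)
  structure(list(n_branch_points = n_branch_points, depth = depth,
                 soma_style = soma_style, domains = domains,
                 seed = as.integer(seed), noise_sd = noise_sd,
                 attach = attach),
            class = "fixture_spec")
}

# internal: run expr under a pinned, seeded RNG, restoring global state
with_fixture_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# internal: random unit vector at angle `ang` (radians) from `dir`
.cone_dir <- function(dir, ang) {
  dir <- dir / sqrt(sum(dir^2))
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  phi <- stats::runif(1, 0, 2 * pi)
  w <- cos(phi) * u + sin(phi) * v
  out <- cos(ang) * dir + sin(ang) * w
  out / sqrt(sum(out^2))
}

#' Generate a synthetic morphology
#'
#' Builds soma samples in the requested style, then grows one neurite
#' tree per requested domain: branch directions are drawn on a cone
#' (25 degrees) around the parent direction, inter-point step lengths
#' are log-normal, and radii taper geometrically with depth. Contour
#' somata are placed as points on a (jittered) circle so the curvature
#' test recognizes them as contours by construction; frustum somata are
#' collinear stacks with a straight (180 degree) curvature angle.
#' Output rows are emitted parents-first with sequential indices.
#'
#' @param spec A \code{fixture_spec}.
#' @return An \code{swc_morphology}.
#' @export
generate_morphology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_rng(spec$seed, {
    rows <- list()
    counter <- 0L
    add <- function(type, x, y, z, radius, parent) {
      counter <<- counter + 1L
      rows[[counter]] <<- data.frame(
        index = counter, type = type,
        x = round(x, 3), y = round(y, 3), z = round(z, 3),
        radius = round(radius, 3), parent = parent)
      counter
    }
    contour_points <- function(center, r, npts) {
      ang <- 2 * pi * (seq_len(npts) - 1) / npts
      cbind(center[1] + r * cos(ang) + stats::rnorm(npts, 0, spec$noise_sd),
            center[2] + r * sin(ang) + stats::rnorm(npts, 0, spec$noise_sd),
            rep(center[3], npts))
    }

    attach_id <- NA_integer_
    soma_tip <- c(0, 0, 0)
    if (spec$soma_style == "single_point") {
      attach_id <- add(1, 0, 0, 0, 5, -1)
    } else if (spec$soma_style == "frustum_stack") {
      xs <- c(0, 2, 4, 6); rs <- c(5, 5.5, 5, 4.5)
      prev <- -1L
      for (i in 1:4) prev <- add(1, xs[i], 0, 0, rs[i], prev)
      attach_id <- prev
      soma_tip <- c(6, 0, 0)
    } else if (spec$soma_style == "contour") {
      pts <- contour_points(c(0, 0, 0), 4, 8)
      prev <- -1L
      for (i in 1:8) prev <- add(1, pts[i, 1], pts[i, 2], pts[i, 3], 1, prev)
    } else {                               # multi_contour
      for (z0 in c(0, 3)) {
        pts <- contour_points(c(0, 0, z0), 4, 8)
        prev <- -1L
        for (i in 1:8) prev <- add(1, pts[i, 1], pts[i, 2], pts[i, 3], 1, prev)
      }
    }

    grow_segment <- function(domain, parent_id, origin, dir, radius,
                             bp_left, depth_left) {
      prev <- parent_id
      pos <- origin
      for (j in 1:3) {
        step <- stats::rlnorm(1, log(3), 0.2)
        pos <- pos + dir * step + stats::rnorm(3, 0, spec$noise_sd)
        prev <- add(domain, pos[1], pos[2], pos[3], radius, prev)
      }
      if (bp_left > 0 && depth_left > 0) {
        left <- ceiling((bp_left - 1) / 2)
        right <- (bp_left - 1) - left
        for (side in 1:2) {
          nd <- .cone_dir(dir, 25 * pi / 180)
          grow_segment(domain, prev, pos, nd, radius * 0.85,
                       if (side == 1) left else right, depth_left - 1)
        }
      }
      invisible(NULL)
    }

    n_tree <- 0
    for (domain in spec$domains) {
      n_tree <- n_tree + 1
      dir <- .cone_dir(c(cos(n_tree), sin(n_tree), 0.2), 10 * pi / 180)
      if (spec$attach && !is.na(attach_id)) {
        grow_segment(domain, attach_id, soma_tip, dir, 1,
                     spec$n_branch_points, spec$depth)
      } else {
        start <- soma_tip + dir * 6
        root <- add(domain, start[1], start[2], start[3], 1, -1)
        grow_segment(domain, root, start, dir, 1, spec$n_branch_points,
                     spec$depth)
      }
    }
    morphology(samples = do.call(rbind, rows), source_format = "swc")
  })
}

# ---- rendering in source dialects --------------------------------------

.domain_label <- function(code) {
  switch(as.character(code), "1" = "Soma", "2" = "Axon", "3" = "Dendrite",
         "4" = "Apical", "Default")
}

.asc_keyword <- function(code) {
  switch(as.character(code), "2" = "Axon", "3" = "Dendrite",
         "4" = "Apical", "Dendrite")
}

.hoc_prefix <- function(code) {
  switch(as.character(code), "1" = "soma", "2" = "axon", "3" = "dend",
         "4" = "apic", "sec")
}

#' Render a morphology in a source-format dialect
#'
#' Writes the morphology in the pinned dialect of the requested format,
#' degrading fields the format cannot carry: NDF drops z and radius, NTS
#' stores thickness = 2 x radius, KNOSSOS stores no type, ESWC appends
#' extra columns. This is the counterpart of the converter module and
#' enables round-trip testing without external data.
#'
#' @param m An \code{swc_morphology} (standard ordering assumed).
#' @param fmt One of \code{"asc"}, \code{"hoc"}, \code{"knossos_nml"},
#'   \code{"neuroml"}, \code{"ndf"}, \code{"nts"}, \code{"eswc"}.
#' @return Character vector of output lines.
#' @export
render_fixture <- function(m, fmt) {
  stopifnot(inherits(m, "swc_morphology"))
  switch(fmt,
         asc = .render_asc(m),
         hoc = .render_hoc(m),
         knossos_nml = .render_knossos(m),
         neuroml = .render_neuroml(m),
         ndf = .render_ndf(m),
         nts = .render_nts(m),
         eswc = .render_eswc(m),
         stop(sprintf("unsupported fixture format '%s'", fmt)))
}

.render_eswc <- function(m) {
  s <- m$samples
  # 3 extra per-sample columns: segment id, level placeholder, flag
  body <- write_swc(morphology(samples = s))
  extras <- sprintf("%d 0 1", s$index)
  c("# extended SWC fixture", paste(body, extras))
}

.render_ndf <- function(m) {
  paths <- morphology_to_paths(m)
  out <- c("// NeuronJ Data File - version 1.4.2")
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    out <- c(out,
             sprintf("// Tracing N%d", k),
             as.character(k), "1", "0",
             .domain_label(p$domain),
             sprintf("// Segment 1 of Tracing N%d", k),
             as.vector(rbind(fmt_swc_float(p$points$x),
                             fmt_swc_float(p$points$y))))
  }
  c(out, "// End of NeuronJ Data File")
}

.render_nts <- function(m) {
  s <- m$samples
  kids <- child_counts(s)
  if (any(kids > 2)) stop("NTS rendering supports binary trees only")
  children_of <- function(row) which(match(s$parent, s$index) == row &
                                       s$parent != -1)
  origin_of <- function(type)
    switch(as.character(type), "2" = "MTO", "3" = "DTO", "4" = "BTO",
           "1" = "SOS", "TTO")
  out <- character(0)
  emit <- function(row, is_origin) {
    soma <- s$type[row] == 1
    mnem <- if (is_origin) origin_of(s$type[row])
            else if (kids[row] == 2) "BP"
            else if (kids[row] == 0) { if (soma) "SOE" else "NE" }
            else if (soma) "SCP" else "CP"
    out <<- c(out, sprintf("%s %s %s %s %s", mnem,
                           fmt_swc_float(s$x[row]), fmt_swc_float(s$y[row]),
                           fmt_swc_float(s$z[row]),
                           fmt_swc_float(2 * s$radius[row])))
    for (ch in children_of(row)) emit(ch, FALSE)
  }
  for (r in which(s$parent == -1)) emit(r, TRUE)
  out
}

.render_asc <- function(m) {
  s <- m$samples
  kids <- child_counts(s)
  cross <- s$parent != -1 &
    s$type != s$type[match(s$parent, s$index)] &
    s$type[match(s$parent, s$index)] == 1
  if (any(cross, na.rm = TRUE))
    stop("ASC dialect cannot express attachment of neurites to the soma; use detached fixtures")
  children_of <- function(row) which(match(s$parent, s$index) == row &
                                       s$parent != -1)
  pt <- function(row) sprintf("  (%s %s %s %s)",
                              fmt_swc_float(s$x[row]), fmt_swc_float(s$y[row]),
                              fmt_swc_float(s$z[row]),
                              fmt_swc_float(2 * s$radius[row]))
  out <- character(0)
  run_lines <- function(row) {
    lines <- character(0)
    cur <- row
    repeat {
      lines <- c(lines, pt(cur))
      if (kids[cur] != 1) break
      cur <- children_of(cur)
    }
    list(lines = lines, end = cur)
  }
  branch_lines <- function(row) {
    rl <- run_lines(row)
    lines <- rl$lines
    if (kids[rl$end] >= 2) {
      ch <- children_of(rl$end)
      sub <- lapply(ch, branch_lines)
      inner <- character(0)
      for (i in seq_along(sub)) {
        inner <- c(inner, sub[[i]])
        if (i < length(sub)) inner <- c(inner, "  |")
      }
      lines <- c(lines, "  (", inner, "  )")
    }
    lines
  }
  for (r in which(s$parent == -1)) {
    if (s$type[r] == 1) {
      rl <- run_lines(r)
      out <- c(out, "(\"CellBody\"", "  (CellBody)", rl$lines, ")")
    } else {
      out <- c(out, sprintf("( (%s)", .asc_keyword(s$type[r])),
               branch_lines(r), ")")
    }
  }
  out
}

.render_hoc <- function(m) {
  paths <- morphology_to_paths(m)
  counters <- integer(0)
  name_of <- character(length(paths))
  for (k in seq_along(paths)) {
    pre <- .hoc_prefix(paths[[k]]$domain)
    i <- counters[pre]
    if (is.na(i)) i <- 0L
    counters[pre] <- i + 1L
    name_of[k] <- sprintf("%s_%d", pre, i)
  }
  ids <- vapply(paths, function(p) p$path_id, character(1))
  out <- sprintf("create %s", paste(name_of, collapse = ", "))
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    if (!is.na(p$parent_path)) {
      pk <- match(p$parent_path, ids)
      np <- nrow(paths[[pk]]$points)
      frac <- if (np > 1) (p$attach_pos - 1) / (np - 1) else 1
      out <- c(out, sprintf("connect %s(0), %s(%s)", name_of[k],
                            name_of[pk], fmt_swc_float(frac)))
    }
  }
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    out <- c(out, sprintf("%s {", name_of[k]),
             sprintf("  pt3dadd(%s, %s, %s, %s)",
                     fmt_swc_float(p$points$x), fmt_swc_float(p$points$y),
                     fmt_swc_float(p$points$z),
                     fmt_swc_float(2 * p$points$radius)),
             "}")
  }
  out
}

.render_knossos <- function(m) {
  s <- m$samples
  nodes <- sprintf('      <node id="%d" x="%s" y="%s" z="%s" radius="%s"/>',
                   s$index, fmt_swc_float(s$x), fmt_swc_float(s$y),
                   fmt_swc_float(s$z), fmt_swc_float(s$radius))
  nr <- s$parent != -1
  edges <- sprintf('      <edge source="%d" target="%d"/>',
                   s$parent[nr], s$index[nr])
  c('<?xml version="1.0" encoding="UTF-8"?>',
    "<things>",
    '  <thing id="1">',
    "    <nodes>", nodes, "    </nodes>",
    "    <edges>", edges, "    </edges>",
    "  </thing>",
    "</things>")
}

.render_neuroml <- function(m) {
  s <- m$samples
  seg <- character(0)
  seg_of <- integer(nrow(s))       # sample row -> segment id
  next_id <- 0L
  for (i in seq_len(nrow(s))) {
    sid <- next_id; next_id <- next_id + 1L
    seg_of[i] <- sid
    d <- fmt_swc_float(2 * s$radius[i])
    p3 <- sprintf('x="%s" y="%s" z="%s" diameter="%s"',
                  fmt_swc_float(s$x[i]), fmt_swc_float(s$y[i]),
                  fmt_swc_float(s$z[i]), d)
    if (s$parent[i] == -1) {
      seg <- c(seg, sprintf('      <segment id="%d" name="seg%d">', sid, sid),
               sprintf('        <proximal %s/>', p3),
               sprintf('        <distal %s/>', p3),
               "      </segment>")
    } else {
      prow <- match(s$parent[i], s$index)
      seg <- c(seg, sprintf('      <segment id="%d" name="seg%d">', sid, sid),
               sprintf('        <parent segment="%d"/>', seg_of[prow]),
               sprintf('        <distal %s/>', p3),
               "      </segment>")
    }
  }
  groups <- character(0)
  for (code in sort(unique(s$type))) {
    gname <- switch(as.character(code), "1" = "soma_group",
                    "2" = "axon_group", "3" = "dendrite_group",
                    "4" = "apical_group", NULL)
    if (is.null(gname)) next
    members <- sprintf('        <member segment="%d"/>',
                       seg_of[s$type == code])
    groups <- c(groups, sprintf('      <segmentGroup id="%s">', gname),
                members, "      </segmentGroup>")
  }
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<neuroml xmlns="http://www.neuroml.org/schema/neuroml2" id="fixture">',
    '  <cell id="fixture_cell">',
    "    <morphology>",
    seg, groups,
    "    </morphology>",
    "  </cell>",
    "</neuroml>")
}

# ---- defect seeding ----------------------------------------------------

#' Seed specification defects into standard SWC text
#'
#' Starts from the standardized rendering of \code{m} and corrupts it so
#' that exactly the requested specification checks fire, recording the
#' seeded defect set for test assertions. A \code{"Number of Lines"}
#' defect (a file with no samples) and a \code{"Missing Field"} defect
#' are terminal for the check battery and therefore cannot be combined
#' with defects that a terminated battery would never reach;
#' contradictory combinations are an error.
#'
#' @param m An \code{swc_morphology} to corrupt.
#' @param defects Character vector of check identifiers (see
#'   \code{\link{swc_check_ids}}).
#' @param seed Integer seed controlling which rows are corrupted.
#' @return Character vector of SWC lines with attribute
#'   \code{"defects"} holding the seeded check identifiers.
#' @export
corrupt_swc <- function(m, defects = character(0), seed = 1) {
  defects <- unique(defects)
  bad <- setdiff(defects, swc_check_ids())
  if (length(bad) > 0)
    stop(sprintf("unknown defect id(s): %s", paste(bad, collapse = ", ")))
  if ("Number of Lines" %in% defects && length(defects) > 1)
    stop("contradictory defects: an empty file exhibits nothing else")
  if (all(c("Sequential Index", "Sorted Order") %in% defects))
    stop("contradictory defects: re-sorting renumbers the indices")
  if ("Missing Field" %in% defects && length(defects) > 1)
    stop("contradictory defects: a missing field aborts all later checks")

  if ("Number of Lines" %in% defects) {
    out <- c("# corrupted fixture", "# no data rows")
    attr(out, "defects") <- defects
    return(out)
  }

  std <- standardize(m, repair = TRUE)$morphology
  if (is.null(std)) stop("input morphology cannot be standardized")

  with_fixture_rng(seed, {
    s <- std$samples

    if ("Soma Contours" %in% defects) {
      root <- which(s$parent == -1 & s$type == 1)
      if (length(root) == 0)
        stop("cannot seed a soma contour: no soma root")
      root <- root[1]
      kid_rows <- which(match(s$parent, s$index) == root & s$parent != -1)
      if (any(s$type[kid_rows] == 1) || length(kid_rows) == 1)
        stop("cannot seed a soma contour on this soma arrangement")
      r0 <- s$radius[root]
      ang <- 2 * pi * (0:7) / 8
      maxi <- max(s$index)
      contour <- data.frame(
        index = maxi + 1:8, type = 1,
        x = round(s$x[root] + r0 * cos(ang), 3),
        y = round(s$y[root] + r0 * sin(ang), 3),
        z = s$z[root], radius = 1,
        parent = c(-1, maxi + 1:7))
      kept <- s[-root, , drop = FALSE]
      kept$parent[kept$parent == s$index[root]] <- maxi + 8
      merged <- rbind(contour, kept)
      s <- resort_samples(merged)$samples
    }

    mat <- cbind(fmt_swc_int(s$index), fmt_swc_int(s$type),
                 fmt_swc_float(s$x), fmt_swc_float(s$y), fmt_swc_float(s$z),
                 fmt_swc_float(s$radius), fmt_swc_int(s$parent))
    n <- nrow(mat)
    used <- integer(0)
    pick <- function(eligible) {
      eligible <- setdiff(eligible, used)
      if (length(eligible) == 0) stop("no eligible row left for a defect")
      row <- if (length(eligible) == 1) eligible
             else eligible[sample.int(length(eligible), 1)]
      used <<- c(used, row)
      row
    }

    if ("Number of Soma Samples" %in% defects)
      mat[mat[, 2] == "1", 2] <- "3"

    if ("Invalid Parent" %in% defects) {
      i <- pick(which(mat[, 7] != "-1"))
      # 10*max + 37 stays nonexistent even if indices are later scaled
      mat[i, 7] <- fmt_swc_int(max(s$index) * 10 + 37)
    }
    if ("XYZ Double" %in% defects) {
      i <- pick(seq_len(n))
      mat[i, 4] <- "NA"
    }
    if ("Radius Positive Double" %in% defects) {
      i <- pick(seq_len(n))
      mat[i, 6] <- "-1.0"
    }
    if ("Non-Standard Type" %in% defects) {
      kids <- child_counts(s)
      elig <- which(kids == 0 & s$parent != -1 &
                      s$type[match(s$parent, s$index)] != 6)
      if (length(setdiff(elig, used)) > 0) {
        i <- pick(elig)
        mat[i, 2] <- "6"
      } else {
        i <- pick(seq_len(n))
        mat[i, 2] <- "1.5"
      }
    }
    if ("Sequential Index" %in% defects) {
      old <- as.numeric(mat[, 1])
      mat[, 1] <- fmt_swc_int(old * 10)
      nr <- mat[, 7] != "-1"
      pv <- as.numeric(mat[nr, 7])
      mat[nr, 7] <- fmt_swc_int(ifelse(pv %in% old, pv * 10, pv))
    }
    if ("Sorted Order" %in% defects) {
      i <- pick(which(s$parent != -1))
      ord <- c(i, setdiff(seq_len(n), i))
      mat <- mat[ord, , drop = FALSE]
      old_idx <- as.numeric(mat[, 1])
      remap <- stats::setNames(seq_len(n), old_idx)
      mat[, 1] <- fmt_swc_int(seq_len(n))
      nr <- mat[, 7] != "-1"
      pv <- mat[nr, 7]
      known <- pv %in% names(remap)
      pv[known] <- fmt_swc_int(remap[pv[known]])
      mat[nr, 7] <- pv
    }
    if ("Index/Parent Integer" %in% defects) {
      i <- pick(seq_len(n))
      mat[i, 1] <- paste0(mat[i, 1], ".00")
    }

    rows <- lapply(seq_len(n), function(i) mat[i, ])
    if ("Missing Field" %in% defects) {
      i <- pick(seq_len(n))
      rows[[i]] <- rows[[i]][1:6]
    }
    out <- c("# corrupted fixture",
             vapply(rows, paste, character(1), collapse = " "))
    attr(out, "defects") <- defects
    out
  })
}
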