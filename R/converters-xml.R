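#' @title Converters for XML reconstruction dialects
#'
#' @description KNOSSOS annotation files and NeuroML cell files both use
#'   the .nml extension but are unrelated XML schemas: KNOSSOS stores
#'   explicit node and edge lists under a \code{<things>} root, NeuroML
#'   stores proximal/distal segments with parent references under a
#'   \code{<neuroml>} (v2) or \code{<morphml>} (v1) root. Both are read
#'   with namespace stripping so v1 and v2 NeuroML documents share one
#'   code path.
#' @name converters-xml
NULL

.read_xml_input <- function(text) {
  if (length(text) == 1 && !grepl("[\n\r<]", text) && file.exists(text))
    return(xml2::read_xml(text))
  xml2::read_xml(paste(text, collapse = "\n"))
}

# ---- KNOSSOS -----------------------------------------------------------

#' Convert a KNOSSOS annotation (NML) file to a morphology
#'
#' Reads the node list (id, x, y, z, optional radius) and edge list
#' (source, target) of every \code{<thing>} and rebuilds each connected
#' component as a tree rooted at its lowest node id. Missing radii
#' default to 0.5; the format stores no structural domain, so all
#' samples are type 0. An edge referencing an unknown node id, or a
#' cyclic edge set, is an error.
#'
#' @param xml File path, XML text, or an \code{xml2} document.
#' @return An \code{swc_morphology} (source_format "knossos_nml").
#' @export
knossos_nml_to_morphology <- function(xml) {
  doc <- if (inherits(xml, "xml_document")) xml else .read_xml_input(xml)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//node")
  edges <- xml2::xml_find_all(doc, ".//edge")
  if (length(nodes) == 0)
    return(morphology(samples = data.frame(
      index = numeric(0), type = numeric(0), x = numeric(0), y = numeric(0),
      z = numeric(0), radius = numeric(0), parent = numeric(0)),
      source_format = "knossos_nml"))

  att <- function(ns, a) xml2::xml_attr(ns, a)
  id <- as.numeric(att(nodes, "id"))
  x <- as.numeric(att(nodes, "x"))
  y <- as.numeric(att(nodes, "y"))
  z <- as.numeric(att(nodes, "z"))
  r <- suppressWarnings(as.numeric(att(nodes, "radius")))
  r[is.na(r)] <- 0.5
  if (any(is.na(id)) || anyDuplicated(id))
    stop("malformed KNOSSOS node list: missing or duplicate node ids")

  n <- length(id)
  adj <- vector("list", n)
  if (length(edges) > 0) {
    src <- as.numeric(att(edges, "source"))
    tgt <- as.numeric(att(edges, "target"))
    sp <- match(src, id); tp <- match(tgt, id)
    if (any(is.na(sp)) || any(is.na(tp)))
      stop("edge references unknown node id")
    for (e in seq_along(sp)) {
      adj[[sp[e]]] <- c(adj[[sp[e]]], tp[e])
      adj[[tp[e]]] <- c(adj[[tp[e]]], sp[e])
    }
  }

  parent_pos <- rep(NA_integer_, n)
  visited <- logical(n)
  order <- integer(0)
  n_tree_edges <- 0L
  while (any(!visited)) {
    comp <- which(!visited)
    root <- comp[which.min(id[comp])]
    stack <- root
    parent_pos[root] <- -1L
    while (length(stack) > 0) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (visited[cur]) next
      visited[cur] <- TRUE
      order <- c(order, cur)
      for (nb in adj[[cur]]) {
        if (!visited[nb]) {
          if (!is.na(parent_pos[nb]))
            stop("cyclic edge set: annotation is not a tree")
          parent_pos[nb] <- cur
          n_tree_edges <- n_tree_edges + 1L
          stack <- c(stack, nb)
        } else if (nb != parent_pos[cur]) {
          stop("cyclic edge set: annotation is not a tree")
        }
      }
    }
  }
  if (length(edges) > 0 && n_tree_edges != length(xml2::xml_attr(edges, "source")))
    stop("cyclic edge set: annotation is not a tree")

  new_index <- integer(n)
  new_index[order] <- seq_len(n)
  po <- parent_pos[order]
  pidx <- rep(-1, n)
  pidx[po != -1L] <- new_index[po[po != -1L]]
  samples <- data.frame(
    index = seq_len(n), type = 0,
    x = x[order], y = y[order], z = z[order], radius = r[order],
    parent = pidx)
  morphology(samples = samples, source_format = "knossos_nml")
}

# ---- NeuroML -----------------------------------------------------------

#' Convert a NeuroML cell morphology to a morphology
#'
#' Supports NeuroML v2 (\code{<neuroml>} root, \code{<segment>} elements
#' with \code{<parent segment="..">}, \code{<proximal>}/\code{<distal>}
#' points, \code{<segmentGroup>} memberships) and the equivalent v1
#' (\code{<morphml>}) layout, with namespaces stripped. Each segment's
#' distal point becomes a sample; the proximal point of a parentless
#' segment becomes that tree's root sample. A \code{fractionAlong} of 0
#' attaches a child at its parent's proximal point. Group or cable names
#' containing soma/axon/dend/apic map to types 1/2/3/4.
#'
#' @param xml File path, XML text, or an \code{xml2} document.
#' @return An \code{swc_morphology} (source_format "neuroml").
#' @export
neuroml_to_morphology <- function(xml) {
  doc <- if (inherits(xml, "xml_document")) xml else .read_xml_input(xml)
  xml2::xml_ns_strip(doc)
  segs <- xml2::xml_find_all(doc, ".//segment")
  if (length(segs) == 0)
    return(morphology(samples = data.frame(
      index = numeric(0), type = numeric(0), x = numeric(0), y = numeric(0),
      z = numeric(0), radius = numeric(0), parent = numeric(0)),
      source_format = "neuroml"))

  seg_id <- xml2::xml_attr(segs, "id")
  seg_cable <- xml2::xml_attr(segs, "cable")       # v1 grouping
  if (anyDuplicated(seg_id)) stop("duplicate segment ids")

  # domain per segment from segmentGroup membership (v2) or cable (v1)
  dom <- rep(NA_integer_, length(segs))
  groups <- xml2::xml_find_all(doc, ".//segmentGroup")
  for (g in groups) {
    gname <- xml2::xml_attr(g, "id")
    members <- xml2::xml_attr(xml2::xml_find_all(g, ".//member"), "segment")
    d <- .domain_from_name(gname)
    dom[seg_id %in% members] <- d
  }
  cables <- xml2::xml_find_all(doc, ".//cable")
  if (length(cables) > 0) {
    cid <- xml2::xml_attr(cables, "id")
    cname <- xml2::xml_attr(cables, "name")
    for (i in seq_along(cid)) {
      hit <- !is.na(seg_cable) & seg_cable == cid[i]
      dom[hit] <- .domain_from_name(cname[i])
    }
  }
  dom[is.na(dom)] <- 0L

  point_of <- function(seg, which) {
    nd <- xml2::xml_find_first(seg, paste0("./", which))
    if (inherits(nd, "xml_missing")) return(NULL)
    c(x = as.numeric(xml2::xml_attr(nd, "x")),
      y = as.numeric(xml2::xml_attr(nd, "y")),
      z = as.numeric(xml2::xml_attr(nd, "z")),
      r = as.numeric(xml2::xml_attr(nd, "diameter")) / 2)
  }

  rows <- list()
  counter <- 0L
  distal_sample <- stats::setNames(rep(NA_integer_, length(segs)), seg_id)
  proximal_sample <- stats::setNames(rep(NA_integer_, length(segs)), seg_id)

  add_row <- function(pt, type, parent) {
    counter <<- counter + 1L
    r <- if (is.na(pt["r"]) || pt["r"] <= 0) 0.5 else pt["r"]
    rows[[counter]] <<- data.frame(index = counter, type = type,
                                   x = pt[["x"]], y = pt[["y"]],
                                   z = pt[["z"]], radius = r,
                                   parent = parent)
    counter
  }

  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    par_nd <- xml2::xml_find_first(seg, "./parent")
    par_attr <- xml2::xml_attr(seg, "parent")        # v1 attribute form
    prox <- point_of(seg, "proximal")
    dist <- point_of(seg, "distal")
    if (is.null(dist)) stop(sprintf("segment '%s' has no distal point",
                                    seg_id[i]))
    has_parent <- !inherits(par_nd, "xml_missing") || !is.na(par_attr)
    if (!has_parent) {
      same <- !is.null(prox) &&
        isTRUE(all(prox[c("x", "y", "z")] == dist[c("x", "y", "z")]))
      if (same) {
        # zero-length root segment (spherical soma convention)
        s <- add_row(dist, dom[i], -1L)
        proximal_sample[i] <- s
        distal_sample[i] <- s
      } else {
        parent_sample <- -1L
        if (!is.null(prox)) {
          root_s <- add_row(prox, dom[i], -1L)
          proximal_sample[i] <- root_s
          parent_sample <- root_s
        }
        distal_sample[i] <- add_row(dist, dom[i], parent_sample)
      }
    } else {
      pid <- if (!inherits(par_nd, "xml_missing"))
        xml2::xml_attr(par_nd, "segment") else par_attr
      frac <- if (!inherits(par_nd, "xml_missing"))
        suppressWarnings(as.numeric(xml2::xml_attr(par_nd, "fractionAlong")))
      else NA_real_
      pp <- match(pid, seg_id)
      if (is.na(pp) || is.na(distal_sample[pp]))
        stop(sprintf("segment '%s' references missing parent segment '%s'",
                     seg_id[i], pid))
      anchor <- if (!is.na(frac) && frac == 0 && !is.na(proximal_sample[pp]))
        proximal_sample[pp] else distal_sample[pp]
      distal_sample[i] <- add_row(dist, dom[i], anchor)
    }
  }
  morphology(samples = do.call(rbind, rows), source_format = "neuroml")
}
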