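#' @title Converters for text reconstruction dialects
#'
#' @description Readers for the pinned dialects of NeuronJ NDF,
#'   Neurolucida ASC, NEURON HOC, Eutectic NTS and extended SWC, each
#'   producing an \code{swc_morphology} through the segment-path
#'   intermediate representation. Fields a format cannot carry receive
#'   SWC defaults: radius 0.5, z 0, type 0. Constructs a dialect marks
#'   as non-structural (spines, markers, colors, text annotations) are
#'   skipped with a conversion note; malformed structural constructs are
#'   errors.
#' @name converters-text
NULL

# internal: shared domain keyword -> type code mapping
.domain_from_name <- function(name) {
  n <- tolower(name)
  if (grepl("soma|cellbody", n)) 1L
  else if (grepl("axon", n)) 2L
  else if (grepl("apic", n)) 4L
  else if (grepl("dend|basal", n)) 3L
  else 0L
}

.text_lines <- function(text) {
  if (length(text) == 1 && !grepl("[\n\r]", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  unlist(strsplit(paste(text, collapse = "\n"), "\r\n|\n|\r"))
}

# ---- format detection --------------------------------------------------

#' Detect the reconstruction format of an input
#'
#' Decision by file extension first, then content sniffing: the XML root
#' element separates KNOSSOS annotation files from NeuroML (both use
#' .nml), and the column count of the first data line separates SWC
#' (7 columns) from extended SWC (8 or more).
#'
#' @param text File path or text content.
#' @param filename Optional file name used for the extension rule when
#'   \code{text} holds content.
#' @return One of \code{"swc"}, \code{"eswc"}, \code{"ndf"},
#'   \code{"asc"}, \code{"hoc"}, \code{"nts"}, \code{"knossos_nml"},
#'   \code{"neuroml"}.
#' @export
detect_format <- function(text, filename = NULL) {
  if (is.null(filename) && length(text) == 1 && !grepl("[\n\r]", text) &&
      file.exists(text)) filename <- text
  lines <- .text_lines(text)
  ext <- if (!is.null(filename)) tolower(tools::file_ext(filename)) else ""

  sniff_xml <- function() {
    root <- tryCatch(xml2::xml_name(xml2::xml_root(
      xml2::read_xml(paste(lines, collapse = "\n")))),
      error = function(e) NA_character_)
    if (is.na(root)) stop("unsupported format: unparseable XML")
    if (root == "things") "knossos_nml"
    else if (root %in% c("neuroml", "morphml")) "neuroml"
    else stop(sprintf("unsupported format: XML root <%s>", root))
  }
  sniff_table <- function() {
    data <- lines[!grepl("^\\s*#", lines) & trimws(lines) != ""]
    if (length(data) == 0) return("swc")
    ncol <- length(strsplit(trimws(data[1]), "[ \t]+")[[1]])
    if (ncol >= 8) "eswc" else "swc"
  }

  if (ext %in% c("swc", "eswc")) return(sniff_table())
  if (ext %in% c("ndf", "asc", "hoc", "nts")) return(ext)
  if (ext %in% c("nml", "xml", "cell.nml", "nml1")) return(sniff_xml())

  # no usable extension: sniff content
  head_txt <- paste(utils::head(lines, 30), collapse = "\n")
  if (grepl("^\\s*<", lines[which(trimws(lines) != "")[1]])) return(sniff_xml())
  if (grepl("NeuronJ", head_txt, ignore.case = TRUE)) return("ndf")
  if (grepl("pt3dadd|create\\s+\\w", head_txt)) return("hoc")
  if (grepl("^\\s*\\(", head_txt)) return("asc")
  if (grepl("\\b(MTO|DTO|TTO|BTO|SOS|CP|BP|NE)\\b", head_txt)) return("nts")
  tab <- tryCatch(sniff_table(), error = function(e) NULL)
  if (!is.null(tab)) return(tab)
  stop("unsupported format")
}

# ---- NeuronJ NDF -------------------------------------------------------

#' Convert a NeuronJ NDF tracing file to a morphology
#'
#' NDF captures the arbor as a two-dimensional linear projection and
#' stores neither branch thickness nor depth, so every converted sample
#' receives a uniform radius of 0.5 and a z coordinate of 0. Each
#' tracing block becomes one unattached path; tracing type labels map
#' onto the standard type codes (axon 2, dendrite 3, ...), unlabeled
#' tracings onto type 0.
#'
#' Pinned dialect: a "// Tracing Nk" header followed by four metadata
#' lines (tracing id, 1-based type index, cluster index, label), then
#' one or more "// Segment j of Tracing Nk" blocks of alternating x and
#' y coordinate lines. An optional "// Type names and colors" section of
#' alternating name/color lines resolves numeric type indices.
#'
#' @param text File path or NDF text.
#' @return An \code{swc_morphology} (source_format "ndf").
#' @export
ndf_to_morphology <- function(text) {
  lines <- trimws(.text_lines(text))
  lines <- lines[lines != ""]

  # type-name table (optional)
  type_names <- character(0)
  tn <- which(grepl("^// Type names and colors", lines))
  if (length(tn) == 1) {
    i <- tn + 1
    while (i <= length(lines) && !startsWith(lines[i], "//")) {
      type_names <- c(type_names, lines[i])   # name line
      i <- i + 2                              # skip color line
    }
  }

  tr_hdr <- which(grepl("^// Tracing ", lines))
  paths <- list()
  for (h in seq_along(tr_hdr)) {
    start <- tr_hdr[h]
    end <- if (h < length(tr_hdr)) tr_hdr[h + 1] - 1 else length(lines)
    block <- lines[start:end]
    block <- block[!grepl("^// End of", block)]
    name <- sub("^// Tracing ", "", block[1])
    seg_hdr <- which(grepl("^// Segment ", block))
    if (length(seg_hdr) == 0)
      stop(sprintf("malformed NDF tracing block '%s': no segments", name))
    meta <- block[2:(seg_hdr[1] - 1)]
    label <- NA_character_
    alpha <- meta[grepl("^[A-Za-z]", meta)]
    if (length(alpha) > 0) {
      label <- alpha[length(alpha)]
    } else if (length(meta) >= 2 && length(type_names) > 0) {
      ti <- suppressWarnings(as.integer(meta[2]))
      if (!is.na(ti) && ti >= 1 && ti <= length(type_names))
        label <- type_names[ti]
    }
    domain <- if (is.na(label) || tolower(label) == "default") 0L
              else .domain_from_name(label)

    xy <- numeric(0)
    for (j in seq_along(seg_hdr)) {
      s0 <- seg_hdr[j] + 1
      s1 <- if (j < length(seg_hdr)) seg_hdr[j + 1] - 1 else length(block)
      vals <- suppressWarnings(as.numeric(block[s0:s1]))
      if (any(is.na(vals)))
        stop(sprintf("malformed NDF tracing block '%s': non-numeric coordinate",
                     name))
      xy <- c(xy, vals)
    }
    if (length(xy) %% 2 != 0)
      stop(sprintf("malformed NDF tracing block '%s': odd coordinate count",
                   name))
    n <- length(xy) / 2
    pts <- data.frame(x = xy[seq(1, by = 2, length.out = n)],
                      y = xy[seq(2, by = 2, length.out = n)],
                      z = 0, radius = 0.5)
    paths[[length(paths) + 1]] <-
      segment_path(pts, domain = domain, path_id = name)
  }
  paths_to_morphology(paths, source_format = "ndf")
}

# ---- Neurolucida ASC ---------------------------------------------------

# internal: tokenize parenthesized ASC text; ";" comments run to EOL
.asc_tokenize <- function(lines) {
  toks <- list()
  for (ln in seq_along(lines)) {
    line <- sub(";.*$", "", lines[ln])
    pat <- "\\(|\\)|\\||\"[^\"]*\"|[^()|\"[:space:]]+"
    mt <- regmatches(line, gregexpr(pat, line))[[1]]
    for (t in mt) toks[[length(toks) + 1]] <- list(text = t, line = ln)
  }
  toks
}

# internal: recursive-descent parse into nested lists; leaves are
# character scalars (symbols/strings/numbers)
.asc_parse <- function(toks) {
  pos <- 1L
  parse_list <- function(open_line) {
    out <- list()
    repeat {
      if (pos > length(toks)) {
        if (is.na(open_line)) return(out)
        stop(sprintf("unbalanced parentheses: '(' at line %d never closed",
                     open_line))
      }
      tk <- toks[[pos]]
      if (tk$text == "(") {
        pos <<- pos + 1L
        out[[length(out) + 1]] <- parse_list(tk$line)
      } else if (tk$text == ")") {
        if (is.na(open_line))
          stop(sprintf("unbalanced parentheses: stray ')' at line %d",
                       tk$line))
        pos <<- pos + 1L
        return(out)
      } else {
        pos <<- pos + 1L
        out[[length(out) + 1]] <- tk$text
      }
    }
  }
  parse_list(NA)
}

# internal: is a parsed element a coordinate point (x y z [d])?
.asc_is_point <- function(el) {
  is.list(el) && length(el) %in% c(3, 4) &&
    all(vapply(el, function(x) is.character(x) &&
                 !is.na(suppressWarnings(as.numeric(x))), logical(1)))
}

.asc_point <- function(el) {
  v <- as.numeric(unlist(el))
  data.frame(x = v[1], y = v[2], z = v[3],
             radius = if (length(v) == 4) v[4] / 2 else NA_real_)
}

#' Convert a Neurolucida ASC file to a morphology
#'
#' Pinned dialect: top-level parenthesized forms. A form opening with a
#' quoted string is a contour; contours named "CellBody" (or carrying a
#' \code{(CellBody)} keyword) become soma paths subject to the
#' downstream curvature test, other contours are skipped with a note. A
#' form opening with a keyword sub-list -- \code{(Dendrite)},
#' \code{(Axon)}, \code{(Apical)}, \code{(CellBody)} -- is a tree of
#' that domain: coordinate quadruples \code{(x y z d)} are points with
#' radius d/2, nested lists with \code{|}-separated alternatives are
#' daughter branches, and any other keyword block (Color, Spine,
#' markers, fonts) is skipped with a note.
#'
#' @param text File path or ASC text.
#' @return An \code{swc_morphology} (source_format "asc").
#' @export
asc_to_morphology <- function(text) {
  lines <- .text_lines(text)
  forms <- .asc_parse(.asc_tokenize(lines))
  paths <- list()
  notes <- character(0)
  counter <- 0

  new_id <- function() { counter <<- counter + 1; sprintf("asc%03d", counter) }

  is_keyword_list <- function(el)
    is.list(el) && length(el) >= 1 && is.character(el[[1]]) &&
      grepl("^[A-Za-z]", el[[1]]) && !.asc_is_point(el)

  # elements: points, branch-lists, keyword blocks. Emits one path and
  # recurses into branches.
  build_tree <- function(elements, domain, parent_id, attach_pos) {
    pts <- NULL
    branch <- NULL
    for (el in elements) {
      if (.asc_is_point(el)) {
        pts <- rbind(pts, .asc_point(el))
      } else if (is.list(el) && any(vapply(el, identical, logical(1), "|"))) {
        branch <- el
      } else if (is_keyword_list(el)) {
        notes <<- c(notes, sprintf("skipped '%s' block", el[[1]]))
      } else if (is.character(el)) {
        # stray atom (e.g. Normal) -- annotation, skip silently
      } else if (is.list(el)) {
        # unmarked sub-list without '|': single daughter branch
        branch <- c(el, list("|"))
      }
    }
    id <- NULL
    if (!is.null(pts) && nrow(pts) > 0) {
      id <- new_id()
      paths[[length(paths) + 1]] <<- segment_path(
        pts, domain = domain, path_id = id,
        parent_path = if (is.null(parent_id)) NA_character_ else parent_id,
        attach_pos = if (is.null(parent_id)) NA_integer_ else attach_pos)
    }
    if (!is.null(branch)) {
      seps <- which(vapply(branch, identical, logical(1), "|"))
      bounds <- c(0, seps, length(branch) + 1)
      anchor_id <- if (!is.null(id)) id else parent_id
      anchor_pos <- if (!is.null(id)) nrow(pts) else attach_pos
      for (b in seq_len(length(bounds) - 1)) {
        sub <- branch[seq_len(bounds[b + 1] - 1 - bounds[b]) + bounds[b]]
        sub <- Filter(function(e) !identical(e, "|"), sub)
        if (length(sub) > 0)
          build_tree(sub, domain, anchor_id, anchor_pos)
      }
    }
    invisible(NULL)
  }

  for (form in forms) {
    if (!is.list(form)) next
    if (length(form) >= 1 && is.character(form[[1]]) &&
        startsWith(form[[1]], "\"")) {
      cname <- gsub("\"", "", form[[1]])
      has_cellbody_kw <- any(vapply(form, function(el)
        is.list(el) && length(el) == 1 && identical(el[[1]], "CellBody"),
        logical(1)))
      if (grepl("cellbody|soma", tolower(cname)) || has_cellbody_kw) {
        pts <- do.call(rbind, lapply(Filter(.asc_is_point, form), .asc_point))
        if (!is.null(pts) && nrow(pts) > 0)
          paths[[length(paths) + 1]] <-
            segment_path(pts, domain = 1L, path_id = new_id())
      } else {
        notes <- c(notes, sprintf("skipped contour \"%s\"", cname))
      }
    } else {
      kw <- Find(function(el) is.list(el) && length(el) == 1 &&
                   is.character(el[[1]]), form)
      domain <- if (!is.null(kw)) .domain_from_name(kw[[1]]) else 0L
      body <- Filter(function(el)
        !(is.list(el) && length(el) == 1 && is.character(el[[1]])), form)
      build_tree(body, domain, NULL, NA)
    }
  }
  m <- paths_to_morphology(paths, source_format = "asc")
  m$notes <- notes
  m
}

# ---- NEURON HOC --------------------------------------------------------

#' Convert a NEURON HOC script (geometry subset) to a morphology
#'
#' Pinned grammar: \code{create} statements declare sections (array
#' declarations \code{name[n]} expand to \code{name[0]}..\code{name[n-1]});
#' \code{connect child(0), parent(x)} statements attach the child's
#' 0-end at fraction x along the parent (\code{child(1)} reverses the
#' child's points); \code{section \{ pt3dadd(x,y,z,d) ... \}} blocks
#' supply the 3-D points with radius d/2. Section names containing
#' soma/axon/dend/apic map to types 1/2/3/4, anything else to 0.
#' Sections declared without any points are dropped with a note.
#'
#' @param text File path or HOC text.
#' @return An \code{swc_morphology} (source_format "hoc").
#' @export
hoc_to_morphology <- function(text) {
  lines <- .text_lines(text)
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("/\\*.*?\\*/", " ", txt)        # block comments
  txt <- gsub("//[^\n]*", "", txt)            # line comments

  sec_rx <- "[A-Za-z_][A-Za-z0-9_]*(\\[[0-9]+\\])?"
  sections <- character(0)
  for (mt in regmatches(txt, gregexpr(
    "create\\s+[A-Za-z_][][A-Za-z0-9_, \t]*", txt))[[1]]) {
    decl <- trimws(sub("^create\\s+", "", mt))
    for (d in trimws(strsplit(decl, ",")[[1]])) {
      arr <- regmatches(d, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\[([0-9]+)\\]$", d))[[1]]
      if (length(arr) == 3) {
        n <- as.integer(arr[3])
        sections <- c(sections, sprintf("%s[%d]", arr[2], seq_len(n) - 1))
      } else if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", d)) {
        sections <- c(sections, d)
      }
    }
  }
  if (length(sections) == 0) stop("no create statements found")

  # connect statements
  conn <- list()
  con_rx <- sprintf(
    "connect\\s+(%s)\\s*\\(([0-9.]+)\\)\\s*,\\s*(%s)\\s*\\(([0-9.]+)\\)",
    sec_rx, sec_rx)
  for (mt in regmatches(txt, gregexpr(con_rx, txt))[[1]]) {
    g <- regmatches(mt, regexec(con_rx, mt))[[1]]
    child <- g[2]; cend <- as.numeric(g[4])
    parent <- g[5]; ppos <- as.numeric(g[7])
    if (!(child %in% sections))
      stop(sprintf("connect references undeclared section '%s'", child))
    if (!(parent %in% sections))
      stop(sprintf("connect references undeclared section '%s'", parent))
    conn[[child]] <- list(parent = parent, child_end = cend,
                          parent_frac = ppos)
  }

  # section { ... pt3dadd ... } blocks
  pts_of <- stats::setNames(vector("list", length(sections)), sections)
  blk_rx <- sprintf("(%s)\\s*\\{([^}]*)\\}", sec_rx)
  for (mt in regmatches(txt, gregexpr(blk_rx, txt))[[1]]) {
    g <- regmatches(mt, regexec(blk_rx, mt))[[1]]
    name <- g[2]; body <- g[4]
    if (!(name %in% sections)) next
    num <- "[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?"
    pa_rx <- sprintf("pt3dadd\\(\\s*(%s)\\s*,\\s*(%s)\\s*,\\s*(%s)\\s*,\\s*(%s)\\s*\\)",
                     num, num, num, num)
    pts <- NULL
    for (pm in regmatches(body, gregexpr(pa_rx, body))[[1]]) {
      pg <- regmatches(pm, regexec(pa_rx, pm))[[1]]
      v <- as.numeric(pg[c(2, 4, 6, 8)])
      pts <- rbind(pts, data.frame(x = v[1], y = v[2], z = v[3],
                                   radius = v[4] / 2))
    }
    if (!is.null(pts)) pts_of[[name]] <- rbind(pts_of[[name]], pts)
  }

  notes <- character(0)
  empty <- names(Filter(is.null, pts_of))
  for (e in empty)
    notes <- c(notes, sprintf("section '%s' has no 3-D points; dropped", e))
  keep <- setdiff(sections, empty)

  paths <- list()
  for (name in keep) {
    pts <- pts_of[[name]]
    cn <- conn[[name]]
    parent_id <- NA_character_; attach_pos <- NA_integer_
    if (!is.null(cn) && cn$parent %in% keep) {
      if (cn$child_end == 1) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      np <- nrow(pts_of[[cn$parent]])
      attach_pos <- max(1L, min(np, round(cn$parent_frac * (np - 1)) + 1L))
      parent_id <- cn$parent
    }
    paths[[length(paths) + 1]] <-
      segment_path(pts, domain = .domain_from_name(name), path_id = name,
                   parent_path = parent_id, attach_pos = attach_pos)
  }
  m <- paths_to_morphology(paths, source_format = "hoc")
  m$notes <- notes
  m
}

# ---- Eutectic NTS ------------------------------------------------------

.nts_origin_domains <- c(MTO = 2L, DTO = 3L, BTO = 4L, TTO = 6L, SOS = 1L)
.nts_known <- c(names(.nts_origin_domains),
                "CP", "SCP", "FS", "BP", "NE", "ES", "MAE", "TAE", "BAE",
                "SOE")

#' Convert a Eutectic NTS point list to a morphology
#'
#' Reverse-engineered point-per-line dialect: each data line holds an
#' optional point number, a type mnemonic, x, y, z and thickness
#' (radius = thickness/2). Tree-origin mnemonics start a new tree and
#' set its domain (MTO axon, DTO basal dendrite, BTO apical dendrite,
#' TTO unspecified neurite, SOS soma outline); CP/SCP/FS continue the
#' current branch; BP marks a branch point (pushed on a stack); NE, ES,
#' MAE, TAE, BAE and SOE end a branch, popping the stack so the next
#' point attaches at the most recent open branch point. Unknown
#' mnemonics are an error.
#'
#' @param text File path or NTS text.
#' @return An \code{swc_morphology} (source_format "nts").
#' @export
nts_to_morphology <- function(text) {
  lines <- trimws(.text_lines(text))
  lines <- lines[lines != "" & !startsWith(lines, ";") &
                   !startsWith(lines, "#")]
  rows <- list()
  counter <- 0L
  parent <- -1L
  domain <- 0L
  stack <- integer(0)

  for (ln in seq_along(lines)) {
    tok <- strsplit(lines[ln], "[ \t]+")[[1]]
    if (grepl("^[0-9]+$", tok[1])) tok <- tok[-1]
    mnem <- toupper(tok[1])
    if (!(mnem %in% .nts_known))
      stop(sprintf("unknown NTS mnemonic '%s' at line %d", tok[1], ln))
    v <- suppressWarnings(as.numeric(tok[2:5]))
    if (length(tok) < 5 || any(is.na(v)))
      stop(sprintf("malformed NTS point at line %d", ln))
    if (mnem %in% names(.nts_origin_domains)) {
      parent <- -1L
      domain <- .nts_origin_domains[[mnem]]
      stack <- integer(0)
    }
    counter <- counter + 1L
    rows[[counter]] <- data.frame(index = counter, type = domain,
                                  x = v[1], y = v[2], z = v[3],
                                  radius = v[4] / 2, parent = parent)
    if (mnem == "BP") {
      stack <- c(stack, counter)
      parent <- counter
    } else if (mnem %in% c("NE", "ES", "MAE", "TAE", "BAE", "SOE")) {
      if (length(stack) > 0) {
        parent <- stack[length(stack)]
        stack <- stack[-length(stack)]
      } else {
        parent <- -1L
      }
    } else {
      parent <- counter
    }
  }
  if (counter == 0L)
    return(morphology(samples = data.frame(
      index = numeric(0), type = numeric(0), x = numeric(0), y = numeric(0),
      z = numeric(0), radius = numeric(0), parent = numeric(0)),
      source_format = "nts"))
  morphology(samples = do.call(rbind, rows), source_format = "nts")
}

# ---- extended SWC ------------------------------------------------------

#' Convert an extended SWC (ESWC) file to a morphology
#'
#' The first seven columns form the SWC samples; columns eight and
#' beyond are preserved into the footer, one "# eswc <index> ..." line
#' per sample keyed by the index as parsed from the source. Rows with
#' inconsistent column counts are an error.
#'
#' @param text File path or ESWC text.
#' @return An \code{swc_morphology} (source_format "eswc").
#' @export
eswc_to_morphology <- function(text) {
  res <- read_swc(text, source_format = "eswc")
  m <- res$morphology
  if (is.null(m) || length(m$raw) == 0) {
    if (!is.null(m)) m$source_format <- "eswc"
    return(m)
  }
  lens <- lengths(m$raw)
  if (length(unique(lens)) != 1)
    stop(sprintf("ragged ESWC rows: column counts %s",
                 paste(sort(unique(lens)), collapse = ", ")))
  ncol <- lens[1]
  if (ncol == 7) return(m)
  if (ncol < 7) stop("ESWC rows have fewer than seven columns")
  extra <- vapply(m$raw, function(tok)
    paste(tok[8:ncol], collapse = " "), character(1))
  idx <- vapply(m$raw, function(tok) tok[1], character(1))
  m$footer <- c(m$footer, sprintf("# eswc %s %s", idx, extra))
  m$raw <- lapply(m$raw, function(tok) tok[1:7])
  m$samples <- tokens_to_samples(do.call(rbind, m$raw))
  m
}
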