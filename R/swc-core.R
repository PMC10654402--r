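#' @title SWC morphology data model
#'
#' @description An \code{swc_morphology} holds one skeletonized neural
#'   reconstruction: an ordered table of sample points (index, type, x, y,
#'   z, radius, parent), the "#"-prefixed header lines that precede the
#'   data, the "#"-prefixed footer lines that follow it, and a tag naming
#'   the source format. Sample order equals file row order. When the
#'   object was parsed from text, the raw field tokens of every data line
#'   are retained so that the specification checks can inspect the exact
#'   spelling of each value ("1.00" versus "1", "NA" versus a number).
#' @name swc_morphology
NULL

#' Construct a morphology object
#'
#' @param samples Data frame with numeric columns \code{index},
#'   \code{type}, \code{x}, \code{y}, \code{z}, \code{radius},
#'   \code{parent}, or \code{NULL} when the raw rows are not (yet)
#'   interpretable.
#' @param header Character vector of header lines (each starting "#").
#' @param footer Character vector of footer lines (each starting "#").
#' @param source_format Tag naming the source dialect (e.g. "swc", "asc").
#' @param raw Optional list of character vectors: the whitespace-split
#'   tokens of each data line as read from the source.
#' @param raw_lines Optional integer vector: the 1-based file line number
#'   of each data row.
#' @param notes Character vector of free-form conversion notes.
#' @return An object of class \code{swc_morphology}.
#' @export
morphology <- function(samples = NULL, header = character(0),
                       footer = character(0), source_format = "swc",
                       raw = NULL, raw_lines = NULL,
                       notes = character(0)) {
  if (!is.null(samples)) {
    need <- c("index", "type", "x", "y", "z", "radius", "parent")
    stopifnot(all(need %in% names(samples)))
    samples <- samples[, need, drop = FALSE]
    rownames(samples) <- NULL
  }
  if (is.null(raw_lines) && !is.null(raw)) raw_lines <- seq_along(raw)
  structure(list(samples = samples, header = as.character(header),
                 footer = as.character(footer),
                 source_format = source_format,
                 raw = raw, raw_lines = raw_lines, notes = notes),
            class = "swc_morphology")
}

#' Number of sample points in a morphology
#' @param m An \code{swc_morphology}.
#' @return Integer count of data rows.
#' @export
n_samples <- function(m) {
  if (!is.null(m$samples)) nrow(m$samples)
  else if (!is.null(m$raw)) length(m$raw)
  else 0L
}

#' @export
print.swc_morphology <- function(x, ...) {
  cat(sprintf("<swc_morphology> %d samples, %d header / %d footer lines (source: %s)\n",
              n_samples(x), length(x$header), length(x$footer),
              x$source_format))
  if (!is.null(x$samples) && nrow(x$samples) > 0) {
    n_roots <- sum(x$samples$parent == -1, na.rm = TRUE)
    cat(sprintf("  roots: %d; types present: %s\n", n_roots,
                paste(sort(unique(x$samples$type)), collapse = " ")))
  }
  invisible(x)
}

# ---- raw-token helpers -------------------------------------------------

# internal: n x 7 character matrix of field tokens; synthesized from the
# numeric samples when the morphology was built in memory
token_matrix <- function(m) {
  if (!is.null(m$raw)) {
    lens <- lengths(m$raw)
    if (length(lens) > 0 && !all(lens == 7L))
      stop("raw rows are ragged; run check_shape first")
    if (length(m$raw) == 0) return(matrix(character(0), ncol = 7))
    do.call(rbind, m$raw)
  } else if (!is.null(m$samples)) {
    s <- m$samples
    cbind(fmt_swc_int(s$index), fmt_swc_int(s$type),
          fmt_swc_float(s$x), fmt_swc_float(s$y), fmt_swc_float(s$z),
          fmt_swc_float(s$radius), fmt_swc_int(s$parent))
  } else {
    matrix(character(0), ncol = 7)
  }
}

# internal: install a rectangular token matrix, refreshing the numeric view
set_tokens <- function(m, mat) {
  m$raw <- lapply(seq_len(nrow(mat)), function(i) mat[i, ])
  if (is.null(m$raw_lines) || length(m$raw_lines) != nrow(mat))
    m$raw_lines <- seq_len(nrow(mat))
  m$samples <- tokens_to_samples(mat)
  m
}

# internal: lenient numeric interpretation of a token matrix (NA where a
# field does not parse); used to refresh m$samples between check stages
tokens_to_samples <- function(mat) {
  num <- function(j) suppressWarnings(as.numeric(mat[, j]))
  data.frame(index = num(1), type = num(2), x = num(3), y = num(4),
             z = num(5), radius = num(6), parent = num(7))
}

# ---- number formatting -------------------------------------------------

# internal: integers without decimal point
fmt_swc_int <- function(v) {
  vapply(v, function(x) format(x, scientific = FALSE, trim = TRUE),
         character(1))
}

#' Format floating-point SWC fields
#'
#' Produces the shortest decimal representation that parses back to the
#' stored double, always including a decimal point (so \code{0} prints as
#' \code{"0.0"}).
#'
#' @param v Numeric vector.
#' @return Character vector of the same length.
#' @export
fmt_swc_float <- function(v) {
  vapply(v, function(x) {
    if (!is.finite(x)) return(as.character(x))
    s <- NULL
    for (d in 1:17) {
      cand <- formatC(x, digits = d, format = "g", width = -1)
      if (!is.na(suppressWarnings(as.numeric(cand))) &&
          as.numeric(cand) == x) { s <- cand; break }
    }
    if (is.null(s)) s <- sprintf("%.17g", x)
    if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
    s
  }, character(1))
}

# ---- reading -----------------------------------------------------------

# internal: turn path / single string / vector of lines into lines + an
# ASCII flag
.as_swc_lines <- function(x) {
  if (length(x) == 1 && !grepl("[\n\r]", x) && file.exists(x)) {
    bytes <- readBin(x, "raw", n = file.info(x)$size)
    ascii <- all(bytes <= as.raw(0x7f))
    txt <- rawToChar(bytes[bytes != as.raw(0)])
    lines <- strsplit(txt, "\r\n|\n|\r")[[1]]
  } else {
    txt <- paste(x, collapse = "\n")
    ascii <- all(utf8ToInt(txt) <= 127L)
    lines <- strsplit(txt, "\r\n|\n|\r")[[1]]
  }
  list(lines = lines, ascii = ascii)
}

#' Read an SWC file
#'
#' Parses SWC text into a morphology plus a check log. Every non-"#" line
#' is split on runs of whitespace into raw field tokens and stored as a
#' provisional sample; no repair is performed at this stage. "#" lines
#' before the first data line form the header, after the last data line
#' the footer; "#" lines interleaved between data lines are attached to
#' the footer with an informational log entry.
#'
#' @param x A file path, a single string containing the whole file, or a
#'   character vector of lines.
#' @param source_format Tag recorded on the morphology (default "swc").
#' @return A list with elements \code{morphology} (an
#'   \code{swc_morphology}, or \code{NULL} if the input is not
#'   ASCII-encoded) and \code{log} (an \code{swc_check_log}).
#' @export
read_swc <- function(x, source_format = "swc") {
  log <- check_log()
  inp <- .as_swc_lines(x)
  if (!inp$ascii) {
    log <- log_add(log, "File Encoding", "error",
                   "not ASCII-encoded, possibly mislabeled file")
    return(list(morphology = NULL, log = log))
  }
  lines <- inp$lines
  trimmed <- trimws(lines)
  is_comment <- startsWith(trimmed, "#")
  is_blank <- trimmed == ""
  is_data <- !is_comment & !is_blank
  data_idx <- which(is_data)

  if (length(data_idx) == 0) {
    log <- log_add(log, "Number of Lines", "error", "no samples detected")
    m <- morphology(samples = NULL, header = lines[is_comment],
                    source_format = source_format,
                    raw = list(), raw_lines = integer(0))
    return(list(morphology = m, log = log))
  }

  first_d <- min(data_idx); last_d <- max(data_idx)
  header <- trimmed[is_comment & seq_along(lines) < first_d]
  footer_tail <- trimmed[is_comment & seq_along(lines) > last_d]
  inter <- which(is_comment & seq_along(lines) > first_d &
                   seq_along(lines) < last_d)
  footer <- c(trimmed[inter], footer_tail)
  if (length(inter) > 0)
    log <- log_add(log, "Comment Placement", "info",
                   "comment lines interleaved with data; attached to footer",
                   lines = inter)

  raw <- strsplit(trimmed[data_idx], "[ \t]+")
  samples <- NULL
  if (all(lengths(raw) == 7L))
    samples <- tokens_to_samples(do.call(rbind, raw))
  m <- morphology(samples = samples, header = header, footer = footer,
                  source_format = source_format, raw = raw,
                  raw_lines = data_idx)
  list(morphology = m, log = log)
}

#' Write a morphology as SWC text
#'
#' Emits the header lines, one line per sample with the seven fields
#' separated by single spaces (index, type and parent as integers; x, y,
#' z and radius as decimal floats), then the footer lines. Output uses LF
#' line endings and is plain ASCII.
#'
#' @param m An \code{swc_morphology} with numeric samples, or one whose
#'   raw tokens should be dumped verbatim (set \code{raw = TRUE}).
#' @param path Optional file path; when given the text is written there.
#' @param raw If \code{TRUE} and raw tokens are present, emit them
#'   unchanged (space-joined) instead of reformatting from the numeric
#'   samples.
#' @return Character vector of output lines, invisibly when \code{path}
#'   is given.
#' @export
write_swc <- function(m, path = NULL, raw = FALSE) {
  stopifnot(inherits(m, "swc_morphology"))
  if (raw && !is.null(m$raw)) {
    body <- vapply(m$raw, paste, character(1), collapse = " ")
  } else {
    if (is.null(m$samples))
      stop("morphology has no interpretable samples; use raw = TRUE")
    mat <- cbind(fmt_swc_int(m$samples$index), fmt_swc_int(m$samples$type),
                 fmt_swc_float(m$samples$x), fmt_swc_float(m$samples$y),
                 fmt_swc_float(m$samples$z), fmt_swc_float(m$samples$radius),
                 fmt_swc_int(m$samples$parent))
    body <- apply(mat, 1, paste, collapse = " ")
    if (nrow(m$samples) == 0) body <- character(0)
  }
  out <- c(m$header, body, m$footer)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(out, con, sep = "\n")
    return(invisible(out))
  }
  out
}

# ---- header metadata ---------------------------------------------------

#' Recommended metadata tags for SWC headers
#' @return Character vector of tag names (compared case-insensitively).
#' @export
swc_metadata_tags <- function() {
  c("contributor", "reference", "creature", "sex", "age", "weight",
    "region", "class", "condition", "label", "slicing", "microscopy",
    "coordinate", "brainspace", "original_source")
}

#' Parse the metadata header of a morphology
#'
#' Each header line of the form \code{"#tag value..."} yields one
#' (tag, value) entry; tags are compared case-insensitively against the
#' recommended set but unknown word-like tags are kept as-is. Lines
#' without a leading word-like tag are preserved verbatim with tag
#' \code{"raw"}.
#'
#' @param m An \code{swc_morphology}.
#' @return Data frame with character columns \code{tag} and \code{value},
#'   one row per header line, in header order.
#' @export
parse_metadata_header <- function(m) {
  out <- data.frame(tag = character(0), value = character(0),
                    stringsAsFactors = FALSE)
  for (line in m$header) {
    body <- sub("^\\s*#", "", line)
    # a tag must follow the "#" immediately; "# free text" stays raw
    mt <- regmatches(body, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*(.*)$", body))[[1]]
    if (length(mt) == 3) {
      tag <- mt[2]
      if (tolower(tag) %in% swc_metadata_tags()) tag <- tolower(tag)
      out <- rbind(out, data.frame(tag = tag, value = mt[3],
                                   stringsAsFactors = FALSE))
    } else {
      out <- rbind(out, data.frame(tag = "raw", value = line,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# ---- synapse footer ----------------------------------------------------

#' Parse the synapse block of a morphology footer
#'
#' Synaptic connectivity lives in the footer between a
#' \code{"#start synapse"} and an \code{"#end synapse"} line. Each record
#' line in between carries, after the "#" sign, nine fields: synapse id;
#' x, y, z position; nearest node (an SWC index); direction (0 output,
#' 1 input); structural domain code; partner neuron id; and putative
#' neurotransmitter. A field-legend line preceding the first record is
#' skipped. Footer content outside the delimiters is ignored.
#'
#' @param m An \code{swc_morphology}.
#' @return Data frame with one row per synapse record (possibly zero
#'   rows), columns \code{synapse_id}, \code{x}, \code{y}, \code{z},
#'   \code{nearest_node}, \code{direction}, \code{domain},
#'   \code{partner_id}, \code{neurotransmitter}.
#' @export
parse_synapse_footer <- function(m) {
  empty <- data.frame(synapse_id = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0),
                      nearest_node = integer(0), direction = integer(0),
                      domain = integer(0), partner_id = character(0),
                      neurotransmitter = character(0),
                      stringsAsFactors = FALSE)
  foot <- trimws(m$footer)
  start <- which(grepl("^#\\s*start synapse\\s*$", foot, ignore.case = TRUE))
  end <- which(grepl("^#\\s*end synapse\\s*$", foot, ignore.case = TRUE))
  if (length(start) == 0 || length(end) == 0) return(empty)
  start <- start[1]; end <- end[end > start][1]
  if (is.na(end) || end <= start + 1) return(empty)

  block <- foot[(start + 1):(end - 1)]
  parse_one <- function(line) strsplit(trimws(sub("^\\s*#", "", line)),
                                       "[ \t]+")[[1]]
  looks_like_record <- function(tok) {
    length(tok) == 9 &&
      !any(is.na(suppressWarnings(as.numeric(tok[2:4])))) &&
      tok[6] %in% c("0", "1")
  }
  toks <- lapply(block, parse_one)
  if (length(toks) > 0 && !looks_like_record(toks[[1]])) {
    # field-legend line preceding the first record
    block <- block[-1]; toks <- toks[-1]
  }
  if (length(toks) == 0) return(empty)

  recs <- empty
  for (i in seq_along(toks)) {
    tok <- toks[[i]]
    if (length(tok) != 9)
      stop(sprintf("synapse record '%s' has %d fields; 9 expected",
                   block[i], length(tok)))
    node <- suppressWarnings(as.integer(tok[5]))
    if (!is.null(m$samples) && (is.na(node) ||
                                !(node %in% m$samples$index)))
      stop(sprintf("synapse record '%s': nearest node %s not in morphology",
                   block[i], tok[5]))
    recs <- rbind(recs, data.frame(
      synapse_id = tok[1],
      x = as.numeric(tok[2]), y = as.numeric(tok[3]), z = as.numeric(tok[4]),
      nearest_node = node, direction = as.integer(tok[6]),
      domain = as.integer(tok[7]), partner_id = tok[8],
      neurotransmitter = tok[9], stringsAsFactors = FALSE))
  }
  recs
}

# ---- node classification ----------------------------------------------

# internal: number of children of each row, rows matched by index value
child_counts <- function(samples) {
  pos <- match(samples$parent, samples$index)
  tabulate(pos[!is.na(pos) & samples$parent != -1], nbins = nrow(samples))
}

#' Classify every sample point by its topological role
#'
#' A point with two or more children is a bifurcation (or
#' multifurcation); otherwise a point with parent \code{-1} is a root, a
#' childless point is a terminal, and the rest are continuation points.
#'
#' @param m An \code{swc_morphology} with numeric samples.
#' @return Character vector, named by sample index, with values
#'   \code{"root"}, \code{"continuation"},
#'   \code{"bifurcation_or_multifurcation"} or \code{"terminal"}.
#' @export
classify_nodes <- function(m) {
  s <- m$samples
  if (is.null(s)) stop("morphology has no interpretable samples")
  nonroot <- s$parent != -1
  bad <- nonroot & !(s$parent %in% s$index)
  if (any(bad))
    stop(sprintf("unresolvable parent(s) at row(s) %s",
                 paste(which(bad), collapse = ",")))
  kids <- child_counts(s)
  cls <- ifelse(kids >= 2, "bifurcation_or_multifurcation",
                ifelse(s$parent == -1, "root",
                       ifelse(kids == 0, "terminal", "continuation")))
  names(cls) <- s$index
  cls
}
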