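# Shared helpers: quick morphology construction and brute-force oracles.

# build a morphology from vectors (recycled where scalar)
make_morph <- function(index, type, x, y = 0, z = 0, radius = 1, parent) {
  n <- length(index)
  morphology(samples = data.frame(
    index = index, type = rep_len(type, n), x = rep_len(x, n),
    y = rep_len(y, n), z = rep_len(z, n), radius = rep_len(radius, n),
    parent = parent))
}

# a linear chain of n points, types all `type`
chain_morph <- function(n, type = 3) {
  make_morph(seq_len(n), type, x = seq_len(n) - 1,
             parent = c(-1, seq_len(n - 1)))
}

# brute-force (depth, subtree size) multiset over selected rows; oracle
# for structure preservation, independent of the package's sorting code
depth_subtree_multiset <- function(samples, keep = rep(TRUE, nrow(samples))) {
  n <- nrow(samples)
  pos <- match(samples$parent, samples$index)
  depth <- function(i) {
    d <- 0
    while (samples$parent[i] != -1) { i <- pos[i]; d <- d + 1 }
    d
  }
  subtree_size <- function(i) {
    count <- 1
    kids <- which(pos == i & samples$parent != -1)
    for (k in kids) count <- count + subtree_size(k)
    count
  }
  out <- vapply(which(keep), function(i)
    paste(depth(i), subtree_size(i), sep = ":"), character(1))
  sort(out)
}

# brute-force topology summary used by round-trip tests
topo_summary <- function(m) {
  s <- m$samples
  pos <- match(s$parent, s$index)
  kids <- tabulate(pos[!is.na(pos) & s$parent != -1], nbins = nrow(s))
  nonroot <- which(s$parent != -1)
  cable <- sum(sqrt((s$x[nonroot] - s$x[pos[nonroot]])^2 +
                      (s$y[nonroot] - s$y[pos[nonroot]])^2 +
                      (s$z[nonroot] - s$z[pos[nonroot]])^2))
  list(n = nrow(s),
       roots = sum(s$parent == -1),
       bifurcations = sum(kids >= 2),
       terminals = sum(kids == 0),
       cable = cable)
}

# a section object for raw coordinate triples (bypasses tree extraction)
section_from_coords <- function(coords) {
  structure(list(coords = coords, swc_indices = seq_len(nrow(coords)),
                 rows = seq_len(nrow(coords)), n = nrow(coords),
                 first_is_root = TRUE, terminal_kind = "terminal",
                 testable = nrow(coords) >= 3),
            class = "soma_section")
}

# did this check id fire (as a warning/error or as a correction)?
triggered <- function(log, id) {
  any(log$check_id == id & (log$severity %in% c("warning", "error") |
                              log$corrective))
}

example_14pt_path <- function() {
  system.file("extdata", "example_14pt.swc", package = "swcforge")
}
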