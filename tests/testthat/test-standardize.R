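# One test block per stage of the check battery, plus pipeline-level
# properties (execution order, idempotence, structure preservation).

test_that("shape checks catch missing fields, short files and absent somata", {
  res <- read_swc(c("1 1 0.0 0.0 0.0 1.0 -1", "2 3 1.0 0.0 0.0 1.0"))
  cs <- check_shape(res$morphology)
  expect_true(has_errors(cs$log))
  expect_equal(cs$log$check_id, "Missing Field")

  res <- read_swc(example_14pt_path())
  cs <- check_shape(res$morphology)
  expect_true(any(cs$log$check_id == "Number of Lines" &
                    cs$log$severity == "warning"))

  m25 <- chain_morph(25, type = 3)
  cs <- check_shape(m25)
  expect_false(any(cs$log$check_id == "Number of Lines"))
  expect_true(any(cs$log$check_id == "Number of Soma Samples" &
                    cs$log$severity == "warning"))
})

test_that("invalid parents become roots with a warning", {
  m <- make_morph(1:3, 3, x = 0:2, parent = c(-1, 1, 99))
  res <- fix_invalid_parents(m)
  expect_equal(res$morphology$samples$parent, c(-1, 1, -1))
  expect_true(triggered(res$log, "Invalid Parent"))

  m <- chain_morph(3)
  res <- fix_invalid_parents(m)
  expect_equal(nrow(res$log), 0)
  expect_equal(res$morphology$samples$parent, c(-1, 1, 2))

  # self-parent cannot be a previously declared index: becomes a root
  m <- make_morph(1:2, 3, x = 0:1, parent = c(-1, 2))
  res <- fix_invalid_parents(m)
  expect_equal(res$morphology$samples$parent, c(-1, -1))
  expect_true(triggered(res$log, "Invalid Parent"))
})

test_that("index/parent coercion fixes float-formatted integers only", {
  res <- read_swc(c("1 1 0.0 0.0 0.0 1.0 -1", "2 3 1.0 0.0 0.0 1.0 1",
                    "3.00 3 2.0 0.0 0.0 1.0 2"))
  out <- coerce_index_parent(res$morphology)
  expect_equal(out$morphology$samples$index, 1:3)
  expect_equal(out$log$severity, "info")
  expect_true(all(out$log$corrective))

  res <- read_swc("1.34 1 0.0 0.0 0.0 1.0 -1")
  out <- coerce_index_parent(res$morphology)
  expect_true(has_errors(out$log))

  res <- read_swc("1 1 0.0 0.0 0.0 1.0 -1")
  out <- coerce_index_parent(res$morphology)
  expect_equal(nrow(out$log), 0)
})

test_that("NaN/NA coordinates become 0.0 with a footer note", {
  res <- read_swc("1 1 0.0 NA 0.0 1.0 -1")
  out <- coerce_coordinates(res$morphology)
  expect_equal(out$morphology$samples$y, 0)
  expect_true(triggered(out$log, "XYZ Double"))
  expect_match(out$morphology$footer, "swcforge-note", all = FALSE)

  # case variants of NaN parse to NaN or fail to parse; all become 0.0
  for (bad in c("NaN", "nan", "NA", "na")) {
    res <- read_swc(sprintf("1 1 0.0 0.0 %s 1.0 -1", bad))
    out <- coerce_coordinates(res$morphology)
    expect_equal(out$morphology$samples$z, 0)
  }

  res <- read_swc("1 1 0.5 -1.5 2.0 1.0 -1")
  out <- coerce_coordinates(res$morphology)
  expect_equal(nrow(out$log), 0)
})

test_that("non-positive or unparseable radii become 0.5", {
  for (bad in c("-2.0", "0.0", "NaN", "NA")) {
    res <- read_swc(sprintf("1 1 0.0 0.0 0.0 %s -1", bad))
    out <- coerce_radius(res$morphology)
    expect_equal(out$morphology$samples$radius, 0.5)
    expect_true(triggered(out$log, "Radius Positive Double"))
  }
  res <- read_swc("1 1 0.0 0.0 0.0 1.25 -1")
  out <- coerce_radius(res$morphology)
  expect_equal(out$morphology$samples$radius, 1.25)
  expect_equal(nrow(out$log), 0)
})

test_that("type normalization handles markers at bifurcations/terminals", {
  # terminal typed 6 with parent type 3: topology-marker dialect
  m <- make_morph(1:3, c(1, 3, 6), x = 0:2, parent = c(-1, 1, 2))
  out <- normalize_types(m)
  expect_equal(out$morphology$samples$type, c(1, 3, 3))
  expect_true(triggered(out$log, "Non-Standard Type"))

  # continuation typed 6 is a legal unspecified neurite
  m <- make_morph(1:3, c(1, 6, 6), x = 0:2, parent = c(-1, 1, 2))
  out <- normalize_types(m)
  expect_equal(out$morphology$samples$type[2], 6)

  # non-numeric type becomes 0 'undefined'
  res <- read_swc("1 x 0.0 0.0 0.0 1.0 -1")
  out <- normalize_types(res$morphology)
  expect_equal(out$morphology$samples$type, 0)
  expect_true(triggered(out$log, "Non-Standard Type"))
})

test_that("re-sorting renumbers and puts parents before children", {
  # child listed before its parent
  res <- read_swc(c("1 1 0.0 0.0 0.0 1.0 -1", "2 3 2.0 0.0 0.0 1.0 3",
                    "3 3 1.0 0.0 0.0 1.0 1"))
  out <- resequence_and_sort(res$morphology)
  s <- out$morphology$samples
  expect_equal(s$index, 1:3)
  pos <- match(s$parent, s$index)
  expect_true(all(pos[s$parent != -1] < which(s$parent != -1)))
  expect_true(triggered(out$log, "Sorted Order"))

  # sparse indices renumber onto 1..N with parents remapped
  m <- make_morph(c(10, 20, 30), 3, x = 0:2, parent = c(-1, 10, 20))
  out <- resequence_and_sort(m)
  expect_equal(out$morphology$samples$index, 1:3)
  expect_equal(out$morphology$samples$parent, c(-1, 1, 2))
  expect_true(triggered(out$log, "Sequential Index"))

  # already standard: fixed point, byte-identical rewrite
  m <- generate_morphology(fixture_spec(seed = 4))
  before <- write_swc(m)
  out <- resequence_and_sort(m)
  expect_equal(write_swc(out$morphology), before)
  expect_false(any(out$log$corrective))

  # no root at all (mutual 2-cycle) is an unrepairable Sorted Order error
  m <- make_morph(1:2, 3, x = 0:1, parent = c(2, 1))
  m2 <- fix_invalid_parents(m)$morphology  # both parents exist: untouched
  out <- resequence_and_sort(m2)
  expect_true(has_errors(out$log))
  expect_equal(out$log$check_id[out$log$severity == "error"], "Sorted Order")
})

test_that("the battery runs in fixed order and reports seeded defects", {
  m <- generate_morphology(fixture_spec(seed = 11, n_branch_points = 3))
  defects <- c("Invalid Parent", "XYZ Double", "Radius Positive Double",
               "Non-Standard Type")
  txt <- corrupt_swc(m, defects, seed = 2)
  res <- standardize(read_swc(txt)$morphology)
  for (d in defects) expect_true(triggered(res$log, d), info = d)
  # entries appear in battery order
  fired <- unique(res$log$check_id[res$log$check_id %in% swc_check_ids()])
  expect_equal(fired, intersect(swc_check_ids(), fired))
  expect_false(res$is_standard)
  expect_true(standardize(res$morphology)$is_standard)
})

test_that("a standard file is recognized as standard", {
  res <- standardize(read_swc(example_14pt_path())$morphology)
  expect_true(res$is_standard)
  expect_false(any(res$log$corrective))
})

test_that("standardization is idempotent over many corrupt fixtures", {
  ids <- setdiff(swc_check_ids(),
                 c("Missing Field", "Number of Lines", "Sorted Order"))
  for (seed in 1:20) {
    m <- generate_morphology(fixture_spec(seed = seed))
    defect <- ids[(seed %% length(ids)) + 1]
    txt <- corrupt_swc(m, defect, seed = seed)
    first <- standardize(read_swc(txt)$morphology)
    if (is.null(first$morphology)) next  # unrepairable defects stay absent
    second <- standardize(first$morphology)
    expect_true(second$is_standard, info = sprintf("seed %d (%s)", seed, defect))
    expect_equal(second$morphology$samples, first$morphology$samples)
  }
})

test_that("re-sorting preserves tree structure (brute-force oracle)", {
  for (seed in 1:8) {
    m <- generate_morphology(fixture_spec(seed = seed, n_branch_points = 4))
    txt <- corrupt_swc(m, "Sorted Order", seed = seed)
    shuffled <- read_swc(txt)$morphology
    before <- depth_subtree_multiset(shuffled$samples)
    out <- resequence_and_sort(shuffled)
    after <- depth_subtree_multiset(out$morphology$samples)
    expect_equal(after, before)
  }
})

test_that("check-only mode never mutates and returns no morphology", {
  path <- tempfile(fileext = ".swc")
  m <- generate_morphology(fixture_spec(seed = 3))
  writeLines(corrupt_swc(m, "Radius Positive Double", seed = 1), path)
  hash_before <- unname(tools::md5sum(path))
  res <- standardize(read_swc(path)$morphology, repair = FALSE)
  expect_null(res$morphology)
  expect_false(res$is_standard)
  expect_true(triggered(res$log, "Radius Positive Double"))
  expect_equal(unname(tools::md5sum(path)), hash_before)
})

test_that("terminal errors abort the battery", {
  res <- standardize(read_swc(c("# nothing", "# here"))$morphology)
  expect_true(has_errors(res$log))
  expect_null(res$morphology)
  expect_equal(nrow(res$log), 1)  # nothing runs after a terminal error

  res <- standardize(read_swc("1 1 0.0 0.0 1.0")$morphology)
  expect_equal(res$log$check_id[1], "Missing Field")
  expect_null(res$morphology)
})
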