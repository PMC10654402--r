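# Per-dialect conversion fixtures are built in code; expected topology
# is verified with the brute-force summary oracle from the helper.

test_that("format detection uses extension then content sniffing", {
  knossos <- c("<things>", '<thing id="1"><nodes/><edges/></thing>',
               "</things>")
  expect_equal(detect_format(knossos), "knossos_nml")
  nml2 <- c('<neuroml xmlns="http://www.neuroml.org/schema/neuroml2">',
            "</neuroml>")
  expect_equal(detect_format(nml2), "neuroml")

  expect_equal(detect_format("1 1 0.0 0.0 0.0 1.0 -1"), "swc")
  expect_equal(detect_format("1 1 0.0 0.0 0.0 1.0 -1 7 8 9 10"), "eswc")

  p <- tempfile(fileext = ".asc"); writeLines("( (Dendrite) (0 0 0 1) )", p)
  expect_equal(detect_format(p), "asc")
  expect_error(detect_format("<mystery/>"), "unsupported")
})

test_that("NDF conversion inserts uniform radius 0.5 and z 0", {
  ndf <- c("// NeuronJ Data File - version 1.4.2",
           "// Type names and colors", "Default", "black", "Axon", "red",
           "// Tracing N1", "1", "2", "0", "Axon",
           "// Segment 1 of Tracing N1",
           "10.0", "20.0", "11.0", "21.0",
           "// Segment 2 of Tracing N1",
           "12.0", "22.0",
           "// Tracing N2", "2", "1", "0", "Default",
           "// Segment 1 of Tracing N2",
           "5.0", "6.0", "7.0", "8.0",
           "// End of NeuronJ Data File")
  m <- ndf_to_morphology(ndf)
  expect_equal(n_samples(m), 5)
  expect_true(all(m$samples$radius == 0.5))
  expect_true(all(m$samples$z == 0))
  expect_equal(m$samples$type[1:3], rep(2, 3))   # Axon label
  expect_equal(m$samples$type[4:5], rep(0, 2))   # unlabeled
  expect_equal(sum(m$samples$parent == -1), 2)

  empty <- ndf_to_morphology("// NeuronJ Data File - version 1.4.2")
  res <- standardize(empty)
  expect_true(has_errors(res$log))
  expect_equal(res$log$check_id[1], "Number of Lines")
})

test_that("ASC conversion maps trees, halves diameters, skips spines", {
  asc <- c("; Neurolucida-style fixture",
           "(\"CellBody\"",
           "  (CellBody)",
           "  (2.0 0.0 0.0 1.0)", "  (1.41 1.41 0.0 1.0)",
           "  (0.0 2.0 0.0 1.0)", "  (-1.41 1.41 0.0 1.0)",
           "  (-2.0 0.0 0.0 1.0)", "  (-1.41 -1.41 0.0 1.0)",
           "  (0.0 -2.0 0.0 1.0)", "  (1.41 -1.41 0.0 1.0)",
           ")",
           "( (Dendrite)",
           "  (5.0 0.0 0.0 2.0)",
           "  (6.0 0.0 0.0 2.0)",
           "  (Spine (6.1 0.1 0.0 0.2))",
           "  (",
           "    (7.0 1.0 0.0 1.0)",
           "    |",
           "    (7.0 -1.0 0.0 1.0)",
           "  )",
           ")")
  m <- asc_to_morphology(asc)
  expect_equal(m$samples$radius[m$samples$type == 3][1], 1.0)  # d/2
  expect_match(m$notes, "Spine", all = FALSE)

  res <- standardize(m)
  s <- res$morphology$samples
  expect_true(triggered(res$log, "Soma Contours"))
  expect_equal(sum(s$type == 1), 1)          # contour collapsed to root
  expect_equal(s$parent[s$type == 1], -1)

  expect_error(asc_to_morphology("( (Dendrite) (0 0 0 1)"), "unbalanced")
})

test_that("HOC conversion builds sections and connect topology", {
  hoc <- c("create soma, dend[2], apic // geometry",
           "connect dend[0](0), soma(1)",
           "connect dend[1](0), dend[0](1)",
           "soma { pt3dadd(0, 0, 0, 10) pt3dadd(5, 0, 0, 10) }",
           "dend[0] {",
           "  pt3dadd(5, 0, 0, 4)",
           "  pt3dadd(10, 0, 0, 3)",
           "}",
           "dend[1] { pt3dadd(10, 0, 0, 2) pt3dadd(15, 5, 0, 2) }")
  m <- hoc_to_morphology(hoc)
  s <- m$samples
  expect_equal(s$type[1], 1)                   # name 'soma'
  expect_equal(s$radius[1], 5)                 # diameter/2
  # duplicated junction points are merged: 6 declared, 2 shared
  expect_equal(nrow(s), 6 - 2)
  # dendrite is attached to the soma end point
  dend_root <- which(s$type == 3)[1]
  expect_equal(s$parent[dend_root], s$index[max(which(s$type == 1))])
  expect_match(m$notes, "apic", all = FALSE)  # pointless section dropped

  top <- topo_summary(m)
  expect_equal(top$roots, 1)
  expect_equal(standardize(m)$is_standard, TRUE)

  expect_error(hoc_to_morphology(
    c("create soma", "connect dend(0), soma(1)", "soma { pt3dadd(0,0,0,1) }")),
    "undeclared")
})

test_that("section names map onto structural domain codes", {
  hoc <- c("create axon[1]", "axon[0] { pt3dadd(0,0,0,2) pt3dadd(1,0,0,2) }")
  m <- hoc_to_morphology(hoc)
  expect_true(all(m$samples$type == 2))
})

test_that("NTS conversion drives the branch stack from mnemonics", {
  m <- nts_to_morphology(c("1 MTO 0.0 0.0 0.0 2.0",
                           "2 CP 1.0 0.0 0.0 2.0",
                           "3 NE 2.0 0.0 0.0 2.0"))
  expect_equal(m$samples$parent, c(-1, 1, 2))
  expect_equal(m$samples$type, rep(2, 3))     # MTO: axon tree
  expect_equal(m$samples$radius, rep(1, 3))   # thickness/2

  m <- nts_to_morphology(c("1 DTO 0.0 0.0 0.0 2.0",
                           "2 BP 1.0 0.0 0.0 2.0",
                           "3 CP 2.0 1.0 0.0 1.0",
                           "4 NE 3.0 2.0 0.0 1.0",
                           "5 NE 2.0 -1.0 0.0 1.0"))
  kids <- tabulate(match(m$samples$parent, m$samples$index)[
    m$samples$parent != -1], nbins = 5)
  expect_equal(sum(kids >= 2), 1)             # exactly one bifurcation
  expect_equal(m$samples$parent[5], 2)        # reattached at the BP

  expect_error(nts_to_morphology("1 XYZ 0 0 0 1"), "mnemonic")
  empty <- nts_to_morphology(character(0))
  expect_true(has_errors(standardize(empty)$log))
})

test_that("KNOSSOS conversion rebuilds trees from node/edge lists", {
  nml <- c("<things>", '<thing id="1">',
           "<nodes>",
           '<node id="5" x="0" y="0" z="0" radius="1.5"/>',
           '<node id="6" x="1" y="0" z="0"/>',
           '<node id="7" x="2" y="0" z="0" radius="1.0"/>',
           "</nodes>",
           '<edges><edge source="5" target="6"/><edge source="6" target="7"/></edges>',
           "</thing>", "</things>")
  m <- knossos_nml_to_morphology(nml)
  expect_equal(m$samples$parent, c(-1, 1, 2))
  expect_equal(m$samples$radius, c(1.5, 0.5, 1.0))  # missing radius -> 0.5

  # two components yield two roots (multi-tree file)
  nml2 <- c("<things>", '<thing id="1">',
            "<nodes>",
            '<node id="1" x="0" y="0" z="0"/>', '<node id="2" x="1" y="0" z="0"/>',
            '<node id="3" x="9" y="0" z="0"/>', '<node id="4" x="10" y="0" z="0"/>',
            "</nodes>",
            '<edges><edge source="1" target="2"/><edge source="3" target="4"/></edges>',
            "</thing>", "</things>")
  m2 <- knossos_nml_to_morphology(nml2)
  expect_equal(sum(m2$samples$parent == -1), 2)

  expect_error(knossos_nml_to_morphology(
    sub('target="4"', 'target="99"', nml2)), "unknown node")
  cyc <- c("<things>", '<thing id="1">',
           "<nodes>",
           '<node id="1" x="0" y="0" z="0"/>', '<node id="2" x="1" y="0" z="0"/>',
           '<node id="3" x="2" y="0" z="0"/>', "</nodes>",
           paste0('<edges><edge source="1" target="2"/>',
                  '<edge source="2" target="3"/>',
                  '<edge source="3" target="1"/></edges>'),
           "</thing>", "</things>")
  expect_error(knossos_nml_to_morphology(cyc), "not a tree")
})

test_that("NeuroML segments become proximal/distal samples with groups", {
  nml <- c('<neuroml xmlns="http://www.neuroml.org/schema/neuroml2" id="x">',
           '<cell id="c"><morphology>',
           '<segment id="0" name="soma">',
           '  <proximal x="0" y="0" z="0" diameter="8"/>',
           '  <distal x="10" y="0" z="0" diameter="8"/>',
           "</segment>",
           '<segment id="1" name="d1">',
           '  <parent segment="0"/>',
           '  <distal x="20" y="5" z="0" diameter="2"/>',
           "</segment>",
           '<segmentGroup id="soma_group"><member segment="0"/></segmentGroup>',
           '<segmentGroup id="axon_group"><member segment="1"/></segmentGroup>',
           "</morphology></cell></neuroml>")
  m <- neuroml_to_morphology(nml)
  expect_equal(n_samples(m), 3)            # proximal root + two distals
  expect_equal(m$samples$parent, c(-1, 1, 2))
  expect_equal(m$samples$type, c(1, 1, 2)) # axon_group member is type 2
  expect_equal(m$samples$radius[1], 4)

  # v1 morphml layout with cables is accepted too
  v1 <- c('<morphml xmlns="http://morphml.org/morphml/schema">',
          "<cells><cell><segments>",
          '<segment id="0" cable="0">',
          '  <proximal x="0" y="0" z="0" diameter="4"/>',
          '  <distal x="5" y="0" z="0" diameter="4"/>',
          "</segment>",
          '<segment id="1" parent="0" cable="1">',
          '  <distal x="9" y="0" z="0" diameter="2"/>',
          "</segment>",
          "</segments>",
          '<cables><cable id="0" name="Soma"/><cable id="1" name="Dendrite"/></cables>',
          "</cell></cells></morphml>")
  m1 <- neuroml_to_morphology(v1)
  expect_equal(n_samples(m1), 3)
  expect_equal(m1$samples$type, c(1, 1, 3))

  expect_error(neuroml_to_morphology(
    sub('segment="0"/>', 'segment="42"/>', nml, fixed = TRUE)),
    "missing parent")
})

test_that("ESWC extra columns are preserved to the footer", {
  m <- generate_morphology(fixture_spec(seed = 2))
  txt <- render_fixture(m, "eswc")
  out <- eswc_to_morphology(txt)
  expect_equal(n_samples(out), n_samples(m))
  eswc_lines <- grep("^# eswc ", out$footer, value = TRUE)
  expect_length(eswc_lines, n_samples(m))

  plain <- eswc_to_morphology("1 1 0.0 0.0 0.0 1.0 -1")
  expect_equal(n_samples(plain), 1)
  expect_length(plain$footer, 0)

  expect_error(eswc_to_morphology(c("1 1 0 0 0 1 -1 9 9",
                                    "2 3 1 0 0 1 1 9")), "ragged")
})

test_that("path flattening merges junctions and inserts defaults", {
  p1 <- segment_path(data.frame(x = 0:4, y = 0, z = 0, radius = 1),
                     domain = 3, path_id = "a")
  m <- paths_to_morphology(list(p1))
  expect_equal(m$samples$parent, c(-1, 1:4))

  # child repeating the junction point is merged, not duplicated
  p2 <- segment_path(data.frame(x = c(4, 5), y = c(0, 1), z = 0,
                                radius = NA_real_),
                     domain = NA, path_id = "b", parent_path = "a",
                     attach_pos = 5)
  m <- paths_to_morphology(list(p1, p2))
  expect_equal(n_samples(m), 6)              # not 7: junction shared
  expect_equal(m$samples$radius[6], 0.5)     # missing radius default
  expect_equal(m$samples$type[6], 0)         # missing domain default

  # detached paths give two roots
  p3 <- segment_path(data.frame(x = 9, y = 9, z = 9), path_id = "c")
  m <- paths_to_morphology(list(p1, p3))
  expect_equal(sum(m$samples$parent == -1), 2)

  bad <- list(
    segment_path(data.frame(x = 0, y = 0, z = 0), path_id = "a",
                 parent_path = "b", attach_pos = 1),
    segment_path(data.frame(x = 1, y = 0, z = 0), path_id = "b",
                 parent_path = "a", attach_pos = 1))
  expect_error(paths_to_morphology(bad), "cyclic")
})

test_that("every converted fixture standardizes without errors", {
  for (fmt in c("ndf", "nts", "eswc", "hoc", "knossos_nml", "neuroml")) {
    m <- generate_morphology(fixture_spec(seed = 17))
    txt <- render_fixture(m, fmt)
    conv <- convert_to_morphology(paste(txt, collapse = "\n"), fmt)
    res <- standardize(conv)
    expect_false(has_errors(res$log), info = fmt)
    s <- res$morphology$samples
    expect_false(any(is.na(unlist(s))), info = fmt)  # no unset fields
    expect_true(all(s$radius > 0), info = fmt)
  }
  # ASC cannot express soma attachment; use a detached fixture
  m <- generate_morphology(fixture_spec(seed = 17, soma_style = "contour"))
  res <- standardize(asc_to_morphology(render_fixture(m, "asc")))
  expect_false(has_errors(res$log))
})

test_that("round trips preserve topology and cable length", {
  for (seed in c(3, 14)) {
    att <- generate_morphology(fixture_spec(seed = seed))
    det <- generate_morphology(fixture_spec(seed = seed,
                                            soma_style = "contour"))
    for (fmt in c("hoc", "knossos_nml", "neuroml")) {
      back <- convert_to_morphology(
        paste(render_fixture(att, fmt), collapse = "\n"), fmt)
      a <- topo_summary(att); b <- topo_summary(back)
      expect_equal(b$roots, a$roots, info = fmt)
      expect_equal(b$bifurcations, a$bifurcations, info = fmt)
      expect_equal(b$terminals, a$terminals, info = fmt)
      expect_equal(b$cable, a$cable, tolerance = 1e-6, info = fmt)
    }
    back <- asc_to_morphology(render_fixture(det, "asc"))
    a <- topo_summary(det); b <- topo_summary(back)
    expect_equal(b[c("roots", "bifurcations", "terminals")],
                 a[c("roots", "bifurcations", "terminals")])
    expect_equal(b$cable, a$cable, tolerance = 1e-6)
  }
})
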