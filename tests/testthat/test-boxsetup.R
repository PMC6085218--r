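test_that("random lines are seeded, contained and uniformly placed", {
  box <- simulation_box(c(20, 30, 40))

  # seeded determinism, line by line
  l1 <- random_lines(box, 1, tube_length = 8, seed = 11)
  l2 <- random_lines(box, 1, tube_length = 8, seed = 11)
  expect_identical(l1, l2)
  expect_false(identical(l1, random_lines(box, 1, tube_length = 8, seed = 12)))

  # a line's geometry does not depend on how many lines precede it
  l5 <- random_lines(box, 5, tube_length = 8, seed = 11)
  expect_identical(l5[[1]], l1[[1]])

  # containment of both endpoints, and start-point uniformity:
  # per-axis mean within 3 standard errors of the box center
  n <- 10000L
  lines <- random_lines(box, n, tube_length = 10, seed = 3)
  starts <- t(vapply(lines, function(l) l$start, numeric(3)))
  ends <- t(vapply(lines, function(l) l$end, numeric(3)))
  for (a in 1:3) {
    expect_true(all(starts[, a] >= 0 & starts[, a] <= box$lengths[a]))
    expect_true(all(ends[, a] >= 0 & ends[, a] <= box$lengths[a]))
    se <- box$lengths[a] / sqrt(12) / sqrt(n)
    expect_lt(abs(mean(starts[, a]) - box$lengths[a] / 2), 3 * se)
  }
  # every line has the requested length
  expect_equal(sqrt(rowSums((ends - starts)^2)), rep(10, n), tolerance = 1e-9)

  expect_error(random_lines(box, 1, tube_length = 25, seed = 1),
               "exceeds the smallest box extent")
})

test_that("bilayer lines are anti-parallel leaflets along the normal axis", {
  box <- simulation_box(c(10, 10, 12))

  lines <- bilayer_lines(box, 2, normal_axis = "z", midplane = 6,
                         tube_length = 4, seed = 5)
  d1 <- lines[[1]]$end - lines[[1]]$start
  d2 <- lines[[2]]$end - lines[[2]]$start
  expect_equal(d1, c(0, 0, -4))
  expect_equal(d2, c(0, 0, 4))
  expect_equal(d1 + d2, c(0, 0, 0))  # anti-parallel pair

  # all direction vectors have zero lateral component
  lines <- bilayer_lines(box, 50, normal_axis = 3, midplane = 6,
                         tube_length = 4, seed = 5)
  for (l in lines) {
    d <- l$end - l$start
    expect_identical(d[1:2], c(0, 0))
  }

  expect_error(bilayer_lines(box, 3, "z", 6, 4, seed = 1), "even")
  expect_error(bilayer_lines(box, 2, "z", 6, 7, seed = 1), "half the box extent")
  expect_error(bilayer_lines(box, 2, "z", 1, 4, seed = 1), "outside the box")
})

test_that("projected bilayer DMPC heads sit bimodally at the leaflet outer faces", {
  box <- simulation_box(c(30, 30, 20))
  mol <- parse_spices(fixture_dmpc())
  lines <- bilayer_lines(box, 200, normal_axis = "z", midplane = 10,
                         tube_length = 8, bond_length = 1, seed = 9)
  tab <- project_population(mol, lines)
  heads <- tab[tab$name == "TriMeNP", ]
  expect_equal(nrow(heads), 200L)
  # START-tagged heads pin to line starts: exactly the two outer faces
  expect_setequal(unique(heads$z), c(18, 2))
  expect_equal(sum(heads$z == 18), 100L)
  expect_equal(sum(heads$z == 2), 100L)
})

test_that("population projection concatenates independent per-molecule blocks", {
  box <- simulation_box(c(20, 20, 20))
  mol <- parse_spices(fixture_dmpc())

  # one molecule on one line reproduces the single-molecule records
  lines <- random_lines(box, 1, tube_length = 8, bond_length = 1, seed = 2)
  tab1 <- project_population(mol, lines)
  mp <- map_molecule_to_line(mol, lines[[1]])
  tab_ref <- particle_positions_and_connections(mol, mp)
  expect_equal(tab1$name, tab_ref$name)
  expect_equal(tab1$bond_offsets, tab_ref$bond_offsets)
  expect_equal(cbind(tab1$x, tab1$y, tab1$z),
               cbind(tab_ref$x, tab_ref$y, tab_ref$z))

  # record count conservation and offset closure across the whole population
  lines <- random_lines(box, 40, tube_length = 8, seed = 4)
  tab <- project_population(mol, lines)
  expect_equal(nrow(tab), 40L * 16L)
  expect_true(offsets_closed(tab))
  expect_equal(sum(lengths(tab$bond_offsets)), 2L * 15L * 40L)

  expect_identical(nrow(project_population(mol, list())), 0L)
})

test_that("force indices come from the backbone-label indirection", {
  box <- simulation_box(c(20, 20, 20))
  chol <- parse_spices(fixture_cholesterol_like())
  lines <- random_lines(box, 3, tube_length = 8, seed = 6)

  fmap <- stats::setNames(1:17, as.character(1:17))
  tab <- project_population(chol, lines, force_map = fmap)
  # every particle of this fixture is labeled, so every record is nonzero
  expect_true(all(tab$force_index > 0))
  expect_equal(tab$force_index[1:17], 1:17)

  # unlabeled particles get 0
  dmpc <- parse_spices(fixture_dmpc())
  tab <- project_population(dmpc, lines, force_map = c(anything = 5L))
  expect_true(all(tab$force_index == 0L))

  # strict mode rejects a molecule label absent from a non-empty map,
  # permissive mode falls back to 0
  expect_error(project_population(chol, lines, force_map = c(`1` = 1L)),
               "missing from force_map")
  tab <- project_population(chol, lines, force_map = c(`1` = 7L), strict = FALSE)
  expect_equal(unique(tab$force_index[tab$name == "MeOH"]), 7L)
  expect_true(all(tab$force_index[chol$nodes$backbone_label != "1"] == 0L))
})

test_that("ASCII tables round-trip and are byte-deterministic under a seed", {
  box <- simulation_box(c(20, 20, 20))

  # empty table: header-only file that reads back empty
  f <- withr::local_tempfile(fileext = ".txt")
  write_box_table(empty_record_table(), f, box = box)
  expect_true(all(startsWith(readLines(f), "#")))
  expect_equal(nrow(read_box_table(f)), 0L)

  # the smallest bonded pair prints +1 / -1
  mol <- parse_spices("A-B")
  mp <- map_molecule_to_line(mol, line_spec(c(0, 0, 0), c(5, 0, 0)))
  write_box_table(particle_positions_and_connections(mol, mp), f)
  lines <- grep("^#", readLines(f), value = TRUE, invert = TRUE)
  expect_equal(length(lines), 2L)
  expect_match(lines[1], "^A\t0\\.000000\t0\\.000000\t0\\.000000\t\\+1\t0$")
  expect_match(lines[2], "^B\t1\\.000000\t0\\.000000\t0\\.000000\t-1\t0$")

  # write/read/write is a byte fixpoint on a 100-molecule random table
  dmpc <- parse_spices(fixture_dmpc())
  tab <- project_population(dmpc, random_lines(box, 100, tube_length = 8, seed = 13))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_box_table(tab, f1, box = box)
  back <- read_box_table(f1)
  expect_s3_class(attr(back, "box"), "simulation_box")
  write_box_table(back, f2, box = attr(back, "box"))
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(back$name, tab$name)
  expect_equal(back$bond_offsets, tab$bond_offsets)
  expect_equal(back$x, tab$x, tolerance = 1e-6)

  # identical seeds give byte-identical output; clamping keeps coordinates in the box
  tab2 <- project_population(dmpc, random_lines(box, 100, tube_length = 8, seed = 13))
  f3 <- withr::local_tempfile()
  write_box_table(tab2, f3, box = box)
  expect_identical(readLines(f1), readLines(f3))
  expect_true(all(back$x >= 0 & back$x <= 20 & back$y >= 0 & back$y <= 20 &
                  back$z >= 0 & back$z <= 20))
})

test_that("malformed ASCII lines raise positional read errors", {
  f <- withr::local_tempfile()
  writeLines(c("# spices particle records", "# records\t1",
               "A\t0.000000\t0.000000\t0.000000\t+1"), f)  # missing field
  expect_error(read_box_table(f), "line 3.*6 tab-separated fields")
  writeLines(c("A\t0.0\tnope\t0.0\t\t0"), f)
  expect_error(read_box_table(f), "field 3")
  writeLines(c("A\t0.0\t0.0\t0.0\t1;2\t0"), f)
  expect_error(read_box_table(f), "field 5")
  writeLines(c("A\t0.0\t0.0\t0.0\t\t-1"), f)
  expect_error(read_box_table(f), "field 6")
})
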