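test_that("tokenizer splits chains, labels and reports bad characters in place", {
  toks <- tokenize_spices("Et-Et")
  expect_equal(vapply(toks, `[[`, character(1), "type"), c("name", "dash", "name"))
  expect_equal(vapply(toks, `[[`, numeric(1), "pos"), c(0, 2, 3))

  toks <- tokenize_spices("Me'12'")
  expect_equal(toks[[1]]$type, "name")
  expect_equal(toks[[2]]$type, "label")
  expect_equal(toks[[2]]$value, "12")
  expect_equal(toks[[2]]$pos, 2)

  toks <- tokenize_spices("A(&")
  types <- vapply(toks, `[[`, character(1), "type")
  expect_equal(types, c("name", "lparen", "error"))
  expect_equal(toks[[3]]$pos, 2)

  # tags and ring closures share bracket syntax but tokenize apart
  toks <- tokenize_spices("A[START][3]")
  expect_equal(vapply(toks, `[[`, character(1), "type"),
               c("name", "tag_start", "ring"))
  expect_equal(toks[[3]]$value, 3L)
})

test_that("parser builds the described graphs", {
  m <- parse_spices("Et")
  expect_equal(n_particles(m), 1L)
  expect_equal(n_bonds(m), 0L)
  expect_equal(m$parts, 1L)

  # branch contents bond to the particle preceding the branch
  m <- parse_spices("A(-B)-C")
  expect_equal(unname(m$bonds), rbind(c(1L, 2L), c(1L, 3L)))

  # ring closure labels bond their two occurrences: smallest labeled ring
  m <- parse_spices("A-B[1]-C-D[1]")
  expect_equal(n_particles(m), 4L)
  expect_equal(n_bonds(m), 4L)
  expect_true(all(c(2L, 4L) %in% m$bonds[m$bonds[, 1] == 2 | m$bonds[, 2] == 2, ]))

  # repeat prefix expands to a linear chain
  m <- parse_spices("W-3Et-W")
  expect_equal(m$nodes$name, c("W", "Et", "Et", "Et", "W"))
  expect_equal(unname(m$bonds), cbind(1:4, 2:5))

  # parts split at '.'; labels and tags attach to the preceding particle
  m <- parse_spices("A'7'[START]-B[END].C")
  expect_equal(m$parts, 2L)
  expect_equal(m$nodes$backbone_label, c("7", NA, NA))
  expect_equal(m$nodes$start, c(TRUE, FALSE, FALSE))
  expect_equal(m$nodes$end, c(FALSE, TRUE, FALSE))
  expect_equal(m$nodes$part, c(1L, 1L, 2L))

  # the DMPC fixture has 16 particles
  expect_equal(n_particles(parse_spices(fixture_dmpc())), 16L)
})

test_that("validator reports every structural violation with its position", {
  rep <- validate_spices("A(-B")
  expect_false(rep$valid)
  expect_match(rep$errors$message, "unclosed branch")
  expect_equal(rep$errors$position, 1L)

  rep <- validate_spices("A-B[1]")
  expect_false(rep$valid)
  expect_match(rep$errors$message, "unmatched ring closure label 1")

  expect_valid_spices("A[START]-B-C[END]")
  expect_valid_spices(fixture_dmpc())
  expect_valid_spices(fixture_cholesterol_like())

  cases <- list(
    list("A-",            "dangling bond separator"),
    list("-A",            "bond separator at start"),
    list("A()B",          "empty branch"),
    list("A)B",           "unmatched '\\)'"),
    list("'x'A",          "must follow a particle"),
    list("A.",            "empty part"),
    list("",              "empty SPICES string"),
    list("A B",           "whitespace"),
    list("A[START]-B[START]", "duplicate \\[START\\]"),
    list("A[START][END]", "already carries a tag"),
    list("A'x''y'",       "duplicate backbone label"),
    list("3Et'x'",        "label may not follow a repeat"),
    list("3Et[END]",      "tag may not follow a repeat"),
    list("A-B[1]-C[1][1]", "unmatched ring closure"),
    list("A[1][1]",       "itself"),
    list("A-B[1][2]-A2[1][2]", "duplicate bond"),
    list("A-0Et",         "repeat count must be a positive integer"),
    list("A(B)",          "expected '-' after '\\('"),
    list("Aé",       "non-ASCII")
  )
  for (cs in cases) {
    rep <- validate_spices(cs[[1]])
    expect_false(rep$valid, info = cs[[1]])
    expect_true(any(grepl(cs[[2]], rep$errors$message)),
                info = sprintf("'%s': wanted /%s/, got: %s", cs[[1]], cs[[2]],
                               paste(rep$errors$message, collapse = "; ")))
  }

  # the validator keeps scanning past the first problem
  rep <- validate_spices("A(-B.C-")
  expect_gte(nrow(rep$errors), 2L)
})

test_that("parse raises a classed condition carrying the report", {
  err <- tryCatch(parse_spices("A(-B"), error = identity)
  expect_s3_class(err, "spices_parse_error")
  expect_s3_class(err$report, "parse_report")
  expect_false(err$report$valid)
})

test_that("catalog checking is sound", {
  cat_ok <- c("TriMeNP", "DMPN", "MeAc", "Et")
  expect_equal(n_particles(parse_spices(fixture_dmpc(), catalog = cat_ok)), 16L)
  err <- tryCatch(parse_spices("Et-Unknown9", catalog = cat_ok), error = identity)
  expect_s3_class(err, "spices_unknown_particle")
  expect_match(conditionMessage(err), "Unknown9")

  # parse with catalog C succeeds iff parse succeeds and names are in C
  for (seed in 1:20) {
    s <- random_molecule(8, branch_prob = 0.4, ring_prob = 0.1, seed = seed)
    mol <- parse_spices(s)
    expect_equal(parse_spices(s, catalog = unique(mol$nodes$name))$nodes, mol$nodes)
    expect_s3_class(tryCatch(parse_spices(s, catalog = "Zz"), error = identity),
                    "spices_unknown_particle")
  }
})

test_that("serialize/parse round-trips preserve the labeled graph", {
  # single node
  expect_equal(serialize_spices(parse_spices("Et")), "Et")

  # DMPC: isomorphic after a round trip
  m <- parse_spices(fixture_dmpc())
  m2 <- parse_spices(serialize_spices(m))
  expect_equal(n_particles(m2), 16L)
  expect_true(molecules_isomorphic(m, m2))

  # random molecules across the parameter space
  for (seed in 1:100) {
    s <- random_molecule(n_particles = 1 + seed %% 18,
                         branch_prob = (seed %% 5) / 5,
                         ring_prob = (seed %% 4) / 10,
                         seed = seed, label_prob = 0.15, tag_prob = 0.3)
    a <- parse_spices(s)
    b <- parse_spices(serialize_spices(a))
    expect_true(molecules_isomorphic(a, b), info = s)
  }

  # serialize refuses an invariant-violating molecule
  broken <- parse_spices("A-B")
  broken$bonds <- rbind(broken$bonds, c(1L, 5L))
  expect_error(serialize_spices(broken), "invariant")
})

test_that("validate is total and error offsets stay inside the input", {
  set.seed(20260928)
  chars <- c(LETTERS, letters, 0:9, "-", "(", ")", "[", "]", "'", ".",
             " ", "&", "#", "@", "+", "~")
  for (k in 1:200) {
    s <- paste(sample(chars, sample(0:25, 1), replace = TRUE), collapse = "")
    rep <- validate_spices(s)   # must never raise
    expect_s3_class(rep, "parse_report")
    expect_equal(rep$valid, nrow(rep$errors) == 0L)
    if (nrow(rep$errors)) {
      expect_true(all(rep$errors$position >= 0))
      expect_true(all(rep$errors$position <= nchar(s)))
    }
  }
})
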