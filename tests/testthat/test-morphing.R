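# The morphing engine: operator enumeration, single-edit application,
# two-stage random sampling and threshold-terminated paths.

test_that("operator enumeration matches hand counts on small molecules", {
  # methane with a carbon-only alphabet: one ADD_ATOM, nothing else
  ops <- applicable_operations(parse_smiles("C"), alphabet = "C")
  expect_length(ops, 1L)
  expect_identical(ops[[1]]$kind, "ADD_ATOM")

  # cyclopropane: every ring bond is removable
  ops <- applicable_operations(parse_smiles("C1CC1"))
  rb <- Filter(function(o) o$kind == "REMOVE_BOND", ops)
  expect_length(rb, 3L)

  # a single atom cannot be removed
  ra <- Filter(function(o) o$kind == "REMOVE_ATOM",
               applicable_operations(parse_smiles("C")))
  expect_length(ra, 0L)

  # saturated atoms admit no ADD_BOND; neopentane's quaternary carbon
  # cannot gain neighbors
  ops <- applicable_operations(parse_smiles("CC(C)(C)C"))
  ab <- Filter(function(o) o$kind == "ADD_BOND", ops)
  expect_true(all(vapply(ab, function(o) !(2L %in% c(o$i, o$j)), logical(1))))
})

test_that("apply_operation performs exactly the requested edit", {
  op <- cmorph:::.morph_op
  expect_identical(canonical_smiles(
    apply_operation(parse_smiles("C"), op("ADD_ATOM", atom = 1L, elem = "C"))),
    canonical_smiles(parse_smiles("CC")))
  expect_identical(canonical_smiles(
    apply_operation(parse_smiles("CCCC"), op("ADD_BOND", i = 1L, j = 4L))),
    canonical_smiles(parse_smiles("C1CCC1")))
  expect_error(
    apply_operation(parse_smiles("CCC"), op("REMOVE_BOND", i = 1L, j = 2L)),
    "disconnect")
  expect_error(
    apply_operation(parse_smiles("CC"), op("REMOVE_ATOM", atom = 3L)))
  expect_error(
    apply_operation(parse_smiles("CC"), op("ADD_BOND", i = 1L, j = 2L)),
    "bonded")
  # the input molecule is never modified
  m <- parse_smiles("CCO")
  invisible(apply_operation(m, op("ADD_ATOM", atom = 1L, elem = "N")))
  expect_identical(canonical_smiles(m), canonical_smiles(parse_smiles("CCO")))
})

test_that("every enumerated operation yields a valid connected molecule", {
  set.seed(61)
  lib <- fx_library()
  mols <- lib[sample.int(length(lib), 12)]
  for (m in mols) {
    for (o in applicable_operations(m)) {
      res <- apply_operation(m, o)     # sanitize() runs inside
      expect_true(cmorph:::is_connected_mol(res))
    }
  }
})

test_that("random steps are seeded, reproducible and single-edit", {
  m <- parse_smiles("CC1CC1O")
  set.seed(71)
  s1 <- random_morph_step(m)
  set.seed(71)
  s2 <- random_morph_step(m)
  expect_identical(s1$op, s2$op)
  expect_identical(canonical_smiles(s1$mol), canonical_smiles(s2$mol))

  # brute-force single-edit check: the child must be reachable from the
  # parent by one enumerated operation
  set.seed(72)
  cur <- m
  for (k in 1:40) {
    st <- random_morph_step(cur)
    sigs <- vapply(applicable_operations(cur), function(o) {
      r <- tryCatch(apply_operation(cur, o), error = function(e) NULL)
      if (is.null(r)) "" else cmorph:::mol_signature(r)
    }, character(1))
    expect_true(cmorph:::mol_signature(st$mol) %in% sigs)
    cur <- st$mol
    if (n_atoms(cur) > 14) cur <- m  # keep the checker brute-forceable
  }
})

test_that("operation kinds are sampled uniformly", {
  # all six kinds are applicable on methylcyclopropanol
  m <- parse_smiles("CC1CC1O")
  kinds_avail <- sort(unique(vapply(applicable_operations(m),
                                    `[[`, character(1), "kind")))
  expect_length(kinds_avail, 6L)
  set.seed(81)
  n <- 6000L
  picked <- character(n)
  for (k in seq_len(n)) picked[k] <- random_morph_step(m)$op$kind
  freq <- table(factor(picked, levels = kinds_avail)) / n
  p <- 1 / 6
  tol <- 3 * sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < tol))
})

test_that("degenerate thresholds drive EXHAUSTED and step-0 HIT", {
  m <- parse_smiles("CCOCC")
  inf_tab <- constant_table(Inf)
  p <- morph_until_complex(m, inf_tab, max_steps = 30L, seed = 91L)
  expect_identical(p$terminal_status, "EXHAUSTED")
  expect_length(p$steps, 30L)

  neg_tab <- constant_table(-1)
  expect_warning(p0 <- morph_until_complex(m, neg_tab, seed = 92L),
                 "already exceeds")
  expect_identical(p0$terminal_status, "HIT")
  expect_length(p0$steps, 0L)
})

test_that("HIT paths cross the threshold exactly once, at the end", {
  tab <- fx_thresholds()
  cond <- stop_condition("p999", 1L)
  lib <- fx_library()
  set.seed(93)
  starts <- lib[sample.int(length(lib), 30)]
  hits <- 0L
  for (k in seq_along(starts)) {
    p <- suppressWarnings(
      morph_until_complex(starts[[k]], tab, cond, seed = 1000L + k))
    if (p$terminal_status != "HIT" || !length(p$steps)) next
    hits <- hits + 1L
    flags <- vapply(p$steps, function(s)
      exceeds(complexity_vector(s$mol), mol_weight(s$mol), tab, cond),
      logical(1))
    expect_false(any(flags[-length(flags)]))
    expect_true(flags[length(flags)])
  }
  expect_gt(hits, 0L)
})

test_that("generate_library deduplicates and is seed-reproducible", {
  tab <- fx_thresholds()
  lib <- fx_library()
  starts <- lib[seq(1, 66)]
  g1 <- generate_library(starts, tab, seed = 94L)
  g2 <- generate_library(starts, tab, seed = 94L)
  expect_identical(g1$hard, g2$hard)
  expect_identical(g1$paths, g2$paths)
  expect_lte(nrow(g1$hard), length(starts))
  expect_false(anyDuplicated(g1$hard$smiles) > 0)
  expect_identical(nrow(g1$paths), length(starts))

  # round-trip: every emitted hard structure exceeds under the same table
  cond <- stop_condition("p999", 1L)
  for (smi in g1$hard$smiles) {
    mm <- parse_smiles(smi)
    expect_true(exceeds(complexity_vector(mm), mol_weight(mm), tab, cond))
  }
})
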