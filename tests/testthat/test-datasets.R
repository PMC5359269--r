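# Labeled-set builders: morphing pairs, SAscore thresholds, dense-region
# density labels, the synthetic fixture generator and test-set loading.

test_that("labeled sets deduplicate and keep classes disjoint", {
  s <- labeled_set(c("CCO", "OCC", "CCN", "CCN"),
                   c("easy", "easy", "hard", "hard"))
  expect_identical(sum(s$label == "easy"), 1L)   # CCO == OCC
  expect_identical(sum(s$label == "hard"), 1L)
  expect_error(labeled_set("CCO", "medium"), "easy.*hard")
  expect_identical(attr(labeled_set("CCO", "easy", role = "test"), "role"),
                   "test")
})

test_that("morphing sets pair each hard morph with its starting structure", {
  lib <- fx_library()
  tab <- fx_thresholds()
  starts <- lib[seq(1, 88)]
  built <- suppressWarnings(
    build_nonpher_sets(starts, tab, easy_from = "starts", seed = 111L))
  set <- built$set
  n_hard <- sum(set$label == "hard")
  n_easy <- sum(set$label == "easy")
  expect_gt(n_hard, 0L)
  expect_identical(n_easy, n_hard)  # strict 1:1 pairing
  # the easy class is exactly the starts of successful paths (after dedup)
  start_smis <- cmorph:::canonical_smiles_batch(
    starts[built$library$hard$start])
  expect_setequal(set$smiles[set$label == "easy"], unique(start_smis))
  expect_length(intersect(set$smiles[set$label == "easy"],
                          set$smiles[set$label == "hard"]), 0L)
})

test_that("morphing sets can draw the easy class from a reference library", {
  lib <- fx_library()
  tab <- fx_thresholds()
  starts <- lib[seq(1, 44)]
  ref <- vapply(lib[200:320], canonical_smiles, character(1))
  b1 <- suppressWarnings(
    build_nonpher_sets(starts, tab, easy_from = "reference",
                       reference = ref, seed = 112L))
  b2 <- suppressWarnings(
    build_nonpher_sets(starts, tab, easy_from = "reference",
                       reference = ref, seed = 112L))
  expect_identical(b1$set, b2$set)  # seeded easy sample is reproducible
  expect_identical(sum(b1$set$label == "easy"), sum(b1$set$label == "hard"))
  expect_error(
    suppressWarnings(build_nonpher_sets(starts, tab,
                                        easy_from = "reference",
                                        reference = ref[1:2], seed = 1L)),
    "smaller")
})

test_that("sascore thresholds split strictly at 6 and 4", {
  scored <- data.frame(smiles = c("CCO", "CCN", "CCC", "CCCC", "CCOC"),
                       sascore = c(3, 5, 7, 6.0, 4.0))
  s <- build_sascore_sets(scored, seed = 1L)
  expect_identical(s$smiles[s$label == "hard"],
                   canonical_smiles(parse_smiles("CCC")))
  expect_identical(s$smiles[s$label == "easy"],
                   canonical_smiles(parse_smiles("CCO")))
  # 6.0 and 4.0 fall in the excluded band
  expect_identical(nrow(s), 2L)
  expect_error(build_sascore_sets(scored, n_easy = 5L), "pool")
})

test_that("neighbor counting excludes the query and matches brute force", {
  fp <- morgan_fp_matrix(rep("CC(=O)Oc1ccccc1C(=O)O", 7))
  for (i in 1:7) expect_identical(neighbor_count(i, fp), 6L)

  fp2 <- morgan_fp_matrix(c("CCCCCCCC", "c1ccc2ccccc2c1", "OP(O)(O)=O"))
  for (i in 1:3) expect_identical(neighbor_count(i, fp2), 0L)
  expect_error(neighbor_count(9L, fp2), "range")
})

test_that("dense-region labels equal an all-pairs brute-force recount", {
  lib <- fx_library()
  # engineered density: 30 copies of one structure (dense), near-duplicates,
  # and a spread of singletons
  smis <- c(rep(vapply(lib[5:8], canonical_smiles, character(1)), each = 30),
            vapply(lib[100:159], canonical_smiles, character(1)))
  dr <- build_dr_sets(smis, seed = 121L)
  fp <- morgan_fp_matrix(cmorph:::canonical_smiles_batch(
    parse_smiles_batch(smis)))
  brute <- integer(length(smis))
  for (i in seq_along(smis)) {
    cnt <- 0L
    for (j in seq_along(smis)) {
      if (i != j && tanimoto(fp[i, ], fp[j, ]) >= 0.6) cnt <- cnt + 1L
    }
    brute[i] <- cnt
  }
  expect_identical(dr$counts, brute)
  expect_setequal(dr$easy_all, smis[brute >= 20])
  expect_setequal(dr$hard, smis[brute <= 1])
  expect_setequal(dr$unlabeled, smis[brute > 1 & brute < 20])
  # training parity after dedup (capped by the unique easy pool)
  expect_identical(sum(dr$set$label == "easy"),
                   min(length(unique(dr$easy_all)),
                       length(unique(dr$hard))))
  expect_identical(sum(dr$set$label == "hard"), length(unique(dr$hard)))

  empty <- build_dr_sets(character())
  expect_identical(nrow(empty$set), 0L)
})

test_that("dense-region labels do not depend on library order", {
  lib <- fx_library()
  smis <- c(rep(canonical_smiles(lib[[12]]), 25),
            vapply(lib[300:329], canonical_smiles, character(1)))
  set.seed(122)
  perm <- sample(seq_along(smis))
  a <- build_dr_sets(smis, seed = 1L)
  b <- build_dr_sets(smis[perm], seed = 1L)
  expect_identical(a$counts[perm], b$counts)
  expect_setequal(a$hard, b$hard)
  expect_setequal(a$easy_all, b$easy_all)
})

test_that("fixture library is deterministic and spans every MW bin", {
  a <- fixture_library(220, seed = 5L)
  b <- fixture_library(220, seed = 5L)
  expect_identical(attr(a, "smiles"), attr(b, "smiles"))
  expect_identical(length(a), 220L)
  bins <- mw_bin(vapply(a, mol_weight, numeric(1)),
                 bin_width = 50, n_bins = 11L)
  expect_identical(sort(unique(bins)), 0:10)
  expect_true(all(table(bins) >= 10))
  expect_false(identical(attr(fixture_library(55, seed = 6L), "smiles"),
                         attr(fixture_library(55, seed = 7L), "smiles")))
})

test_that("test-set loading enforces labels and reports composition", {
  p <- withr::local_tempfile(fileext = ".smi")
  lib <- fx_library()
  smis <- unique(vapply(lib, canonical_smiles, character(1)))[1:160]
  writeLines(c(paste(smis[1:120], sprintf("t%03d", 1:120), "easy"),
               paste(smis[121:160], sprintf("t%03d", 121:160), "hard")), p)
  ts <- load_test_set(p)
  expect_identical(attr(ts, "role"), "test")
  expect_identical(sum(ts$label == "easy"), 120L)
  expect_identical(sum(ts$label == "hard"), 40L)

  bad <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO a easy", "CCN b difficult"), bad)
  expect_error(load_test_set(bad), "label")
  empty <- withr::local_tempfile(fileext = ".smi")
  writeLines("# nothing", empty)
  expect_error(load_test_set(empty), "empty")
})
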