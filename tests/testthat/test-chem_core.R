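# Molecule handling: SMILES parsing, canonical identity, molecular weight,
# circular fingerprints and Tanimoto similarity.

test_that("parsing resolves implicit hydrogens and rejects bad input", {
  m <- parse_smiles("C")
  expect_identical(n_atoms(m), 1L)
  expect_identical(m$nH, 4L)

  expect_error(parse_smiles("C("), "unbalanced")
  expect_error(parse_smiles("C1CC"), "ring-closure")
  expect_error(parse_smiles(""), "empty")
  expect_error(parse_smiles("C(F)(F)(F)(F)F"), "valence")

  # largest-fragment policy for dot-disconnected input
  expect_identical(n_atoms(parse_smiles("CCO.C")), 3L)

  # formal charges survive the round trip
  tma <- parse_smiles("C[N+](C)(C)C")
  expect_identical(sum(tma$charge), 1L)
  expect_identical(tma$nH[tma$charge == 1L], 0L)
})

test_that("bulk parsing skips invalid records with a warning", {
  smi <- c(a = "CCO", b = "C(", c = "c1ccccc1", d = "C(F)(F)(F)(F)F")
  expect_warning(mols <- parse_smiles_batch(smi), "skipped")
  expect_setequal(names(mols), c("a", "c"))
  expect_setequal(attr(mols, "skipped"), c("b", "d"))
})

test_that("canonical SMILES is encoding-independent and idempotent", {
  expect_identical(canonical_smiles(parse_smiles("OCC")),
                   canonical_smiles(parse_smiles("CCO")))
  expect_identical(canonical_smiles(parse_smiles("c1ccccc1")),
                   canonical_smiles(parse_smiles("C1=CC=CC=C1")))
  m <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O")
  can <- canonical_smiles(m)
  expect_identical(canonical_smiles(parse_smiles(can)), can)
})

test_that("canonical SMILES is invariant under 1000 atom renumberings", {
  m <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O")
  n <- n_atoms(m)
  set.seed(11)
  perms <- lapply(seq_len(1000), function(i) sample.int(n))
  permuted <- lapply(perms, function(p) permute_mol(m, p))
  cans <- cmorph:::canonical_smiles_batch(permuted)
  expect_identical(length(unique(cans)), 1L)
  expect_identical(unique(cans), canonical_smiles(m))
})

test_that("canonical classes match brute-force graph isomorphism", {
  smis <- c("OCC", "CCO", "C(C)O", "CCC", "C1CC1", "C=CC", "CC=C",
            "C1CN1", "N1CC1", "CC(C)C", "CCCC", "OC=O", "C(=O)O")
  mols <- lapply(smis, parse_smiles)
  cans <- vapply(mols, canonical_smiles, character(1))
  for (i in seq_along(mols)) {
    for (j in seq_along(mols)) {
      expect_identical(cans[i] == cans[j], mols_isomorphic(mols[[i]], mols[[j]]),
                       info = paste(smis[i], "vs", smis[j]))
    }
  }
})

test_that("molecular weight matches hand values and an independent backend", {
  expect_equal(mol_weight(parse_smiles("C")), 16.04, tolerance = 1e-3)
  expect_equal(mol_weight(parse_smiles("O")), 18.02, tolerance = 1e-3)

  smis <- c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
            "FC(F)(F)C1CCC(O)CC1", "CCSSCC", "ClCCBr")
  obmols <- ChemmineOB::forEachMol("SMILES", paste(smis, collapse = "\n"),
                                   identity)
  for (k in seq_along(smis)) {
    expect_equal(mol_weight(parse_smiles(smis[k])),
                 ChemmineOB::prop_OB(obmols[[k]])$MW,
                 tolerance = 0.02, info = smis[k])
  }
})

test_that("molecular weight is additive over disjoint fragments", {
  a <- parse_smiles("CCO")
  b <- parse_smiles("c1ccccc1")
  combined <- molgraph(
    c(a$elem, b$elem),
    rbind(a$bonds,
          within(b$bonds, {i <- i + n_atoms(a); j <- j + n_atoms(a)})),
    c(a$charge, b$charge)
  )
  expect_equal(mol_weight(combined), mol_weight(a) + mol_weight(b),
               tolerance = 1e-9)
})

test_that("fingerprints have the contracted shape and identity behavior", {
  f <- morgan_fp(parse_smiles("CCO"))
  expect_length(f, 512L)
  expect_gte(sum(f), 1L)
  expect_identical(attr(f, "radius"), 2L)
  expect_error(morgan_fp(parse_smiles("CCO"), radius = 3L), "radius")

  # representation independence
  expect_identical(as.integer(morgan_fp(parse_smiles("OCC"))),
                   as.integer(morgan_fp(parse_smiles("CCO"))))
  m <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(as.integer(morgan_fp(m)),
                   as.integer(morgan_fp(parse_smiles(canonical_smiles(m)))))

  fm <- morgan_fp_matrix(c("CCO", "c1ccccc1", "CCN"))
  expect_identical(dim(fm), c(3L, 512L))
  expect_true(all(fm %in% 0:1))
  expect_true(all(rowSums(fm) >= 1))
})

test_that("tanimoto follows the set-overlap definition", {
  a <- integer(512); a[c(1, 2, 3)] <- 1L
  b <- integer(512); b[c(2, 3, 4)] <- 1L
  d <- integer(512); d[c(10, 11)] <- 1L
  expect_identical(tanimoto(a, a), 1)
  expect_identical(tanimoto(a, d), 0)
  expect_identical(tanimoto(a, b), 0.5)            # 2 common / 4 union
  expect_identical(tanimoto(integer(512), integer(512)), 1.0)
  expect_error(tanimoto(a, integer(256)), "mismatch")

  # symmetry, bounds, and identity iff equal bitsets
  set.seed(21)
  for (k in 1:25) {
    x <- as.integer(stats::runif(64) < 0.3)
    y <- as.integer(stats::runif(64) < 0.3)
    expect_identical(tanimoto(x, y), tanimoto(y, x))
    expect_gte(tanimoto(x, y), 0)
    expect_lte(tanimoto(x, y), 1)
    expect_identical(tanimoto(x, y) == 1, identical(x, y) || (sum(x | y) == 0))
  }

  # matrix form agrees with the pairwise definition
  fm <- morgan_fp_matrix(c("CCO", "CCN", "c1ccccc1", "CCCC"))
  sim <- cmorph:::tanimoto_matrix(fm)
  for (i in 1:4) for (j in 1:4)
    expect_equal(sim[i, j], tanimoto(fm[i, ], fm[j, ]), tolerance = 1e-12)
})

test_that(".smi and CSV readers follow the record conventions", {
  p <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# comment", "CCO mol1 easy", "c1ccccc1 mol2", "CCN"), p)
  df <- read_smi(p)
  expect_identical(nrow(df), 3L)
  expect_identical(df$smiles, c("CCO", "c1ccccc1", "CCN"))
  expect_identical(df$id, c("mol1", "mol2", NA))
  expect_identical(df$label, c("easy", NA, NA))

  p2 <- withr::local_tempfile(fileext = ".smi")
  write_smi(df, p2)
  expect_identical(read_smi(p2)$smiles, df$smiles)

  pc <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(SMILES = c("CCO", "CCN"),
                              sascore = c(2.5, 7.1)), pc, row.names = FALSE)
  sc <- read_mol_csv(pc)
  expect_identical(names(sc), c("smiles", "sascore"))
  pc_bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), pc_bad, row.names = FALSE)
  expect_error(read_mol_csv(pc_bad), "smiles")
})
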