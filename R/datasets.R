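# Labeled easy/hard set construction by the three competing strategies
# (morphing, SAscore thresholds, dense-region), plus the deterministic
# synthetic fixture library that stands in for large vendor catalogs in
# tests and examples.

#' Labeled SMILES set
#'
#' @param smiles character vector (canonicalized on construction unless
#'   `canonicalize = FALSE`).
#' @param label `"easy"` or `"hard"` per record.
#' @param source free-text provenance tag per record (recycled).
#' @param role `"train"` or `"test"`.
#' @param canonicalize canonicalize and deduplicate within label classes.
#' @returns data.frame of class `labeled_set` with columns `smiles`,
#'   `label`, `source` and attribute `role`.
#' @export
labeled_set <- function(smiles, label, source = "unknown", role = "train",
                        canonicalize = TRUE) {
  stopifnot(length(smiles) == length(label))
  if (!all(label %in% c("easy", "hard")))
    stop("labels must be 'easy' or 'hard'")
  role <- match.arg(role, c("train", "test"))
  df <- data.frame(smiles = as.character(smiles),
                   label = as.character(label),
                   source = rep_len(as.character(source), length(smiles)),
                   stringsAsFactors = FALSE)
  if (canonicalize && nrow(df)) {
    mols <- parse_smiles_batch(df$smiles)
    kept <- names(mols)
    df <- df[as.integer(kept), , drop = FALSE]
    df$smiles <- canonical_smiles_batch(mols)
  }
  df <- df[!duplicated(paste(df$smiles, df$label)), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, role = role, class = c("labeled_set", "data.frame"))
}

#' Build easy/hard training sets by morphing
#'
#' Hard examples are the threshold-crossing terminal morphs of
#' [generate_library()]; easy examples are either the starting structures
#' of the successful paths (`easy_from = "starts"`, the pairing used in the
#' stop-condition grid) or an equal-size random sample from a reference
#' library of accessible compounds (`easy_from = "reference"`).
#'
#' @param starts starting structures (list of `molgraph` or SMILES vector).
#' @param table calibrated `threshold_table`.
#' @param cond a [stop_condition()].
#' @param easy_from `"starts"` or `"reference"`.
#' @param reference SMILES vector (required for `easy_from = "reference"`).
#' @param max_steps morph step cap.
#' @param seed integer seed.
#' @returns List with `set` (a `labeled_set`) and `library` (the
#'   `morph_library` bookkeeping).
#' @export
build_nonpher_sets <- function(starts, table, cond = stop_condition(),
                               easy_from = c("starts", "reference"),
                               reference = NULL, max_steps = 30L,
                               seed = 1L) {
  easy_from <- match.arg(easy_from)
  if (is.character(starts)) starts <- parse_smiles_batch(starts)
  nm <- names(starts)
  if (is.null(nm)) nm <- names(starts) <- as.character(seq_along(starts))
  lib <- generate_library(starts, table, cond, max_steps, seed = seed)
  hard <- lib$hard
  if (!nrow(hard)) {
    warning("no morphing path crossed the thresholds; empty set")
    return(list(set = labeled_set(character(), character(),
                                  canonicalize = FALSE),
                library = lib))
  }
  if (easy_from == "starts") {
    start_smi <- canonical_smiles_batch(starts[hard$start])
    # strict 1:1 pairing: drop pairs whose start repeats so that the easy
    # and hard classes stay equal-sized after deduplication
    keep <- !duplicated(start_smi) & start_smi != hard$smiles
    hard <- hard[keep, , drop = FALSE]
    easy_smi <- start_smi[keep]
  } else {
    if (is.null(reference)) stop("reference library required")
    ref_mols <- parse_smiles_batch(reference)
    ref_smi <- setdiff(unique(canonical_smiles_batch(ref_mols)),
                       hard$smiles)
    if (length(ref_smi) < nrow(hard))
      stop("reference library smaller than the hard set")
    set.seed(seed + 1L)
    easy_smi <- sample(ref_smi, nrow(hard))
  }
  set <- labeled_set(
    c(easy_smi, hard$smiles),
    c(rep("easy", length(easy_smi)), rep("hard", nrow(hard))),
    source = "morphing", canonicalize = FALSE
  )
  list(set = set, library = lib)
}

#' Build easy/hard sets from precomputed SAscore values
#'
#' Hard examples are records whose SAscore strictly exceeds 6; easy
#' examples are sampled uniformly from records with SAscore strictly below
#' 4; scores in `[4, 6]` are excluded from both classes. SAscore itself is
#' consumed as an input column, never computed here.
#'
#' @param scored data.frame with columns `smiles` and `sascore`.
#' @param n_easy easy-class size (default: match the hard class).
#' @param seed integer seed for the easy-class sample.
#' @returns A `labeled_set`.
#' @export
build_sascore_sets <- function(scored, n_easy = NULL, seed = 1L) {
  stopifnot(all(c("smiles", "sascore") %in% names(scored)))
  hard <- scored$smiles[scored$sascore > 6]
  pool <- scored$smiles[scored$sascore < 4]
  if (is.null(n_easy)) n_easy <- length(hard)
  if (n_easy > length(pool))
    stop("easy pool (", length(pool), ") smaller than requested ", n_easy)
  set.seed(seed)
  easy <- sample(pool, n_easy)
  labeled_set(c(easy, hard),
              c(rep("easy", length(easy)), rep("hard", length(hard))),
              source = "sascore")
}

#' Number of fingerprint neighbors of one molecule
#'
#' Count of other library members with Tanimoto similarity at or above `t`
#' (the query itself is excluded).
#'
#' @param i 1-based index into `fps`.
#' @param fps 0/1 fingerprint matrix (rows = molecules).
#' @param t Tanimoto threshold (default 0.6).
#' @returns Integer neighbor count.
#' @export
neighbor_count <- function(i, fps, t = 0.6) {
  fps <- as.matrix(fps)
  if (i < 1L || i > nrow(fps)) stop("index out of range")
  stopifnot(t >= 0, t <= 1)
  sims <- vapply(seq_len(nrow(fps)), function(j) tanimoto(fps[i, ], fps[j, ]),
                 numeric(1))
  sum(sims[-i] >= t)
}

#' Build easy/hard sets by chemical-space density (dense region)
#'
#' A compound with `easy_min` (20) or more Tanimoto-0.6 neighbors is
#' labeled easy, one with at most `hard_max` (1) neighbor hard; the middle
#' band stays unlabeled but is returned for auditability. The easy class is
#' subsampled to the hard-class size for training parity.
#'
#' @param library SMILES vector.
#' @param t Tanimoto threshold (default 0.6).
#' @param easy_min minimum neighbor count for the easy class (default 20).
#' @param hard_max maximum neighbor count for the hard class (default 1).
#' @param seed integer seed for the parity subsample.
#' @param nbits fingerprint length.
#' @returns List with `set` (parity `labeled_set`), `easy_all`, `hard`,
#'   `unlabeled` (character SMILES) and `counts` (integer neighbor counts).
#' @export
build_dr_sets <- function(library, t = 0.6, easy_min = 20L, hard_max = 1L,
                          seed = 1L, nbits = 512L) {
  if (!length(library)) {
    empty <- labeled_set(character(), character(), canonicalize = FALSE)
    return(list(set = empty, easy_all = character(),
                hard = character(), unlabeled = character(),
                counts = integer()))
  }
  mols <- parse_smiles_batch(library)
  smi <- canonical_smiles_batch(mols)  # duplicates kept: density counting
  fp <- morgan_fp_matrix(smi, nbits)
  sim <- tanimoto_matrix(fp)
  counts <- as.integer(rowSums(sim >= t) - 1L)
  easy_all <- smi[counts >= easy_min]
  hard <- smi[counts <= hard_max]
  unlab <- smi[counts > hard_max & counts < easy_min]
  set.seed(seed)
  easy_u <- unique(easy_all)
  hard_u <- unique(hard)
  easy <- if (length(easy_u) > length(hard_u))
    sort(sample(easy_u, length(hard_u))) else easy_u
  set <- labeled_set(c(easy, hard_u),
                     c(rep("easy", length(easy)), rep("hard", length(hard_u))),
                     source = "dense-region", canonicalize = FALSE)
  list(set = set, easy_all = easy_all, hard = hard, unlabeled = unlab,
       counts = counts)
}

# Divalent fragment vocabulary for the fixture generator: inline SMILES and
# the mass each fragment contributes when embedded in a chain.
.fixture_fragments <- local({
  am <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
          F = 18.998, Cl = 35.45)
  frag <- function(smi, C = 0, H = 0, N = 0, O = 0, S = 0, F = 0, Cl = 0) {
    list(smi = smi,
         mass = C * am["C"] + H * am["H"] + N * am["N"] + O * am["O"] +
           S * am["S"] + F * am["F"] + Cl * am["Cl"])
  }
  list(
    frag("C", C = 1, H = 2),                     # methylene
    frag("CC", C = 2, H = 4),                    # ethylene
    frag("C(C)", C = 2, H = 4),                  # methyl branch
    frag("O", O = 1),                            # ether
    frag("N", N = 1, H = 1),                     # secondary amine
    frag("S", S = 1),                            # thioether
    frag("C(=O)", C = 1, O = 1),                 # carbonyl
    frag("C(=O)O", C = 1, O = 2),                # ester linkage
    frag("C=C", C = 2, H = 2),                   # alkene
    frag("C(F)", C = 1, H = 1, F = 1),           # fluoromethylene
    frag("C(Cl)", C = 1, H = 1, Cl = 1),         # chloromethylene
    frag("C1=CC=C(C=C1)", C = 6, H = 4),         # para-phenylene
    frag("C1CCC(CC1)", C = 6, H = 10),           # cyclohexylene
    frag("C1=CC=C(C=C1)C", C = 7, H = 6),        # tolylene
    frag("C(N)", C = 1, H = 3, N = 1)            # aminomethylene
  )
})

# Single-fragment molecules for the first MW bin (< 50 Da).
.fixture_small <- c("C", "CC", "CO", "CCC", "CN", "O", "CCO", "C=C", "C#C",
                    "CCN", "C=O", "N")

#' Deterministic synthetic SMILES library spanning all MW bins
#'
#' Generates `n` valid structures by combinatorial assembly of
#' alkyl/ether/amine/aryl fragments, cycling the target MW bin so every
#' 50-Da bin from 0 to `n_bins - 1` is populated. The library emulates the
#' MW coverage of a screening catalog at desk scale so that calibration,
#' morphing, dense-region and classifier code paths can run without any
#' download; it does not emulate a real catalog's scaffold diversity (see
#' the methods vignette).
#'
#' @param n number of molecules (default 1100).
#' @param seed integer seed; identical `(n, seed)` gives an identical
#'   library.
#' @param bin_width,n_bins MW bin geometry to span.
#' @returns Named list of `molgraph` objects; names are record ids, the
#'   `"smiles"` attribute carries the generated SMILES.
#' @export
fixture_library <- function(n = 1100L, seed = 1L, bin_width = 50,
                            n_bins = 11L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  frags <- .fixture_fragments
  masses <- vapply(frags, `[[`, numeric(1), "mass")
  hcap <- 2 * 1.008
  smiles <- character(n)
  for (k in seq_len(n)) {
    b <- (k - 1L) %% n_bins
    if (b == 0L) {
      smiles[k] <- sample(.fixture_small, 1L)
      next
    }
    lo <- b * bin_width
    hi <- lo + bin_width
    total <- hcap
    parts <- character()
    while (total < lo) {
      ok <- which(total + masses < hi)
      pick <- ok[sample.int(length(ok), 1L)]
      parts <- c(parts, frags[[pick]]$smi)
      total <- total + masses[pick]
    }
    smiles[k] <- paste(parts, collapse = "")
  }
  names(smiles) <- sprintf("fix%05d", seq_len(n))
  mols <- parse_smiles_batch(smiles)
  if (length(mols) != n)
    stop("fixture generator produced unparsable SMILES")  # generator contract
  attr(mols, "smiles") <- smiles
  mols
}

#' Load a labeled test set from a .smi file
#'
#' Expects `SMILES id label` records with label `easy` or `hard` (the
#' layout of curated benchmark files such as a 120-easy / 40-hard
#' collection). Unknown label tokens and unparsable structures are
#' reported with their line numbers.
#'
#' @param path .smi path.
#' @returns A `labeled_set` with role `"test"`.
#' @export
load_test_set <- function(path) {
  df <- read_smi(path)
  if (!nrow(df)) stop("empty test-set file: ", path)
  lab <- ifelse(is.na(df$label) & !is.na(df$id) &
                  df$id %in% c("easy", "hard"), df$id, df$label)
  bad <- which(is.na(lab) | !(lab %in% c("easy", "hard")))
  if (length(bad))
    stop("missing/unknown label on record(s): ",
         paste(utils::head(bad, 20), collapse = ", "))
  labeled_set(df$smiles, lab, source = basename(path), role = "test")
}
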