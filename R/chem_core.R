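# SMILES I/O, canonicalization, circular fingerprints and Tanimoto
# similarity. Format conversions are delegated to OpenBabel (through
# ChemmineOB and the obabel binary); the package only owns the graph
# object defined in molgraph.R.

.ob <- function(from, to, source) {
  ChemmineOB::convertFormat(from, to, source)
}

# Light well-formedness screen applied before handing a SMILES string to
# OpenBabel, which silently repairs some malformed inputs (e.g. "C(").
.check_smiles_syntax <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    return("empty SMILES")
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]", s))
    return("illegal character in SMILES")
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) return("unbalanced parentheses")
  }
  if (depth != 0L) return("unbalanced parentheses")
  br <- cumsum((chars == "[") - (chars == "]"))
  if (any(br > 1L) || any(br < 0L) || br[length(br)] != 0L)
    return("unbalanced brackets")
  # ring-closure digits must come in pairs (outside atom brackets)
  outside <- br == 0L & chars != "]"
  digits <- chars[outside & chars %in% as.character(0:9)]
  # drop digits that belong to %nn two-digit closures: treat each %nn as one
  s_nobr <- gsub("\\[[^]]*\\]", "A", s)
  two <- gregexpr("%[0-9]{2}", s_nobr)[[1]]
  ids <- character()
  if (two[1] != -1)
    ids <- regmatches(s_nobr, gregexpr("%[0-9]{2}", s_nobr))[[1]]
  s_rest <- gsub("%[0-9]{2}", "", s_nobr)
  ids <- c(ids, regmatches(s_rest, gregexpr("[0-9]", s_rest))[[1]])
  # every un-bracketed digit is one ring closure; counts must be even per id
  tab <- table(ids)
  if (any(tab %% 2L != 0L)) return("unmatched ring-closure digit")
  NULL
}

# Parse one V2000 molblock into a molgraph (coordinates discarded).
parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("truncated molblock")
  counts <- lines[4]
  n <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n) || is.na(nb) || n < 1L) stop("empty or unreadable molblock")
  atoms <- lines[5:(4 + n)]
  elem <- trimws(substr(atoms, 32, 34))
  oldchg <- suppressWarnings(as.integer(substr(atoms, 37, 39)))
  charge <- integer(n)
  known <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  hit <- !is.na(oldchg) & oldchg %in% as.integer(names(known))
  charge[hit] <- known[as.character(oldchg[hit])]
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  if (nb > 0L) {
    bl <- lines[(5 + n):(4 + n + nb)]
    bonds <- data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
    if (any(bonds$order == 4L))
      stop("aromatic (order 4) bonds unsupported; kekulize first")
  }
  # modern charge properties override the atom-line field
  chglines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chglines)) {
    charge <- integer(n)
    for (cl in chglines) {
      k <- as.integer(substr(cl, 7, 9))
      for (e in seq_len(k)) {
        off <- 10 + (e - 1) * 8
        idx <- as.integer(substr(cl, off, off + 3))
        val <- as.integer(substr(cl, off + 4, off + 7))
        charge[idx] <- val
      }
    }
  }
  molgraph(elem, bonds, charge)
}

# Keep the largest connected component (fragment) of a molgraph.
largest_fragment <- function(m) {
  g <- mol_igraph(m)
  comp <- igraph::components(g)
  if (comp$no == 1L) return(m)
  keep <- which(comp$membership == which.max(comp$csize))
  subset_atoms(m, keep)
}

# Induced subgraph on a set of atom indices.
subset_atoms <- function(m, keep) {
  keep <- sort(keep)
  remap <- integer(length(m$elem))
  remap[keep] <- seq_along(keep)
  b <- m$bonds
  b <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
  b$i <- remap[b$i]
  b$j <- remap[b$j]
  molgraph(m$elem[keep], b, m$charge[keep])
}

#' Parse a SMILES string
#'
#' Converts a SMILES string into the package's sanitized molecular graph.
#' Implicit hydrogens are resolved from the valence model; multi-fragment
#' inputs (dot-separated SMILES) are reduced to their largest fragment;
#' aromatic rings are kekulized.
#'
#' @param s a single SMILES string.
#' @returns A `molgraph` object.
#' @examples
#' m <- parse_smiles("c1ccccc1")
#' n_atoms(m)
#' @export
parse_smiles <- function(s) {
  msg <- .check_smiles_syntax(s)
  if (!is.null(msg)) stop("invalid SMILES '", s, "': ", msg)
  mb <- tryCatch(.ob("SMI", "MOL", paste0(s, "\n")),
                 error = function(e) "")
  if (!nzchar(mb) || !grepl("V2000", mb))
    stop("invalid SMILES '", s, "': OpenBabel could not parse it")
  m <- parse_molblock(mb)
  largest_fragment(m)
}

#' Parse many SMILES, skipping invalid records
#'
#' Bulk counterpart of [parse_smiles()]: unparsable or valence-violating
#' records are dropped with a warning rather than aborting the read, which
#' is the behavior large SMILES libraries require.
#'
#' @param smiles character vector of SMILES.
#' @returns A named list of `molgraph` objects (names are the input indices
#'   as characters, or `names(smiles)` when present); skipped records are
#'   reported via a warning and recorded in the `"skipped"` attribute.
#' @export
parse_smiles_batch <- function(smiles) {
  nm <- names(smiles)
  if (is.null(nm)) nm <- as.character(seq_along(smiles))
  src <- paste0(paste(smiles, seq_along(smiles), sep = "\t"),
                collapse = "\n")
  sdf <- tryCatch(.ob("SMI", "SDF", paste0(src, "\n")),
                  error = function(e) "")
  recs <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  out <- vector("list", length(smiles))
  for (r in recs) {
    r <- sub("^\n+", "", r)
    title <- strsplit(r, "\n", fixed = TRUE)[[1]][1]
    idx <- suppressWarnings(as.integer(trimws(title)))
    if (is.na(idx) || idx < 1L || idx > length(smiles)) next
    syntax <- .check_smiles_syntax(smiles[idx])
    m <- if (is.null(syntax)) {
      tryCatch(largest_fragment(parse_molblock(r)), error = function(e) NULL)
    } else NULL
    if (!is.null(m)) out[[idx]] <- m
  }
  seen <- which(!vapply(out, is.null, logical(1)))
  skipped <- setdiff(seq_along(smiles), seen)
  out <- out[seen]
  names(out) <- nm[seen]
  if (length(skipped))
    warning(length(skipped), " record(s) failed to parse and were skipped: ",
            paste(utils::head(nm[skipped], 10), collapse = ", "))
  attr(out, "skipped") <- nm[skipped]
  out
}

#' Canonical SMILES
#'
#' Deterministic canonical SMILES (OpenBabel canonical form); equal for all
#' SMILES encodings of the same structure. This is the identity used for
#' morph deduplication.
#'
#' @param m a `molgraph`.
#' @returns A single SMILES string.
#' @export
canonical_smiles <- function(m) {
  stopifnot(inherits(m, "molgraph"))
  out <- .ob("MOL", "CAN", to_molblock(m))
  s <- strsplit(trimws(out), "[ \t\n]+")[[1]][1]
  if (is.na(s) || !nzchar(s)) stop("canonicalization failed")
  s
}

# Vectorized canonicalization of molgraphs through one OpenBabel call.
canonical_smiles_batch <- function(mols) {
  if (!length(mols)) return(character())
  sdf <- paste(vapply(mols, to_molblock, character(1)), collapse = "\n$$$$\n")
  out <- .ob("SDF", "CAN", paste0(sdf, "\n$$$$\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != length(mols))
    stop("batch canonicalization lost records (", length(lines), "/",
         length(mols), ")")
  vapply(strsplit(trimws(lines), "[ \t]+"), `[`, character(1), 1L)
}

# ---- circular fingerprints -------------------------------------------------

.fp_backend <- "openbabel ECFP4 (radius-2 circular), folded"

.hex_bits <- local({
  tab <- matrix(0L, 16, 4)
  for (v in 0:15) tab[v + 1, ] <- as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L)
  rownames(tab) <- c(0:9, letters[1:6])
  tab
})

# Decode obabel -ofpt hex dump (one block per molecule) into a 0/1 matrix.
.decode_fpt <- function(lines, nbits) {
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no fingerprints in obabel output")
  ends <- c(starts[-1] - 1L, length(lines))
  t(vapply(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1L):ends[k]]
    block <- block[grepl("^[0-9a-fA-F ]+$", block)]  # drop commentary lines
    hx <- paste(block, collapse = " ")
    words <- strsplit(trimws(hx), "[ \t]+")[[1]]
    chars <- strsplit(tolower(paste(words, collapse = "")), "")[[1]]
    bits <- as.vector(t(.hex_bits[chars, , drop = FALSE]))
    if (length(bits) != nbits)
      stop("fingerprint length ", length(bits), " != ", nbits)
    bits
  }, integer(nbits)))
}

#' Circular fingerprints for a set of SMILES
#'
#' Computes radius-2 circular (ECFP4-class) fingerprints folded to a fixed
#' length, one row per input SMILES, via the OpenBabel fingerprint engine in
#' a single batch call.
#'
#' @param smiles character vector of SMILES strings.
#' @param nbits fingerprint length in bits (default 512).
#' @returns Integer 0/1 matrix with `length(smiles)` rows and `nbits`
#'   columns; rownames are the input names (or indices).
#' @export
morgan_fp_matrix <- function(smiles, nbits = 512L) {
  stopifnot(length(smiles) >= 1L, nbits >= 32L)
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel)) stop("obabel binary not found on PATH")
  nm <- names(smiles)
  if (is.null(nm)) nm <- as.character(seq_along(smiles))
  fin <- tempfile(fileext = ".smi")
  on.exit(unlink(fin), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), fin)
  out <- suppressWarnings(
    system2(obabel, c(fin, "-ofpt", "-xfECFP4", paste0("-xN", nbits), "-xh"),
            stdout = TRUE, stderr = FALSE))
  fp <- .decode_fpt(out, nbits)
  got <- as.integer(sub("^>([0-9]+).*", "\\1",
                        grep("^>", out, value = TRUE)))
  if (length(got) != length(smiles))
    stop("fingerprinting skipped ", length(smiles) - length(got),
         " record(s); parse the library first")
  rownames(fp) <- nm[got]
  fp[order(got), , drop = FALSE]
}

#' Circular fingerprint of one molecule
#'
#' @param m a `molgraph` (or a SMILES string).
#' @param radius neighborhood radius; only the ECFP4 radius of 2 is
#'   supported by the fingerprint backend.
#' @param nbits fingerprint length (default 512).
#' @returns Integer 0/1 vector of class `morganfp` with attributes `radius`,
#'   `nbits` and `backend`.
#' @export
morgan_fp <- function(m, radius = 2L, nbits = 512L) {
  if (radius != 2L)
    stop("the fingerprint backend is fixed at radius 2 (ECFP4)")
  smi <- if (inherits(m, "molgraph")) canonical_smiles(m) else
    canonical_smiles(parse_smiles(m))
  v <- morgan_fp_matrix(smi, nbits)[1L, ]
  structure(as.integer(v), class = "morganfp", radius = radius,
            nbits = nbits, backend = .fp_backend)
}

#' Tanimoto similarity between two bit fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|} on set bits; defined as 1 when both
#' fingerprints are empty.
#'
#' @param a,b equal-length 0/1 fingerprint vectors.
#' @returns Numeric similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b))
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  u <- sum(a | b)
  if (u == 0L) return(1.0)
  sum(a & b) / u
}

# All-pairs Tanimoto matrix from a 0/1 fingerprint matrix (rows = molecules).
tanimoto_matrix <- function(fp) {
  fp <- as.matrix(fp)
  storage.mode(fp) <- "double"
  inter <- tcrossprod(fp)
  pop <- rowSums(fp)
  uni <- outer(pop, pop, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1e-300))
  sim
}

# ---- file formats ----------------------------------------------------------

#' Read a .smi file
#'
#' One record per line: `SMILES [whitespace] optional-id [whitespace]
#' optional-label`; lines starting with `#` are comments.
#'
#' @param path file path.
#' @returns data.frame with columns `smiles`, `id`, `label` (NA when absent).
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(smiles = character(), id = character(),
                      label = character()))
  parts <- strsplit(lines, "[ \t]+")
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1L),
    id = vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                character(1)),
    label = vapply(parts, function(p) if (length(p) >= 3) p[3] else
      NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a .smi file
#'
#' @param df data.frame with a `smiles` column and optional `id` / `label`.
#' @param path output path.
#' @returns `path`, invisibly.
#' @export
write_smi <- function(df, path) {
  stopifnot("smiles" %in% names(df))
  cols <- df$smiles
  if (!is.null(df$id)) cols <- paste(cols, df$id, sep = "\t")
  if (!is.null(df$label)) cols <- paste(cols, df$label, sep = "\t")
  writeLines(cols, path)
  invisible(path)
}

#' Read a CSV with a smiles column
#'
#' Generic reader for score tables (e.g. a precomputed SAscore column next
#' to each structure).
#'
#' @param path CSV path; must contain a `smiles` column.
#' @returns data.frame.
#' @export
read_mol_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"smiles" %in% names(df)) stop("CSV must contain a 'smiles' column")
  df
}
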