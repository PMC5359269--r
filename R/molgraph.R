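# Internal molecular-graph representation used by the morphing engine.
#
# A `molgraph` is a hydrogen-suppressed connected multigraph-free graph:
# heavy atoms carry an element symbol, a formal charge and an implicit
# hydrogen count; bonds carry an integer order 1..3 (aromatic systems are
# kept kekulized throughout).

# Smallest-first lists of allowed bonding valences per element (neutral).
.base_valences <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L,
  Br = 1L, I = 1L
)

# Average atomic masses (Da), sufficient for the supported alphabet.
.atomic_masses <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  Br = 79.904, I = 126.904
)

#' Construct a molecular graph
#'
#' Builds the package's internal molecule object from element symbols,
#' formal charges and a bond table, then sanitizes it (valence check and
#' implicit-hydrogen assignment). Users normally obtain molecules with
#' [parse_smiles()]; this constructor is exposed for programmatic building
#' and for tests.
#'
#' @param elem character vector of element symbols for the heavy atoms.
#' @param bonds data.frame (or matrix) with columns `i`, `j`, `order`;
#'   1-based atom indices, integer order 1, 2 or 3.
#' @param charge integer vector of formal charges (default all 0).
#' @returns An object of class `molgraph`.
#' @seealso [parse_smiles()], [canonical_smiles()], [mol_weight()]
#' @export
molgraph <- function(elem, bonds = NULL, charge = NULL) {
  elem <- as.character(elem)
  n <- length(elem)
  if (n == 0L) stop("a molecule must contain at least one atom")
  if (is.null(charge)) charge <- integer(n)
  charge <- as.integer(charge)
  if (length(charge) != n) stop("charge must have one entry per atom")
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:3] <- c("i", "j", "order")
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
  }
  m <- structure(
    list(elem = elem, charge = charge, bonds = bonds, nH = integer(n)),
    class = "molgraph"
  )
  sanitize(m)
}

#' Sanitize a molecular graph
#'
#' Checks elements, bond indices and bond orders, verifies that every atom's
#' bond-order sum is chemically admissible for its element and formal charge,
#' and fills in implicit hydrogen counts (smallest allowed valence not below
#' the bond-order sum).
#'
#' @param m a `molgraph`.
#' @returns The sanitized `molgraph` (with `nH` populated).
#' @export
sanitize <- function(m) {
  stopifnot(inherits(m, "molgraph"))
  n <- length(m$elem)
  b <- m$bonds
  unknown <- setdiff(unique(m$elem), names(.base_valences))
  if (length(unknown))
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  if (nrow(b)) {
    if (any(b$i < 1L | b$i > n | b$j < 1L | b$j > n))
      stop("bond endpoint out of range")
    if (any(b$i == b$j)) stop("self-bond not allowed")
    if (any(is.na(b$order)) || any(b$order < 1L | b$order > 3L))
      stop("bond order must be 1, 2 or 3")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) stop("duplicate bond")
  }
  bs <- bond_order_sum(m)
  nH <- integer(n)
  # fast path: neutral atoms of single-valence elements
  single <- c(C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, Cl = 1L,
              Br = 1L, I = 1L, B = 3L, H = 1L)
  fast <- m$charge == 0L & m$elem %in% names(single)
  if (any(fast)) {
    v <- single[m$elem[fast]]
    if (any(v < bs[fast])) {
      a <- which(fast)[which(v < bs[fast])[1]]
      stop(sprintf("valence violation at atom %d (%s%+d): bond order sum %d",
                   a, m$elem[a], m$charge[a], bs[a]))
    }
    nH[fast] <- v - bs[fast]
  }
  for (a in which(!fast)) {
    allowed <- .allowed_valences(m$elem[a], m$charge[a])
    v <- allowed[allowed >= bs[a]]
    if (!length(v))
      stop(sprintf("valence violation at atom %d (%s%+d): bond order sum %d",
                   a, m$elem[a], m$charge[a], bs[a]))
    nH[a] <- min(v) - bs[a]
  }
  m$nH <- nH
  m
}

# Allowed valences for an element at a formal charge. Positive charge adds a
# bonding slot for N/O/S/P-type donors, negative charge removes one; charged
# carbon loses a slot in either direction.
.allowed_valences <- function(elem, charge) {
  base <- .base_valences[[elem]]
  if (charge == 0L) return(base)
  if (elem %in% c("C", "Si")) {
    v <- base - abs(charge)
  } else {
    v <- base + charge
  }
  v <- v[v >= 0L]
  if (!length(v)) stop("no admissible valence for ", elem, " charge ", charge)
  v
}

# Per-atom sum of bond orders (heavy neighbors only).
bond_order_sum <- function(m) {
  n <- length(m$elem)
  if (!nrow(m$bonds)) return(integer(n))
  ends <- c(m$bonds$i, m$bonds$j)
  w <- c(m$bonds$order, m$bonds$order)
  as.integer(tabulate(rep(ends, w), nbins = n))
}

# Heavy-atom degree vector.
mol_degree <- function(m) {
  n <- length(m$elem)
  if (!nrow(m$bonds)) return(integer(n))
  tabulate(c(m$bonds$i, m$bonds$j), nbins = n)
}

# igraph view of the heavy-atom skeleton.
mol_igraph <- function(m) {
  igraph::graph_from_data_frame(
    d = if (nrow(m$bonds)) m$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_along(m$elem))
  )
}

# TRUE when the heavy-atom graph has a single connected component.
is_connected_mol <- function(m) {
  if (length(m$elem) == 1L) return(TRUE)
  igraph::is_connected(mol_igraph(m))
}

#' Number of heavy atoms
#' @param m a `molgraph`.
#' @returns Integer count of non-hydrogen atoms.
#' @export
n_atoms <- function(m) length(m$elem)

#' Molecular weight
#'
#' Average molecular weight in daltons, implicit hydrogens included.
#'
#' @param m a `molgraph`.
#' @returns Numeric weight (Da).
#' @examples
#' mol_weight(parse_smiles("C"))  # 16.04
#' mol_weight(parse_smiles("O"))  # 18.02
#' @export
mol_weight <- function(m) {
  stopifnot(inherits(m, "molgraph"))
  sum(.atomic_masses[m$elem]) + sum(m$nH) * .atomic_masses[["H"]]
}

# Serialize a molgraph as a V2000 molfile block (coordinates zeroed;
# charges written as M CHG properties).
to_molblock <- function(m, name = "") {
  n <- length(m$elem)
  nb <- nrow(m$bonds)
  lines <- c(
    name,
    "  cmorph",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, m$elem),
    if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                    m$bonds$i, m$bonds$j, m$bonds$order)
  )
  chg <- which(m$charge != 0L)
  if (length(chg)) {
    grp <- split(chg, ceiling(seq_along(chg) / 8))
    lines <- c(lines, vapply(grp, function(idx) {
      paste0(sprintf("M  CHG%3d", length(idx)),
             paste0(sprintf("%4d%4d", idx, m$charge[idx]), collapse = ""))
    }, character(1)))
  }
  paste(c(lines, "M  END"), collapse = "\n")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d heavy atoms, %d bonds, MW %.2f Da>\n",
              length(x$elem), nrow(x$bonds), mol_weight(x)))
  cat(" ", canonical_smiles(x), "\n")
  invisible(x)
}

# Structural identity at graph level (used by the single-edit checker in
# tests); canonical SMILES remains the user-facing identity.
mol_signature <- function(m) {
  b <- m$bonds
  if (nrow(b)) {
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j), b$order, sep = ":")
    key <- sort(key)
  } else key <- character()
  paste(paste(m$elem, m$charge, collapse = ","), paste(key, collapse = ","),
        sep = "|")
}
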