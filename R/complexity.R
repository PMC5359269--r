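# The four molecular-complexity indices that terminate morphing paths:
# Bertz (graph information content over bond connections plus heteroatom
# distribution), Whitlock (weighted ring/unsaturation/heteroatom/stereocenter
# count), Barone-Chanon (additive degree/ring contributions) and an
# SMCM-style atom/bond/ring/chirality sum. All are computed on the
# hydrogen-suppressed kekulized graph and are invariant under atom
# renumbering.

# ---- shared graph quantities ----------------------------------------------

# Topological symmetry classes: atoms sharing an identical sorted vector of
# bond-order-weighted shortest-path distances to all other atoms (compared
# at 4 decimals) are one class. Heavy lifting in src/complexity_fast.cpp.
.symmetry_classes <- function(m, cutoff = 100L) {
  D <- cpp_bo_dist(length(m$elem), m$bonds$i, m$bonds$j, m$bonds$order)
  cpp_symmetry_classes(D, as.integer(cutoff))
}

# Iterative neighborhood refinement ranks (Morgan-style): used to decide
# whether the branches around a candidate stereocenter are distinct.
.refinement_ranks <- function(m) {
  deg <- mol_degree(m)
  inv <- paste(m$elem, m$charge, deg, m$nH, bond_order_sum(m))
  rank <- match(inv, unique(sort(inv)))
  if (!nrow(m$bonds)) return(rank)
  cpp_refine_ranks(as.integer(rank), m$bonds$i, m$bonds$j, m$bonds$order)
}

# Potential tetrahedral stereocenters. An atom qualifies when it is a
# four-coordinate carbon (counting implicit H), bears at most one hydrogen,
# and its heavy-atom neighbors fall into pairwise distinct refinement
# classes. Unassigned centers count by design: morphing never sets stereo
# labels, but stereo-rich skeletons must register as complex.
count_stereocenters <- function(m) {
  n <- length(m$elem)
  if (n < 4L || !nrow(m$bonds)) return(0L)
  deg <- mol_degree(m)
  cand <- which(m$elem == "C" & deg + m$nH == 4L & m$nH <= 1L & deg >= 3L)
  if (!length(cand)) return(0L)
  rank <- .refinement_ranks(m)
  adj <- vector("list", n)
  for (r in seq_len(nrow(m$bonds))) {
    adj[[m$bonds$i[r]]] <- c(adj[[m$bonds$i[r]]], m$bonds$j[r])
    adj[[m$bonds$j[r]]] <- c(adj[[m$bonds$j[r]]], m$bonds$i[r])
  }
  sum(vapply(cand, function(a) {
    nb <- rank[adj[[a]]]
    anyDuplicated(nb) == 0L
  }, logical(1)))
}

# Ring count (cyclomatic number) of the heavy-atom graph.
ring_count <- function(m) {
  ncomp <- .n_components(m)
  nrow(m$bonds) - length(m$elem) + ncomp
}

.n_components <- function(m) {
  n <- length(m$elem)
  if (!nrow(m$bonds)) return(n)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(m$bonds))) {
    a <- find(m$bonds$i[r]); b <- find(m$bonds$j[r])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

.info_entropy <- function(counts) {
  counts <- counts[counts > 0]
  tot <- sum(counts)
  if (tot == 0 || length(counts) < 2L) return(0)
  p <- counts / tot
  -sum(p * log2(p))
}

# ---- the four indices ------------------------------------------------------

#' Bertz complexity index
#'
#' Graph-theoretic information content of the bonding pattern plus an
#' information term for the heteroatom distribution. Bond "connections" are
#' counted between topological symmetry classes (atoms with identical
#' bond-order-weighted distance profiles) so the index is invariant under
#' atom renumbering; values on kekulized aromatic systems follow the
#' kekulized bond orders.
#'
#' @param m a `molgraph`.
#' @returns Non-negative numeric complexity; 0 for a single atom.
#' @export
bertz_index <- function(m) {
  stopifnot(inherits(m, "molgraph"))
  n <- length(m$elem)
  if (n < 2L) return(0)
  cls <- .symmetry_classes(m)
  counts <- cpp_bertz_connections(n, m$bonds$i, m$bonds$j, m$bonds$order,
                                  cls)
  if (!length(counts)) counts <- 1
  tot <- sum(counts)
  connection_ie <- tot * (.info_entropy(counts) + log2(tot))
  atom_ie <- n * .info_entropy(as.numeric(table(m$elem)))
  connection_ie + atom_ie
}

#' Whitlock complexity index
#'
#' Weighted structural-feature count: 4 per ring, 2 per unit of
#' unsaturation, 1 per heteroatom, 2 per (potential) stereocenter.
#' Unsaturation is counted on the kekulized graph, so benzene contributes
#' one ring and three unsaturations.
#'
#' @param m a `molgraph`.
#' @returns Non-negative integer-valued score.
#' @export
whitlock_index <- function(m) {
  stopifnot(inherits(m, "molgraph"))
  rings <- ring_count(m)
  unsat <- if (nrow(m$bonds)) sum(m$bonds$order - 1L) else 0L
  het <- sum(m$elem != "C")
  chiral <- count_stereocenters(m)
  4 * rings + 2 * unsat + 1 * het + 2 * chiral
}

#' Barone-Chanon additive complexity index
#'
#' Simple additivity over the heavy-atom skeleton: each atom contributes 3
#' times its heavy-atom degree, heteroatoms add a further 3, and each ring
#' adds 6. This is the package's documented reading of the simple additive
#' Barone-Chanon index (see the methods vignette).
#'
#' @param m a `molgraph`.
#' @returns Non-negative numeric score.
#' @export
bc_index <- function(m) {
  stopifnot(inherits(m, "molgraph"))
  deg <- mol_degree(m)
  sum(3 * deg) + 3 * sum(m$elem != "C") + 6 * ring_count(m)
}

# Atom contributions for the SMCM-style index: Allred-Rochow
# electronegativity relative to carbon.
.smcm_atom_values <- c(
  B = 0.81, C = 1.00, N = 1.23, O = 1.40, F = 1.64, Si = 0.70,
  P = 0.82, S = 0.98, Cl = 1.13, Br = 1.10, I = 0.88, H = 0.88
)

#' SMCM-style synthetic molecular complexity metric
#'
#' Sum of electronegativity-scaled atom contributions, bond contributions
#' (bond order times the geometric mean of the two atom values), a ring
#' term (2 per ring) and a chirality term (1 per potential stereocenter).
#' The contribution table is this package's parametrization of the
#' atom/bond/ring/chirality structure of synthetic-complexity metrics; see
#' the methods vignette.
#'
#' @param m a `molgraph`.
#' @returns Non-negative numeric score.
#' @export
smcm_index <- function(m) {
  stopifnot(inherits(m, "molgraph"))
  av <- .smcm_atom_values[m$elem]
  atom_term <- sum(av)
  bond_term <- if (nrow(m$bonds)) {
    sum(m$bonds$order * sqrt(av[m$bonds$i] * av[m$bonds$j]))
  } else 0
  atom_term + bond_term + 2 * ring_count(m) + count_stereocenters(m)
}

#' All four complexity indices at once
#'
#' Equivalent to calling the four scalar index functions, but shares the
#' ring-count and stereocenter computations (the morphing loop's hot path).
#'
#' @param m a `molgraph`.
#' @returns Named numeric vector `c(bertz, whitlock, bc, smcm)`.
#' @examples
#' complexity_vector(parse_smiles("CC(=O)Oc1ccccc1C(=O)O"))
#' @export
complexity_vector <- function(m) {
  stopifnot(inherits(m, "molgraph"))
  rings <- ring_count(m)
  stereo <- count_stereocenters(m)
  deg <- mol_degree(m)
  unsat <- if (nrow(m$bonds)) sum(m$bonds$order - 1L) else 0L
  het <- sum(m$elem != "C")
  av <- .smcm_atom_values[m$elem]
  bond_term <- if (nrow(m$bonds)) {
    sum(m$bonds$order * sqrt(av[m$bonds$i] * av[m$bonds$j]))
  } else 0
  c(bertz = bertz_index(m),
    whitlock = 4 * rings + 2 * unsat + 1 * het + 2 * stereo,
    bc = sum(3 * deg) + 3 * het + 6 * rings,
    smcm = sum(av) + bond_term + 2 * rings + stereo)
}

.complexity_indices <- c("bertz", "whitlock", "bc", "smcm")

#' Complexity table for a set of molecules
#'
#' Computes the four indices and the molecular weight for each molecule;
#' the tabular form behind the `complexity` CLI subcommand.
#'
#' @param mols list of `molgraph` objects (or character SMILES vector).
#' @returns data.frame with columns `smiles`, `bertz`, `whitlock`, `bc`,
#'   `smcm`, `mw`.
#' @export
complexity_table <- function(mols) {
  if (is.character(mols)) mols <- parse_smiles_batch(mols)
  cv <- t(vapply(mols, complexity_vector, numeric(4)))
  data.frame(
    smiles = vapply(mols, canonical_smiles, character(1)),
    bertz = cv[, "bertz"], whitlock = cv[, "whitlock"],
    bc = cv[, "bc"], smcm = cv[, "smcm"],
    mw = vapply(mols, mol_weight, numeric(1)),
    row.names = NULL
  )
}
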