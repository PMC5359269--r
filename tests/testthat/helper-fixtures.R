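# Shared fixtures, memoized per test run so the synthetic library and its
# calibration are built once.

.fx_env <- new.env(parent = emptyenv())

fx_library <- function(n = 440L, seed = 101L) {
  key <- paste0("lib_", n, "_", seed)
  if (is.null(.fx_env[[key]]))
    .fx_env[[key]] <- fixture_library(n, seed = seed)
  .fx_env[[key]]
}

fx_thresholds <- function(n = 440L, seed = 101L) {
  key <- paste0("thr_", n, "_", seed)
  if (is.null(.fx_env[[key]]))
    .fx_env[[key]] <- calibrate_thresholds(fx_library(n, seed),
                                           id = "test-fixture")
  .fx_env[[key]]
}

# Renumber the atoms of a molgraph: perm[k] is the old index placed at new
# position k.
permute_mol <- function(m, perm) {
  b <- m$bonds
  molgraph(m$elem[perm],
           if (nrow(b)) data.frame(i = match(b$i, perm),
                                   j = match(b$j, perm),
                                   order = b$order) else NULL,
           m$charge[perm])
}

# Brute-force labeled-graph isomorphism (element+charge vertex colors,
# bond-order edge colors) -- the independent identity oracle.
mols_isomorphic <- function(m1, m2) {
  if (length(m1$elem) != length(m2$elem) ||
      nrow(m1$bonds) != nrow(m2$bonds)) return(FALSE)
  all_lab <- unique(c(paste(m1$elem, m1$charge), paste(m2$elem, m2$charge)))
  g1 <- mol_igraph_t(m1)
  g2 <- mol_igraph_t(m2)
  igraph::isomorphic(
    g1, g2, method = "vf2",
    vertex.color1 = match(paste(m1$elem, m1$charge), all_lab),
    vertex.color2 = match(paste(m2$elem, m2$charge), all_lab),
    edge.color1 = m1$bonds$order,
    edge.color2 = m2$bonds$order
  )
}

mol_igraph_t <- function(m) {
  igraph::graph_from_data_frame(
    d = if (nrow(m$bonds)) m$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_along(m$elem))
  )
}

# A threshold table with every threshold set to one constant (degenerate
# tables drive the unreachable/always-hit morphing contracts).
constant_table <- function(value) {
  tab <- fx_thresholds()
  tab$values[] <- value
  tab
}

# Single-edit checker: reconstructs, from the structural delta between
# parent and child, the unique candidate operations that could explain it,
# and verifies that one enumerated applicable operation reproduces the
# child exactly. Returns TRUE iff the child is one elementary edit away.
is_single_edit <- function(parent, child) {
  op <- cmorph:::.morph_op
  np <- length(parent$elem); nc <- length(child$elem)
  bp <- nrow(parent$bonds); bc <- nrow(child$bonds)
  target <- cmorph:::mol_signature(child)
  try_op <- function(o) {
    r <- tryCatch(apply_operation(parent, o), error = function(e) NULL)
    !is.null(r) && cmorph:::mol_signature(r) == target
  }
  if (nc == np + 1L && bc == bp + 1L) {
    # atom addition: the new atom is last and singly bonded
    nb <- child$bonds[child$bonds$i == nc | child$bonds$j == nc, ,
                      drop = FALSE]
    if (nrow(nb) != 1L || nb$order != 1L) return(FALSE)
    a <- setdiff(c(nb$i, nb$j), nc)
    return(try_op(op("ADD_ATOM", atom = a, elem = child$elem[nc])))
  }
  if (nc == np - 1L) {
    for (a in seq_len(np))
      if (try_op(op("REMOVE_ATOM", atom = a))) return(TRUE)
    return(FALSE)
  }
  if (nc == np && bc == bp + 1L) {
    key_p <- paste(pmin(parent$bonds$i, parent$bonds$j),
                   pmax(parent$bonds$i, parent$bonds$j))
    key_c <- paste(pmin(child$bonds$i, child$bonds$j),
                   pmax(child$bonds$i, child$bonds$j))
    new <- child$bonds[!(key_c %in% key_p), , drop = FALSE]
    if (nrow(new) != 1L || new$order != 1L) return(FALSE)
    return(try_op(op("ADD_BOND", i = new$i, j = new$j)))
  }
  if (nc == np && bc == bp - 1L) {
    key_p <- paste(pmin(parent$bonds$i, parent$bonds$j),
                   pmax(parent$bonds$i, parent$bonds$j))
    key_c <- paste(pmin(child$bonds$i, child$bonds$j),
                   pmax(child$bonds$i, child$bonds$j))
    gone <- parent$bonds[!(key_p %in% key_c), , drop = FALSE]
    if (nrow(gone) != 1L) return(FALSE)
    return(try_op(op("REMOVE_BOND", i = gone$i, j = gone$j)))
  }
  if (nc == np && bc == bp) {
    de <- which(parent$elem != child$elem)
    if (length(de) == 1L)
      return(try_op(op("MUTATE_ATOM", atom = de, elem = child$elem[de])))
    if (length(de) > 1L) return(FALSE)
    key_p <- paste(pmin(parent$bonds$i, parent$bonds$j),
                   pmax(parent$bonds$i, parent$bonds$j), parent$bonds$order)
    key_c <- paste(pmin(child$bonds$i, child$bonds$j),
                   pmax(child$bonds$i, child$bonds$j), child$bonds$order)
    ch <- which(!(key_c %in% key_p))
    if (length(ch) != 1L) return(FALSE)
    b <- child$bonds[ch, ]
    return(try_op(op("MUTATE_BOND", i = b$i, j = b$j, order = b$order)))
  }
  FALSE
}
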