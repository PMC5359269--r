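# The morphing engine. A starting structure undergoes random elementary
# edits -- add/remove/mutate an atom or a bond -- and the path is terminated
# the first time the morph's complexity exceeds the calibrated thresholds
# for its MW bin. Every intermediate must be valence-valid and connected;
# operator enumeration guarantees this by construction and sanitization
# re-checks it.

.morph_kinds <- c("ADD_ATOM", "REMOVE_ATOM", "MUTATE_ATOM",
                  "ADD_BOND", "REMOVE_BOND", "MUTATE_BOND")

#' Default element alphabet for atom addition and mutation
#'
#' The standard drug-like organic subset.
#' @returns Character vector of element symbols.
#' @export
default_alphabet <- function() c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

.morph_op <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "morph_op")
}

#' @export
print.morph_op <- function(x, ...) {
  extras <- x[setdiff(names(x), "kind")]
  cat("<", x$kind, ": ",
      paste(names(extras), unlist(extras), sep = "=", collapse = ", "),
      ">\n", sep = "")
  invisible(x)
}

# Enumerate all applicable instances of one operation kind.
.enumerate_kind <- function(m, kind, alphabet) {
  n <- length(m$elem)
  nb <- nrow(m$bonds)
  nH <- m$nH
  ops <- list()
  switch(kind,
    ADD_ATOM = {
      sites <- which(nH >= 1L)
      for (a in sites) for (e in alphabet)
        ops[[length(ops) + 1L]] <- .morph_op("ADD_ATOM", atom = a, elem = e)
    },
    REMOVE_ATOM = {
      if (n > 1L) {
        g <- mol_igraph(m)
        arti <- as.integer(names(igraph::articulation_points(g)))
        for (a in setdiff(seq_len(n), arti))
          ops[[length(ops) + 1L]] <- .morph_op("REMOVE_ATOM", atom = a)
      }
    },
    MUTATE_ATOM = {
      bs <- bond_order_sum(m)
      for (a in which(m$charge == 0L)) {
        for (e in setdiff(alphabet, m$elem[a])) {
          if (any(.base_valences[[e]] >= bs[a]))
            ops[[length(ops) + 1L]] <- .morph_op("MUTATE_ATOM", atom = a,
                                                 elem = e)
        }
      }
    },
    ADD_BOND = {
      free <- which(nH >= 1L)
      if (length(free) >= 2L) {
        bonded <- character()
        if (nb) bonded <- paste(pmin(m$bonds$i, m$bonds$j),
                                pmax(m$bonds$i, m$bonds$j))
        for (ii in seq_len(length(free) - 1L)) {
          for (jj in (ii + 1L):length(free)) {
            i <- free[ii]; j <- free[jj]
            if (!(paste(i, j) %in% bonded))
              ops[[length(ops) + 1L]] <- .morph_op("ADD_BOND", i = i, j = j)
          }
        }
      }
    },
    REMOVE_BOND = {
      if (nb) {
        g <- mol_igraph(m)
        br <- igraph::bridges(g)
        ringbonds <- setdiff(seq_len(nb), as.integer(br))
        for (r in ringbonds)
          ops[[length(ops) + 1L]] <- .morph_op("REMOVE_BOND",
                                               i = m$bonds$i[r],
                                               j = m$bonds$j[r])
      }
    },
    MUTATE_BOND = {
      if (nb) {
        for (r in seq_len(nb)) {
          o <- m$bonds$order[r]
          i <- m$bonds$i[r]; j <- m$bonds$j[r]
          for (o2 in setdiff(1:3, o)) {
            d <- o2 - o
            if (d < 0L || (nH[i] >= d && nH[j] >= d))
              ops[[length(ops) + 1L]] <- .morph_op("MUTATE_BOND", i = i,
                                                   j = j, order = o2)
          }
        }
      }
    },
    stop("unknown operation kind: ", kind)
  )
  ops
}

#' Enumerate all applicable morph operations
#'
#' Every elementary edit whose application yields a valence-valid,
#' connected, single-component molecule: atom addition (a new alphabet atom
#' single-bonded to an atom with free valence), atom removal (non-cut
#' vertices only), element mutation (valence-feasible swaps), bond addition
#' (single bond between unbonded atoms with free valence -- creates a ring),
#' bond removal (ring bonds only) and bond-order mutation within available
#' valence.
#'
#' @param m a connected `molgraph`.
#' @param alphabet element symbols for atom addition/mutation.
#' @returns List of `morph_op` objects (possibly empty).
#' @export
applicable_operations <- function(m, alphabet = default_alphabet()) {
  stopifnot(inherits(m, "molgraph"))
  unlist(lapply(.morph_kinds, function(k) .enumerate_kind(m, k, alphabet)),
         recursive = FALSE)
}

#' Apply one morph operation
#'
#' Returns a new sanitized molecule differing from the input by exactly the
#' given operation; the input is unchanged. Inapplicable operations raise
#' an error rather than silently returning the input.
#'
#' @param m a `molgraph`.
#' @param op a `morph_op` (as enumerated by [applicable_operations()]).
#' @returns A new `molgraph`.
#' @export
apply_operation <- function(m, op) {
  stopifnot(inherits(m, "molgraph"), inherits(op, "morph_op"))
  n <- length(m$elem)
  out <- switch(op$kind,
    ADD_ATOM = {
      if (op$atom < 1L || op$atom > n || m$nH[op$atom] < 1L)
        stop("ADD_ATOM: no free valence at atom ", op$atom)
      b <- rbind(m$bonds,
                 data.frame(i = op$atom, j = n + 1L, order = 1L))
      molgraph(c(m$elem, op$elem), b, c(m$charge, 0L))
    },
    REMOVE_ATOM = {
      if (n == 1L) stop("REMOVE_ATOM: cannot empty the molecule")
      if (op$atom < 1L || op$atom > n)
        stop("REMOVE_ATOM: atom index out of range")
      res <- subset_atoms(m, setdiff(seq_len(n), op$atom))
      if (!is_connected_mol(res))
        stop("REMOVE_ATOM: atom ", op$atom, " is a cut vertex")
      res
    },
    MUTATE_ATOM = {
      elem <- m$elem
      elem[op$atom] <- op$elem
      molgraph(elem, m$bonds, m$charge)
    },
    ADD_BOND = {
      key <- paste(pmin(m$bonds$i, m$bonds$j), pmax(m$bonds$i, m$bonds$j))
      if (paste(min(op$i, op$j), max(op$i, op$j)) %in% key)
        stop("ADD_BOND: atoms already bonded")
      b <- rbind(m$bonds, data.frame(i = op$i, j = op$j, order = 1L))
      molgraph(m$elem, b, m$charge)
    },
    REMOVE_BOND = {
      r <- which((m$bonds$i == op$i & m$bonds$j == op$j) |
                   (m$bonds$i == op$j & m$bonds$j == op$i))
      if (!length(r)) stop("REMOVE_BOND: no such bond")
      res <- molgraph(m$elem, m$bonds[-r, , drop = FALSE], m$charge)
      if (!is_connected_mol(res))
        stop("REMOVE_BOND: bond is acyclic; removal would disconnect")
      res
    },
    MUTATE_BOND = {
      r <- which((m$bonds$i == op$i & m$bonds$j == op$j) |
                   (m$bonds$i == op$j & m$bonds$j == op$i))
      if (!length(r)) stop("MUTATE_BOND: no such bond")
      b <- m$bonds
      if (b$order[r] == op$order) stop("MUTATE_BOND: order unchanged")
      b$order[r] <- op$order
      molgraph(m$elem, b, m$charge)
    },
    stop("unknown operation kind: ", op$kind)
  )
  out
}

# Constant-time availability test per operation kind; must agree exactly
# with .enumerate_kind() producing at least one instance.
.kind_available <- function(m, kind, alphabet) {
  n <- length(m$elem)
  nb <- nrow(m$bonds)
  switch(kind,
    ADD_ATOM = length(alphabet) > 0L && any(m$nH >= 1L),
    # every connected graph with >= 2 vertices has >= 2 non-cut vertices
    REMOVE_ATOM = n > 1L,
    MUTATE_ATOM = {
      cand <- which(m$charge == 0L)
      if (!length(cand) || !length(alphabet)) FALSE else {
        maxv <- vapply(alphabet, function(e) max(.base_valences[[e]]),
                       numeric(1))
        bs <- bond_order_sum(m)
        any(vapply(cand, function(a)
          any(alphabet != m$elem[a] & maxv >= bs[a]), logical(1)))
      }
    },
    ADD_BOND = {
      free <- which(m$nH >= 1L)
      if (length(free) < 2L) FALSE else {
        b <- m$bonds
        both_free <- if (nb) sum(b$i %in% free & b$j %in% free) else 0L
        choose(length(free), 2L) > both_free
      }
    },
    # a removable (ring) bond exists iff the graph has a cycle
    REMOVE_BOND = nb - n + 1L > 0L,
    MUTATE_BOND = {
      if (!nb) FALSE else
        any(m$bonds$order > 1L |
              (m$nH[m$bonds$i] >= 1L & m$nH[m$bonds$j] >= 1L))
    }
  )
}

#' One random morph step
#'
#' Two-stage uniform sampling: first uniformly over the operation kinds
#' with at least one applicable instance, then uniformly over the
#' instances of the chosen kind. Reproducible under `set.seed()`.
#'
#' @param m a `molgraph`.
#' @param alphabet element alphabet.
#' @param max_retries sanitization retries before giving up (edits are
#'   valence-safe by construction, so retries are rarely consumed).
#' @returns List `(op, mol)`, or NULL when no operation applies (dead end).
#' @export
random_morph_step <- function(m, alphabet = default_alphabet(),
                              max_retries = 50L) {
  avail <- .morph_kinds[vapply(.morph_kinds, .kind_available,
                               logical(1), m = m, alphabet = alphabet)]
  if (!length(avail)) return(NULL)
  inst_cache <- list()
  for (try in seq_len(max_retries)) {
    kind <- avail[sample.int(length(avail), 1L)]
    if (is.null(inst_cache[[kind]]))
      inst_cache[[kind]] <- .enumerate_kind(m, kind, alphabet)
    inst <- inst_cache[[kind]]
    if (!length(inst)) next  # unreachable if availability is exact
    op <- inst[[sample.int(length(inst), 1L)]]
    res <- tryCatch(apply_operation(m, op), error = function(e) NULL)
    if (!is.null(res)) return(list(op = op, mol = res))
  }
  NULL
}

#' Morph a structure until it crosses the complexity threshold
#'
#' Iterates [random_morph_step()] from a starting structure; after each
#' step the four complexity indices and the MW are computed, and the path
#' stops at the first morph for which [exceeds()] is true (status `HIT`).
#' Paths that survive `max_steps` steps produce no hard example (status
#' `EXHAUSTED`); paths with no applicable operation end as `DEAD_END`. A
#' starting structure that already exceeds the thresholds is a `HIT` at
#' step 0 (with a warning).
#'
#' @param start a `molgraph`.
#' @param table a calibrated [calibrate_thresholds()] table.
#' @param cond a [stop_condition()].
#' @param max_steps morphing step cap (default 30).
#' @param alphabet element alphabet.
#' @param seed optional integer seed for this path.
#' @returns A `morph_path`: list with `start`, `steps` (each step holds
#'   `op`, `mol`, `cv`, `mw`), `terminal_status` and `seed`.
#' @export
morph_until_complex <- function(start, table, cond = stop_condition(),
                                max_steps = 30L,
                                alphabet = default_alphabet(),
                                seed = NULL) {
  stopifnot(inherits(start, "molgraph"))
  if (!is_connected_mol(start))
    stop("starting structure must be a single connected component")
  if (!is.null(seed)) set.seed(seed)
  path <- structure(
    list(start = start, steps = list(), terminal_status = NA_character_,
         seed = seed),
    class = "morph_path"
  )
  hit0 <- tryCatch(
    exceeds(complexity_vector(start), mol_weight(start), table, cond),
    error = function(e) {
      warning("path aborted: ", conditionMessage(e))
      NA
    })
  if (is.na(hit0)) {
    path$terminal_status <- "DEAD_END"
    return(path)
  }
  if (isTRUE(hit0)) {
    warning("starting structure already exceeds thresholds (HIT at step 0)")
    path$terminal_status <- "HIT"
    return(path)
  }
  m <- start
  for (step in seq_len(max_steps)) {
    nxt <- random_morph_step(m, alphabet)
    if (is.null(nxt)) {
      path$terminal_status <- "DEAD_END"
      return(path)
    }
    m <- nxt$mol
    cv <- complexity_vector(m)
    mw <- mol_weight(m)
    hit <- tryCatch(exceeds(cv, mw, table, cond), error = function(e) {
      warning("path aborted at step ", step, ": ", conditionMessage(e))
      NA
    })
    path$steps[[step]] <- list(op = nxt$op, mol = m, cv = cv, mw = mw)
    if (is.na(hit)) {
      path$terminal_status <- "DEAD_END"
      return(path)
    }
    if (hit) {
      path$terminal_status <- "HIT"
      return(path)
    }
  }
  path$terminal_status <- "EXHAUSTED"
  path
}

#' @export
print.morph_path <- function(x, ...) {
  cat(sprintf("<morph_path: %d step(s), status %s>\n", length(x$steps),
              x$terminal_status))
  invisible(x)
}

#' Generate a hard-to-synthesize library by morphing
#'
#' Runs one morphing path per starting structure and collects the terminal
#' `HIT` morphs, deduplicated by canonical SMILES. Easy-class counterparts
#' are assembled separately (see [build_nonpher_sets()]).
#'
#' @param starts list of `molgraph` starting structures (or SMILES vector).
#' @param table calibrated `threshold_table`.
#' @param cond a [stop_condition()].
#' @param max_steps morphing step cap per path (default 30).
#' @param alphabet element alphabet.
#' @param seed integer seed; child seeds are derived per path.
#' @returns A `morph_library`: list with `hard` (data.frame of canonical
#'   `smiles`, originating `start`, `steps`) and `paths` (per-start
#'   `status` + `steps` bookkeeping).
#' @export
generate_library <- function(starts, table, cond = stop_condition(),
                             max_steps = 30L,
                             alphabet = default_alphabet(), seed = 1L) {
  if (is.character(starts)) starts <- parse_smiles_batch(starts)
  if (!length(starts)) stop("empty starting set")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, length(starts))
  nm <- names(starts)
  if (is.null(nm)) nm <- as.character(seq_along(starts))
  status <- character(length(starts))
  nsteps <- integer(length(starts))
  hits <- list()
  hit_start <- character()
  for (k in seq_along(starts)) {
    p <- suppressWarnings(
      morph_until_complex(starts[[k]], table, cond, max_steps, alphabet,
                          seed = child[k]))
    status[k] <- p$terminal_status
    nsteps[k] <- length(p$steps)
    if (p$terminal_status == "HIT") {
      term <- if (length(p$steps)) p$steps[[length(p$steps)]]$mol else p$start
      hits[[length(hits) + 1L]] <- term
      hit_start <- c(hit_start, nm[k])
    }
  }
  hard <- data.frame(smiles = character(), start = character(),
                     steps = integer())
  if (length(hits)) {
    smi <- canonical_smiles_batch(hits)
    keep <- !duplicated(smi)
    hard <- data.frame(smiles = smi[keep], start = hit_start[keep],
                       steps = nsteps[match(hit_start[keep], nm)],
                       row.names = NULL)
  }
  structure(
    list(hard = hard,
         paths = data.frame(start = nm, status = status, steps = nsteps,
                            row.names = NULL),
         cond = cond, max_steps = max_steps, seed = seed),
    class = "morph_library"
  )
}

#' @export
print.morph_library <- function(x, ...) {
  cat(sprintf(
    "<morph_library: %d hard structures from %d paths (%d HIT / %d EXHAUSTED / %d DEAD_END)>\n",
    nrow(x$hard), nrow(x$paths), sum(x$paths$status == "HIT"),
    sum(x$paths$status == "EXHAUSTED"), sum(x$paths$status == "DEAD_END")))
  invisible(x)
}
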