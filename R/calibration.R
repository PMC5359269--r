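# Molecular-weight-binned complexity thresholds. A reference library of
# synthetically accessible molecules is binned by MW (eleven 50-Da bins by
# default, values above the last edge clamped into it) and, per bin and per
# index, three threshold levels are extracted: the observed maximum, the
# 999th permille and the 99th percentile (nearest-rank). A structure whose
# complexity exceeds its bin's thresholds for at least k indices is flagged
# hard-to-synthesize.

.threshold_levels <- c("max", "p999", "p99")

#' Molecular-weight bin index
#'
#' Half-open 50-Da intervals `[i*w, (i+1)*w)`, 0-based; weights at or above
#' the last edge clamp into the last bin.
#'
#' @param mw molecular weight(s), Da; must be non-negative.
#' @param table a `threshold_table` (supplies bin width and count), or NULL
#'   to use `bin_width`/`n_bins`.
#' @param bin_width,n_bins bin geometry used when `table` is NULL.
#' @returns Integer bin index (0-based), vectorized over `mw`.
#' @export
mw_bin <- function(mw, table = NULL, bin_width = 50, n_bins = 11L) {
  if (!is.null(table)) {
    bin_width <- table$bin_width
    n_bins <- table$n_bins
  }
  if (any(mw < 0)) stop("molecular weight must be non-negative")
  pmin(as.integer(floor(mw / bin_width)), n_bins - 1L)
}

# Nearest-rank percentile: value at rank ceil(q * n) of the sorted sample.
.nearest_rank <- function(x, q) {
  x <- sort(x)
  x[max(1L, ceiling(q * length(x)))]
}

#' Calibrate per-bin complexity thresholds from a reference library
#'
#' Computes the four complexity indices and MW for every library molecule,
#' bins by MW, and records per (bin, index) the maximum, the 999th permille
#' and the 99th percentile (nearest-rank, no interpolation). Bins with no
#' molecules are flagged unavailable; morphs landing there are rejected.
#'
#' @param library list of `molgraph` objects, or character SMILES vector.
#' @param bin_width bin width in Da (default 50).
#' @param n_bins number of bins (default 11).
#' @param id provenance label stored with the table.
#' @returns A `threshold_table`: list with `bin_width`, `n_bins`, a
#'   `n_bins x 4 x 3` threshold array `values`, per-bin counts, and
#'   provenance.
#' @export
calibrate_thresholds <- function(library, bin_width = 50, n_bins = 11L,
                                 id = "reference") {
  if (is.character(library)) library <- parse_smiles_batch(library)
  if (!length(library)) stop("empty calibration library")
  cv <- t(vapply(library, complexity_vector, numeric(4)))
  mw <- vapply(library, mol_weight, numeric(1))
  calibrate_from_values(cv, mw, bin_width, n_bins, id)
}

#' Calibrate thresholds from precomputed complexity values
#'
#' Value-level entry point behind [calibrate_thresholds()]: takes the four
#' index values and the MW per molecule instead of the molecules, so
#' threshold extraction can also be driven from a precomputed complexity
#' table.
#'
#' @param cv numeric matrix with one row per molecule and columns
#'   `bertz`, `whitlock`, `bc`, `smcm`.
#' @param mw numeric vector of molecular weights (Da).
#' @inheritParams calibrate_thresholds
#' @returns A `threshold_table`.
#' @export
calibrate_from_values <- function(cv, mw, bin_width = 50, n_bins = 11L,
                                  id = "reference") {
  cv <- as.matrix(cv)
  if (is.null(colnames(cv))) colnames(cv) <- .complexity_indices
  stopifnot(nrow(cv) == length(mw),
            all(.complexity_indices %in% colnames(cv)))
  cv <- cv[, .complexity_indices, drop = FALSE]
  bins <- mw_bin(mw, bin_width = bin_width, n_bins = n_bins)
  values <- array(
    NA_real_, dim = c(n_bins, 4L, 3L),
    dimnames = list(bin = as.character(0:(n_bins - 1L)),
                    index = .complexity_indices,
                    level = .threshold_levels)
  )
  counts <- integer(n_bins)
  for (b in 0:(n_bins - 1L)) {
    rows <- which(bins == b)
    counts[b + 1L] <- length(rows)
    if (!length(rows)) next
    for (ix in seq_len(4L)) {
      x <- cv[rows, ix]
      values[b + 1L, ix, "max"] <- max(x)
      values[b + 1L, ix, "p999"] <- .nearest_rank(x, 0.999)
      values[b + 1L, ix, "p99"] <- .nearest_rank(x, 0.99)
    }
  }
  if (all(counts == 0L)) stop("no library molecule fell into any bin")
  structure(
    list(bin_width = bin_width, n_bins = as.integer(n_bins),
         values = values, counts = counts,
         provenance = list(id = id, size = nrow(cv),
                           date = format(Sys.Date()))),
    class = "threshold_table"
  )
}

#' @export
print.threshold_table <- function(x, ...) {
  cat(sprintf(
    "<threshold_table: %d bins x %.0f Da, library '%s' (n=%d), %d empty bin(s)>\n",
    x$n_bins, x$bin_width, x$provenance$id, x$provenance$size,
    sum(x$counts == 0L)))
  invisible(x)
}

#' Morphing stop condition
#'
#' The rule terminating a morphing path: a morph stops when at least
#' `k_indices` of the four complexity indices strictly exceed their
#' (MW bin, index) threshold at the chosen level. The default --
#' 999th permille, at least one index -- is the best-performing criterion
#' of the stop-condition grid experiment.
#'
#' @param level one of `"max"`, `"p999"`, `"p99"`.
#' @param k_indices integer 1..4.
#' @returns A `stop_condition` object.
#' @export
stop_condition <- function(level = "p999", k_indices = 1L) {
  level <- match.arg(level, .threshold_levels)
  k_indices <- as.integer(k_indices)
  if (k_indices < 1L || k_indices > 4L) stop("k_indices must be 1..4")
  structure(list(level = level, k_indices = k_indices),
            class = "stop_condition")
}

#' Does a complexity vector exceed its bin thresholds?
#'
#' TRUE when at least `cond$k_indices` of the four index values are
#' strictly greater than the (bin, index) threshold at `cond$level`.
#'
#' @param cv named complexity vector (as from [complexity_vector()]).
#' @param mw molecular weight of the same structure.
#' @param table a `threshold_table`.
#' @param cond a [stop_condition()].
#' @returns Logical scalar.
#' @export
exceeds <- function(cv, mw, table, cond = stop_condition()) {
  stopifnot(inherits(table, "threshold_table"),
            inherits(cond, "stop_condition"))
  b <- mw_bin(mw, table)
  thr <- table$values[b + 1L, , cond$level]
  if (anyNA(thr))
    stop("bin ", b, " is uncalibrated (no reference molecules)")
  sum(cv[.complexity_indices] > thr) >= cond$k_indices
}

#' Serialize a threshold table to CSV (+ JSON provenance sidecar)
#'
#' @param table a `threshold_table`.
#' @param path CSV output path; provenance goes to `<path>.json`.
#' @returns `path`, invisibly.
#' @export
write_threshold_table <- function(table, path) {
  stopifnot(inherits(table, "threshold_table"))
  long <- expand.grid(bin = 0:(table$n_bins - 1L),
                      index = .complexity_indices,
                      level = .threshold_levels,
                      stringsAsFactors = FALSE)
  long$value <- as.vector(table$values)
  utils::write.csv(long, path, row.names = FALSE)
  meta <- c(table$provenance,
            list(bin_width = table$bin_width, n_bins = table$n_bins,
                 counts = table$counts))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a threshold table written by [write_threshold_table()]
#'
#' @param path CSV path.
#' @returns A `threshold_table`.
#' @export
read_threshold_table <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list(bin_width = 50, n_bins = max(long$bin) + 1L, id = "unknown",
         size = NA_integer_, date = NA_character_, counts = NULL)
  n_bins <- as.integer(meta$n_bins)
  values <- array(
    NA_real_, dim = c(n_bins, 4L, 3L),
    dimnames = list(bin = as.character(0:(n_bins - 1L)),
                    index = .complexity_indices,
                    level = .threshold_levels)
  )
  values[cbind(long$bin + 1L, match(long$index, .complexity_indices),
               match(long$level, .threshold_levels))] <- long$value
  counts <- if (!is.null(meta$counts)) as.integer(unlist(meta$counts)) else
    rep(NA_integer_, n_bins)
  structure(
    list(bin_width = as.numeric(meta$bin_width), n_bins = n_bins,
         values = values, counts = counts,
         provenance = list(id = meta$id, size = meta$size, date = meta$date)),
    class = "threshold_table"
  )
}
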