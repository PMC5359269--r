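# End-to-end workflow wiring: one config object, deterministic per-stage
# seed fan-out, and a bundle of artifacts (thresholds, hard/easy sets,
# path log, evaluation report) stamped with a config hash.

#' Pipeline configuration
#'
#' Collects every tunable of the calibrate / morph / build-sets / evaluate
#' workflow with the method's defaults: 50-Da bins x 11, 30 morph steps,
#' 999th-permille / k=1 stop condition, 100 trees, 5 easy-class samples.
#'
#' @param seed global integer seed; per-stage child seeds derive from it.
#' @param bin_width,n_bins calibration bin geometry.
#' @param max_steps morph step cap.
#' @param level,k_indices stop condition.
#' @param alphabet morphing element alphabet.
#' @param n_trees forest size.
#' @param k_samples easy-class samples for averaging.
#' @param n_fixture fixture-library size when no library file is given.
#' @returns A `run_config` list.
#' @export
run_config <- function(seed = 1L, bin_width = 50, n_bins = 11L,
                       max_steps = 30L, level = "p999", k_indices = 1L,
                       alphabet = default_alphabet(), n_trees = 100L,
                       k_samples = 5L, n_fixture = 1100L) {
  stopifnot(bin_width > 0, n_bins > 0, max_steps > 0, n_trees > 0,
            k_samples > 0, n_fixture > 0)
  cond <- stop_condition(level, k_indices)  # validates level/k
  structure(list(seed = as.integer(seed), bin_width = bin_width,
                 n_bins = as.integer(n_bins),
                 max_steps = as.integer(max_steps),
                 level = cond$level, k_indices = cond$k_indices,
                 alphabet = alphabet, n_trees = as.integer(n_trees),
                 k_samples = as.integer(k_samples),
                 n_fixture = as.integer(n_fixture)),
            class = "run_config")
}

# Deterministic child seeds from the global seed, one per pipeline stage.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Rolling polynomial hash of the serialized config: stamps every artifact
# of a run (a fingerprint for provenance, not a cryptographic digest).
config_hash <- function(cfg) {
  js <- as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))
  h <- 17
  for (b in utf8ToInt(js)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full morphing pipeline
#'
#' Calibrates thresholds on a library, morphs starting structures into
#' hard examples, builds the paired easy/hard training set, trains and
#' evaluates the fingerprint random forest, and writes the artifact bundle
#' (`thresholds.csv`, `hard.smi`, `easy.smi`, `paths.csv`, `report.json`,
#' `config.json`) into `out_dir`. Without an input library the built-in
#' fixture generator supplies both the calibration library and the
#' starting structures.
#'
#' @param cfg a [run_config()].
#' @param library optional SMILES vector (calibration + starts); defaults
#'   to `fixture_library(cfg$n_fixture, ...)`.
#' @param out_dir output directory (created if needed); NULL to skip
#'   writing files.
#' @returns List with `thresholds`, `sets`, `evaluation`, `paths`,
#'   `config`, `hash` (invisibly when writing files).
#' @export
run_pipeline <- function(cfg = run_config(), library = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- derive_seeds(cfg$seed, 4L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  mols <- stage("library", {
    if (is.null(library))
      fixture_library(cfg$n_fixture, seed = seeds[1],
                      bin_width = cfg$bin_width, n_bins = cfg$n_bins)
    else parse_smiles_batch(library)
  })
  table <- stage("calibrate",
                 calibrate_thresholds(mols, cfg$bin_width, cfg$n_bins,
                                      id = if (is.null(library))
                                        "fixture" else "user-library"))
  cond <- stop_condition(cfg$level, cfg$k_indices)
  built <- stage("morph", suppressWarnings(
    build_nonpher_sets(mols, table, cond, easy_from = "starts",
                       max_steps = cfg$max_steps, seed = seeds[2])))
  set <- built$set
  evaluation <- stage("evaluate", {
    hard <- set$smiles[set$label == "hard"]
    easy_pool <- set$smiles[set$label == "easy"]
    if (length(hard) < 2L) stop("too few hard examples to evaluate")
    test <- labeled_set(c(easy_pool, hard),
                        c(rep("easy", length(easy_pool)),
                          rep("hard", length(hard))),
                        role = "test", canonicalize = FALSE)
    repeat_eval(hard, easy_pool, test, k = cfg$k_samples,
                n_trees = cfg$n_trees, seed = seeds[3])
  })
  hash <- config_hash(cfg)
  out <- list(thresholds = table, sets = set, evaluation = evaluation,
              paths = built$library$paths, config = cfg, hash = hash)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_threshold_table(table, file.path(out_dir, "thresholds.csv"))
    write_smi(set[set$label == "hard", ], file.path(out_dir, "hard.smi"))
    write_smi(set[set$label == "easy", ], file.path(out_dir, "easy.smi"))
    utils::write.csv(built$library$paths, file.path(out_dir, "paths.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(hash = hash, seed = cfg$seed,
           mean = as.list(evaluation$mean),
           per_sample = lapply(evaluation$samples, function(r)
             c(as.list(r$confusion),
               list(acc = r$acc, sn = r$sn, sp = r$sp, auc = r$auc)))),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(c(unclass(cfg), list(hash = hash)),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE)
    return(invisible(out))
  }
  out
}
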