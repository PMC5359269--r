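# Random-forest benchmarking of easy/hard training libraries:
# 512-bit radius-2 circular fingerprints, 100 trees, confusion-matrix
# metrics (positive class = easy), ROC/AUC, five-sample averaging and the
# twelve-configuration stop-condition grid.

.fp_features <- function(smiles, nbits = 512L) {
  fp <- morgan_fp_matrix(smiles, nbits)
  colnames(fp) <- paste0("b", seq_len(ncol(fp)))
  fp
}

#' Train a fingerprint random-forest classifier
#'
#' Fits an ensemble of `n_trees` decision trees (bootstrap samples, random
#' feature subsets) on 512-bit radius-2 circular fingerprints. The
#' positive class is `easy`.
#'
#' @param train a `labeled_set` containing both classes.
#' @param n_trees number of trees (default 100).
#' @param seed integer seed (forest growth is seeded for reproducibility).
#' @param nbits fingerprint length.
#' @returns An `sa_classifier`: list with the fitted forest and a manifest
#'   of the hyperparameters actually used.
#' @export
train_classifier <- function(train, n_trees = 100L, seed = 1L,
                             nbits = 512L) {
  stopifnot(inherits(train, "data.frame"),
            all(c("smiles", "label") %in% names(train)))
  if (length(unique(train$label)) < 2L)
    stop("training set must contain both classes")
  x <- .fp_features(train$smiles, nbits)
  y <- factor(train$label, levels = c("hard", "easy"))
  set.seed(seed)
  fit <- randomForest::randomForest(x, y, ntree = n_trees)
  structure(
    list(forest = fit,
         params = list(n_trees = n_trees, nbits = nbits, radius = 2L,
                       mtry = fit$mtry, seed = seed,
                       n_train = nrow(train),
                       class_sizes = as.list(table(train$label)))),
    class = "sa_classifier"
  )
}

#' @export
print.sa_classifier <- function(x, ...) {
  cat(sprintf("<sa_classifier: %d trees on %d molecules (%d-bit fingerprints)>\n",
              x$params$n_trees, x$params$n_train, x$params$nbits))
  invisible(x)
}

#' Predicted probability of the easy class
#'
#' @param clf an `sa_classifier`.
#' @param smiles character vector of SMILES.
#' @returns Numeric vector of P(easy).
#' @export
predict_proba <- function(clf, smiles) {
  stopifnot(inherits(clf, "sa_classifier"))
  x <- .fp_features(smiles, clf$params$nbits)
  as.numeric(stats::predict(clf$forest, x, type = "prob")[, "easy"])
}

#' Confusion matrix on a labeled test set
#'
#' Counts at the conventional 0.5 probability threshold; predicted easy
#' when P(easy) > 0.5. TP are easy structures predicted easy, TN hard
#' predicted hard.
#'
#' @param clf an `sa_classifier`.
#' @param test a `labeled_set`.
#' @returns Named integer vector `c(TP, TN, FP, FN)` of class
#'   `confusion_matrix`.
#' @export
confusion <- function(clf, test) {
  stopifnot(all(c("smiles", "label") %in% names(test)))
  if (any(!test$label %in% c("easy", "hard")))
    stop("test set contains unlabeled records")
  p <- predict_proba(clf, test$smiles)
  pred <- ifelse(p > 0.5, "easy", "hard")
  confusion_from_labels(test$label, pred)
}

#' Confusion matrix from label vectors
#'
#' @param truth,pred character vectors with values `easy`/`hard`.
#' @returns `confusion_matrix` vector `c(TP, TN, FP, FN)`.
#' @export
confusion_from_labels <- function(truth, pred) {
  structure(c(
    TP = sum(truth == "easy" & pred == "easy"),
    TN = sum(truth == "hard" & pred == "hard"),
    FP = sum(truth == "hard" & pred == "easy"),
    FN = sum(truth == "easy" & pred == "hard")
  ), class = "confusion_matrix")
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' `acc = (TP+TN)/(TP+FN+FP+TN)`, `sn = TP/(TP+FN)`, `sp = TN/(TN+FP)`.
#' A metric whose denominator is zero is reported as NA, not an error.
#'
#' @param cm confusion counts (named vector with TP, TN, FP, FN).
#' @returns Named numeric vector `c(acc, sn, sp)`.
#' @export
metrics <- function(cm) {
  cm <- cm[c("TP", "TN", "FP", "FN")]
  if (anyNA(cm)) stop("confusion matrix must contain TP, TN, FP, FN")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  c(acc = unname((cm["TP"] + cm["TN"]) / total),
    sn = unname(if (cm["TP"] + cm["FN"] > 0) cm["TP"] / (cm["TP"] + cm["FN"])
                else NA_real_),
    sp = unname(if (cm["TN"] + cm["FP"] > 0) cm["TN"] / (cm["TN"] + cm["FP"])
                else NA_real_))
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds; the AUC is the trapezoidal area under the
#' ROC, equal to the Mann-Whitney probability that a random positive
#' scores above a random negative (ties counting one half).
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary truth: 1/TRUE/"easy" = positive.
#' @returns List with `roc` (data.frame `fpr`, `tpr`, from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels)) labels <- labels == "easy"
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    stop("both classes required for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  npos <- sum(y); nneg <- sum(!y)
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)  # one ROC point per threshold
  tpr <- c(0, tp[last] / npos, 1)
  fpr <- c(0, fp[last] / nneg, 1)
  keep <- !duplicated(data.frame(fpr, tpr))
  roc <- data.frame(fpr = fpr[keep], tpr = tpr[keep])
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Full evaluation report of a classifier on a test set
#'
#' @param clf an `sa_classifier`.
#' @param test a `labeled_set`.
#' @returns An `eval_report`: list with `confusion`, `acc`, `sn`, `sp`,
#'   `auc`, `roc` and the classifier manifest.
#' @export
evaluate_classifier <- function(clf, test) {
  p <- predict_proba(clf, test$smiles)
  cm <- confusion_from_labels(test$label, ifelse(p > 0.5, "easy", "hard"))
  met <- metrics(cm)
  ra <- roc_auc(p, test$label)
  structure(
    list(confusion = cm, acc = met[["acc"]], sn = met[["sn"]],
         sp = met[["sp"]], auc = ra$auc, roc = ra$roc,
         params = clf$params),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: Acc %.1f%% | SN %.1f%% | SP %.1f%% | AUC %.3f>\n",
              100 * x$acc, 100 * x$sn, 100 * x$sp, x$auc))
  invisible(x)
}

#' Repeated evaluation over independent easy-class samples
#'
#' Draws `k` independent easy-class samples of the hard-set size from the
#' pool, trains one forest per sample and reports the arithmetic mean of
#' accuracy, sensitivity, specificity and AUC together with the per-sample
#' reports.
#'
#' @param hard character vector of hard-class SMILES.
#' @param easy_pool character vector to sample the easy class from
#'   (must be at least as large as `hard`).
#' @param test a `labeled_set`.
#' @param k number of samples (default 5).
#' @param n_trees trees per forest.
#' @param seed integer seed; per-sample child seeds are derived from it.
#' @returns List with `mean` (named numeric acc/sn/sp/auc) and `samples`
#'   (list of `eval_report`).
#' @export
repeat_eval <- function(hard, easy_pool, test, k = 5L, n_trees = 100L,
                        seed = 1L) {
  if (length(easy_pool) < length(hard))
    stop("easy pool smaller than the hard set")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, k)
  reports <- vector("list", k)
  for (s in seq_len(k)) {
    set.seed(child[s])
    easy <- sort(sample(easy_pool, length(hard)))  # order-stable training set
    train <- labeled_set(c(easy, hard),
                         c(rep("easy", length(easy)),
                           rep("hard", length(hard))),
                         source = "repeat_eval", canonicalize = FALSE)
    # forest growth shares the top-level seed so that identical samples
    # (degenerate pools) give identical models; easy-class draws vary by s
    clf <- train_classifier(train, n_trees, seed = seed)
    reports[[s]] <- evaluate_classifier(clf, test)
  }
  means <- colMeans(do.call(rbind, lapply(reports, function(r)
    c(acc = r$acc, sn = r$sn, sp = r$sp, auc = r$auc))))
  list(mean = means, samples = reports)
}

#' Stop-condition grid experiment
#'
#' Runs the full morph-train-evaluate pipeline for every combination of
#' threshold level (max, 999th permille, 99th percentile) and number of
#' indices required to exceed it (1..4): twelve configurations. Each
#' configuration's training set pairs the threshold-crossing morphs with
#' their own starting structures, so classes are balanced by construction.
#'
#' @param starts starting structures (list of `molgraph` or SMILES).
#' @param table calibrated `threshold_table`.
#' @param test a `labeled_set` for evaluation.
#' @param max_steps morph step cap.
#' @param n_trees trees per forest.
#' @param seed integer seed (shared morph seed per configuration).
#' @returns data.frame with one row per configuration: `level`,
#'   `k_indices`, `n_hard`, `n_easy`, `acc`, `sn`, `sp`, `auc`, and a
#'   logical `best` flagging the argmax-accuracy row.
#' @export
stop_condition_grid <- function(starts, table, test, max_steps = 30L,
                                n_trees = 100L, seed = 1L) {
  if (is.character(starts)) starts <- parse_smiles_batch(starts)
  grid <- expand.grid(level = .threshold_levels, k_indices = 1:4,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cond <- stop_condition(grid$level[g], grid$k_indices[g])
    built <- suppressWarnings(
      build_nonpher_sets(starts, table, cond, easy_from = "starts",
                         max_steps = max_steps, seed = seed))
    set <- built$set
    n_hard <- sum(set$label == "hard")
    n_easy <- sum(set$label == "easy")
    if (n_hard < 2L || n_easy < 2L) {
      rows[[g]] <- data.frame(level = cond$level, k_indices = cond$k_indices,
                              n_hard = n_hard, n_easy = n_easy,
                              acc = NA_real_, sn = NA_real_, sp = NA_real_,
                              auc = NA_real_)
      next
    }
    clf <- train_classifier(set, n_trees, seed = seed)
    rep <- evaluate_classifier(clf, test)
    rows[[g]] <- data.frame(level = cond$level, k_indices = cond$k_indices,
                            n_hard = n_hard, n_easy = n_easy,
                            acc = rep$acc, sn = rep$sn, sp = rep$sp,
                            auc = rep$auc)
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  if (any(!is.na(out$acc)))
    out$best[which.max(out$acc)] <- TRUE
  rownames(out) <- NULL
  out
}
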