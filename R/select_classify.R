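#' Default SVM hyperparameter grid (22 combinations)
#'
#' The grid searched during classification: linear kernel with
#' C in {1, 10, 100, 1000}; polynomial kernel with C = 1 and degree 2 or 3;
#' radial kernel with C in {1, 10, 100, 1000} crossed with
#' gamma in {1, 0.1, 0.01, 0.001}. `gamma = NA` means the library default
#' (1 / n_features).
#'
#' @return Data.frame with columns `kernel`, `cost`, `degree`, `gamma`;
#'   22 rows.
#' @export
default_svm_grid <- function() {
  g <- rbind(
    data.frame(kernel = "linear", cost = c(1, 10, 100, 1000),
               degree = NA_real_, gamma = NA_real_),
    data.frame(kernel = "polynomial", cost = 1, degree = c(2, 3),
               gamma = NA_real_),
    expand.grid(kernel = "radial", cost = c(1, 10, 100, 1000),
                degree = NA_real_, gamma = c(1, 0.1, 0.01, 0.001),
                stringsAsFactors = FALSE)[, c("kernel", "cost", "degree",
                                              "gamma")]
  )
  rownames(g) <- NULL
  g
}

## Stratified fold assignment: within each class, shuffled indices are dealt
## to folds round-robin. Deterministic given seed.
make_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels are constant", call. = FALSE)
  if (min(table(labels)) < k) {
    stop("more folds (", k, ") than minority-class size", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## z-score columns by training-fold statistics; constant columns pass
## through unscaled (sd set to 1).
scale_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}
scale_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$center, "-"), 2, sc$scale, "/")
}

## Linear SVR coefficient vector (the RFE ranking weights).
svr_weights <- function(x, y) {
  fit <- e1071::svm(x, y, type = "eps-regression", kernel = "linear",
                    scale = FALSE)
  as.numeric(crossprod(fit$coefs, fit$SV))
}

#' Rank features by recursive elimination under a linear SVR estimator
#'
#' Implements the recursive feature elimination ranking: starting from all
#' features, repeatedly fit a linear support vector regression on the
#' (z-scored) feature matrix against the 0/1 group labels, delete the
#' feature with the smallest absolute coefficient, and repeat until all
#' features are rated. The elimination order reversed is the ranking (most
#' to least important); the weight recorded for each feature is its absolute
#' coefficient at the round it was eliminated. Ties in coefficient magnitude
#' break by ascending column index. `elim_step` > 1 removes that many
#' lowest-weight features per round, a standard speed/granularity trade-off
#' for very wide matrices (the default removes one per round).
#'
#' @param features Numeric matrix, subjects x features (column names are the
#'   feature ids).
#' @param labels 0/1 group indicator per subject (1 = case).
#' @param cv_folds Fold count carried in the result for downstream
#'   cross-validated sweeps.
#' @param seed Integer seed (standardisation and the SVR are deterministic;
#'   the seed is recorded and used by downstream fold assignment).
#' @param elim_step Features eliminated per round (default 1).
#' @return Object of class `feature_ranking`: `ranking` (feature ids, most
#'   important first), `weights` (aligned |coefficient| at elimination),
#'   `cv_folds`, `seed`.
#' @export
rfe_rank <- function(features, labels, cv_folds = 10L, seed = 1L,
                     elim_step = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels are constant", call. = FALSE)
  if (min(table(labels)) < 2L) stop("need >= 2 subjects per class",
                                    call. = FALSE)
  ids <- colnames(features)
  if (is.null(ids)) ids <- paste0("F", seq_len(ncol(features)))
  sc <- scale_fit(features)
  x <- scale_apply(features, sc)
  y <- as.numeric(labels)
  remaining <- seq_len(ncol(x))
  elim_ids <- character(0)
  elim_w <- numeric(0)
  while (length(remaining) > 1L) {
    w <- abs(svr_weights(x[, remaining, drop = FALSE], y))
    k <- min(elim_step, length(remaining) - 1L)
    drop_local <- order(w, seq_along(w))[seq_len(k)]  # ties: lower index out
    drop_local <- sort(drop_local, decreasing = TRUE)
    ## record least-important-first among the dropped block
    ord <- order(w[drop_local], seq_along(w)[drop_local])
    for (j in drop_local[ord]) {
      elim_ids <- c(elim_ids, ids[remaining[j]])
      elim_w <- c(elim_w, w[j])
    }
    remaining <- remaining[-drop_local]
  }
  w_last <- abs(svr_weights(x[, remaining, drop = FALSE], y))
  elim_ids <- c(elim_ids, ids[remaining])
  elim_w <- c(elim_w, w_last)
  structure(list(ranking = rev(elim_ids), weights = rev(elim_w),
                 cv_folds = cv_folds, seed = seed),
            class = "feature_ranking")
}

#' Classification metrics from a confusion table
#'
#' Accuracy, precision, recall and f1 from true/false positive/negative
#' counts, with cases as the positive class. Undefined ratios (zero
#' denominator) are reported as `NA`, not 0.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return Named numeric `c(acc, precision, recall, f1)`.
#' @export
metrics_from_confusion <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  c(acc = acc, precision = precision, recall = recall, f1 = f1)
}

## Fit one SVM combo on (x, y) and return oriented decision scores for newx
## (higher score = more case-like) plus predicted labels.
svm_fit_predict <- function(x, y, newx, combo) {
  args <- list(x = x, y = factor(y, levels = c(0, 1)),
               type = "C-classification", kernel = combo$kernel,
               cost = combo$cost, scale = FALSE)
  if (!is.na(combo$degree)) args$degree <- combo$degree
  if (!is.na(combo$gamma)) args$gamma <- combo$gamma
  fit <- do.call(e1071::svm, args)
  pr <- stats::predict(fit, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  ## e1071 names the column "A/B" with positive values favouring class A
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  score <- if (identical(first, "1")) dv[, 1] else -dv[, 1]
  list(label = as.integer(as.character(pr)), score = as.numeric(score),
       fit = fit)
}

#' Grid-searched SVM classification with repeated stratified k-fold CV
#'
#' For each repeat the fold assignment is reshuffled (seeded). Within a
#' repeat every hyperparameter combination of the grid is evaluated by
#' k-fold cross-validation; the combination with the best CV accuracy is
#' selected and the reported metrics for that repeat are computed from its
#' held-out predictions (AUC from the continuous decision scores, not
#' thresholded labels). Aggregates are means over repeats.
#'
#' `selector` optionally performs in-training-fold feature selection: a
#' function `(x_train, y_train) -> column indices`, applied inside each
#' fold before standardisation and fitting, so that selection never sees
#' the held-out fold. Without it, classification uses all supplied columns
#' (appropriate when the caller has already selected features on independent
#' data — selecting on the full matrix first and then cross-validating is
#' optimistic; see the package vignette).
#'
#' @param features Numeric matrix, subjects x features.
#' @param labels 0/1 group indicator (1 = case).
#' @param grid Hyperparameter grid (see [default_svm_grid()]).
#' @param cv_folds Folds per repeat (default 10).
#' @param n_repeats Repeats of the whole CV (default 50).
#' @param seed Integer seed; repeat r uses fold seed `seed + r`.
#' @param selector Optional in-fold feature selector (see Details).
#' @return Object of class `classification_report`: `aggregate` (named
#'   vector auc/acc/f1/precision/recall), `per_repeat` data.frame (one row
#'   per repeat, incl. chosen kernel/cost/degree/gamma), `n_repeats`,
#'   `cv_folds`, `seed`.
#' @export
svm_classify <- function(features, labels, grid = default_svm_grid(),
                         cv_folds = 10L, n_repeats = 50L, seed = 1L,
                         selector = NULL) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            nrow(grid) >= 1L)
  labels <- as.integer(labels)
  n <- length(labels)
  per_repeat <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- make_folds(labels, cv_folds, seed + r)
    ## held-out predictions: [subject, combo]
    pred <- matrix(NA_integer_, n, nrow(grid))
    score <- matrix(NA_real_, n, nrow(grid))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      cols <- if (is.null(selector)) {
        seq_len(ncol(features))
      } else {
        selector(features[tr, , drop = FALSE], labels[tr])
      }
      sc <- scale_fit(features[tr, cols, drop = FALSE])
      xtr <- scale_apply(features[tr, cols, drop = FALSE], sc)
      xte <- scale_apply(features[!tr, cols, drop = FALSE], sc)
      for (g in seq_len(nrow(grid))) {
        fp <- svm_fit_predict(xtr, labels[tr], xte, grid[g, ])
        pred[!tr, g] <- fp$label
        score[!tr, g] <- fp$score
      }
    }
    cv_acc <- colMeans(pred == labels)
    best <- which.max(cv_acc)
    tp <- sum(pred[, best] == 1L & labels == 1L)
    tn <- sum(pred[, best] == 0L & labels == 0L)
    fp_ <- sum(pred[, best] == 1L & labels == 0L)
    fn <- sum(pred[, best] == 0L & labels == 1L)
    m <- metrics_from_confusion(tp, tn, fp_, fn)
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = score[, best],
      levels = c(0, 1), direction = "<", quiet = TRUE)))
    per_repeat[[r]] <- data.frame(
      repeat_index = r, auc = auc, acc = m[["acc"]], f1 = m[["f1"]],
      precision = m[["precision"]], recall = m[["recall"]],
      kernel = grid$kernel[best], cost = grid$cost[best],
      degree = grid$degree[best], gamma = grid$gamma[best],
      stringsAsFactors = FALSE)
  }
  per_repeat <- do.call(rbind, per_repeat)
  aggregate <- c(auc = mean(per_repeat$auc), acc = mean(per_repeat$acc),
                 f1 = mean(per_repeat$f1),
                 precision = mean(per_repeat$precision),
                 recall = mean(per_repeat$recall))
  structure(list(aggregate = aggregate, per_repeat = per_repeat,
                 n_repeats = n_repeats, cv_folds = cv_folds, seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Repeated cross-validated classification (", x$n_repeats,
      " repeats x ", x$cv_folds, "-fold)\n", sep = "")
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Accuracy sweep over the top-N ranked features
#'
#' For each N, classifies with the N most important features of `ranking`
#' and records the mean repeated-CV accuracy; the N maximising accuracy
#' defines the selected ("abnormal") feature set. The sweep can be
#' restricted to a subset of N values (`n_values`) to bound runtime on wide
#' matrices. Note the ranking is taken as given; if it was computed on the
#' same subjects the sweep measures an optimistic, selection-biased
#' accuracy, which is how exploratory selection curves are usually drawn.
#'
#' @inheritParams svm_classify
#' @param ranking A `feature_ranking` (or character vector of feature ids,
#'   most important first).
#' @param n_max Largest N to try (default: all ranked features).
#' @param n_values Integer vector of N values to evaluate (default
#'   `1:n_max`).
#' @param n_repeats CV repeats per N (default 1; the sweep is a curve, the
#'   final report should use [svm_classify()] with many repeats).
#' @return Object of class `topn_sweep`: data.frame `sweep` (`n`,
#'   `accuracy`), `best_n`, `selected_features`, `ranking`.
#' @export
topn_accuracy_sweep <- function(features, labels, ranking,
                                grid = default_svm_grid(), n_max = NULL,
                                n_values = NULL, cv_folds = 10L,
                                n_repeats = 1L, seed = 1L) {
  ids <- if (inherits(ranking, "feature_ranking")) ranking$ranking
         else as.character(ranking)
  stopifnot(all(ids %in% colnames(features)))
  if (is.null(n_max)) n_max <- length(ids)
  if (n_max > length(ids)) stop("'n_max' exceeds ranked feature count",
                                call. = FALSE)
  if (is.null(n_values)) n_values <- seq_len(n_max)
  n_values <- sort(unique(as.integer(n_values)))
  stopifnot(all(n_values >= 1L), all(n_values <= length(ids)))
  acc <- vapply(n_values, function(N) {
    rep_ <- svm_classify(features[, ids[seq_len(N)], drop = FALSE], labels,
                         grid = grid, cv_folds = cv_folds,
                         n_repeats = n_repeats, seed = seed)
    rep_$aggregate[["acc"]]
  }, numeric(1))
  ## among ties the largest N wins: the discriminative set errs on
  ## inclusion rather than dropping regions that cost nothing to keep
  best <- n_values[max(which(acc == max(acc)))]
  structure(list(sweep = data.frame(n = n_values, accuracy = acc),
                 best_n = best,
                 selected_features = ids[seq_len(best)],
                 ranking = ids),
            class = "topn_sweep")
}

#' Write a classification report to JSON / TSV
#'
#' @param report A `classification_report`.
#' @param path Output path; `.json` writes aggregate + per-repeat, anything
#'   else a one-row TSV of the aggregate metrics.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "classification_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(aggregate = as.list(report$aggregate),
                              per_repeat = report$per_repeat,
                              n_repeats = report$n_repeats,
                              cv_folds = report$cv_folds,
                              seed = report$seed),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(t(report$aggregate)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
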