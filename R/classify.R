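#' Median imputation of missing feature values
#'
#' Replaces every missing cell by the median of the observed values in its
#' column; observed cells are unchanged. Applied to the full table before
#' cross-validation, replicating the usual order of operations (the mild
#' information leakage this entails is documented; see
#' [evaluate_model()]'s `impute = "train"` for the leak-free alternative).
#'
#' @param table data.frame.
#' @param columns columns to impute (default: all numeric except
#'   `sample_id`).
#' @return the table with no missing cells in the imputed columns.
#' @export
median_impute <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                       "sample_id")
  for (cl in columns) {
    v <- table[[cl]]
    if (all(is.na(v))) stop("column '", cl, "' is fully missing")
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    table[[cl]] <- v
  }
  table
}

#' Shared train/test splits for repeated cross-validation
#'
#' Draws `n_repeats` random splits into training (`train_fraction`, default
#' 75%) and test (the rest). The same scheme object is passed to every model
#' evaluated, so per-split accuracies are paired and models are directly
#' comparable. By default splits are stratified by line (largest-remainder
#' allocation of the global 75% across lines) so that every line appears in
#' training; with 14 lines of ~5 tumors, unstratified splits frequently lose
#' a line entirely. Set `stratify = FALSE` for plain random splits.
#'
#' @param labels factor of class labels (or a data.frame with a `line`
#'   column).
#' @param n_repeats number of repeated splits (study default 1000).
#' @param train_fraction fraction of samples used for training, in (0, 1).
#' @param stratify stratify splits by class (default `TRUE`).
#' @param seed integer seed making the scheme reproducible.
#' @return object of class `cv_scheme`: list of `splits` (each
#'   `list(train=, test=)` index vectors), `n_repeats`, `train_fraction`,
#'   `stratify`, `seed`, `n`, and a `scheme_id` fingerprint.
#' @export
make_cv_scheme <- function(labels, n_repeats = 1000, train_fraction = 0.75,
                           stratify = TRUE, seed = NULL) {
  if (is.data.frame(labels)) labels <- labels$line
  labels <- factor(labels)
  n <- length(labels)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must be in (0, 1)")
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("train fraction leaves an empty train or test set")
  cls_idx <- split(seq_len(n), labels)
  ni <- lengths(cls_idx)
  if (stratify && any(ni < 2))
    stop("stratified splits need >= 2 samples per class")
  with_seed(seed, {
    splits <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      if (stratify) {
        # largest-remainder allocation of n_train across classes, >= 1 each
        exact <- train_fraction * ni
        base <- pmax(floor(exact), 1L)
        rem <- n_train - sum(base)
        if (rem > 0) {
          ord <- order(exact - floor(exact), decreasing = TRUE)
          add <- ord[seq_len(min(rem, length(ord)))]
          base[add] <- base[add] + 1L
        } else if (rem < 0) {
          ord <- order(exact - floor(exact))
          for (i in ord) {
            if (rem == 0) break
            if (base[i] > 1L) { base[i] <- base[i] - 1L; rem <- rem + 1L }
          }
        }
        train <- unlist(lapply(seq_along(cls_idx), function(i)
          sample(cls_idx[[i]], base[i])), use.names = FALSE)
      } else {
        train <- sample.int(n, n_train)
      }
      train <- sort(train)
      splits[[r]] <- list(train = train, test = setdiff(seq_len(n), train))
    }
    sch <- structure(list(splits = splits, n_repeats = n_repeats,
                          train_fraction = train_fraction,
                          stratify = stratify, seed = seed, n = n),
                     class = "cv_scheme")
    sch$scheme_id <- hash_obj(splits)
    sch
  })
}

table_to_xy <- function(table, columns, require_complete = TRUE) {
  if (length(columns) == 0) stop("empty column set")
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(table[columns])
  if (!is.numeric(x)) stop("feature columns must be numeric")
  if (require_complete && anyNA(x))
    stop("missing values present; run median_impute() first")
  y <- factor(table$line)
  if (nlevels(y) < 2) stop("need >= 2 classes")
  list(x = x, y = y)
}

#' Fit a Random Forest tumor-line classifier
#'
#' Grows `n_trees` CART trees on bootstrap samples with `mtry` (default
#' `floor(sqrt(p))`) candidate variables per split and reports out-of-bag
#' (OOB) accuracy: each sample is classified by majority vote of the trees
#' whose bootstrap sample excluded it. Ties in votes are broken towards the
#' lowest class index for determinism.
#'
#' @param table data.frame with a `line` label column; no missing values in
#'   the model columns (see [median_impute()]).
#' @param columns feature columns to use.
#' @param n_trees number of trees (study headline setting 20000; smaller
#'   values are appropriate for sweeps).
#' @param mtry candidate variables per split (default `floor(sqrt(p))`).
#' @param importance also compute OOB permutation importance.
#' @param seed integer seed.
#' @return object of class `rf_model` with `oob_accuracy` (percent),
#'   `importance` (percentage-point mean decrease in OOB accuracy, when
#'   requested), class `levels`, `columns` and the forest.
#' @export
fit_forest <- function(table, columns, n_trees = 20000, mtry = NULL,
                       importance = FALSE, seed = NULL) {
  d <- table_to_xy(table, columns)
  p <- ncol(d$x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  with_seed(seed, {
    fit <- .rf_train_cpp(d$x, as.integer(d$y) - 1L, nlevels(d$y),
                         as.integer(n_trees), as.integer(mtry),
                         isTRUE(importance))
    votes <- fit$oob_votes
    pred <- max.col(votes, ties.method = "first")
    has_votes <- rowSums(votes) > 0
    oob <- 100 * mean(pred == as.integer(d$y) & has_votes)
    imp <- if (isTRUE(importance)) {
      v <- 100 * fit$importance
      names(v) <- columns
      v
    }
    structure(list(forest = fit, levels = levels(d$y), columns = columns,
                   n_trees = n_trees, mtry = mtry, oob_accuracy = oob,
                   importance = imp),
              class = "rf_model")
  })
}

#' Predict tumor lines with a fitted forest
#' @param object an `rf_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return factor of predicted lines.
#' @export
predict.rf_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$columns])
  if (anyNA(x)) stop("missing values in newdata")
  cls <- .rf_predict_cpp(object$forest, x)
  factor(object$levels[cls + 1L], levels = object$levels)
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("Random Forest: %d trees, mtry %d, %d features, OOB accuracy %.1f%%\n",
              x$n_trees, x$mtry, length(x$columns), x$oob_accuracy))
  invisible(x)
}

#' Evaluate a column subset under a shared cross-validation scheme
#'
#' For every split of the scheme, trains a Random Forest on the training
#' samples and records the percentage of test samples classified correctly.
#' Classes absent from a training split are never predicted and simply score
#' as errors when present in the test set.
#'
#' @param table data.frame (no missing values in `columns`).
#' @param columns feature columns.
#' @param scheme a [make_cv_scheme()] object built on this table.
#' @param n_trees trees per split (default 500 for repeated evaluation).
#' @param mtry candidate variables per split (default `floor(sqrt(p))`).
#' @param seed integer seed.
#' @param model_name label carried into the result.
#' @param impute `"none"` (default; the table must already be complete, the
#'   full-table convention) or `"train"`: impute per split with training-set
#'   medians only, avoiding any leakage from test samples.
#' @return object of class `model_result`: `cv_accuracies` (percent, one per
#'   split), `mean`, `sd`, `model_name`, `columns`, `scheme_id`.
#' @export
evaluate_model <- function(table, columns, scheme, n_trees = 500,
                           mtry = NULL, seed = NULL, model_name = NULL,
                           impute = c("none", "train")) {
  stopifnot(inherits(scheme, "cv_scheme"))
  impute <- match.arg(impute)
  d <- table_to_xy(table, columns, require_complete = impute == "none")
  if (scheme$n != nrow(table))
    stop("scheme was built for a different number of samples")
  p <- ncol(d$x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  yi <- as.integer(d$y) - 1L
  with_seed(seed, {
    acc <- vapply(scheme$splits, function(sp) {
      xtr <- d$x[sp$train, , drop = FALSE]
      xte <- d$x[sp$test, , drop = FALSE]
      if (impute == "train") {
        for (j in seq_len(ncol(xtr))) {
          med <- stats::median(xtr[, j], na.rm = TRUE)
          if (is.na(med)) stop("column fully missing in a training split")
          xtr[is.na(xtr[, j]), j] <- med
          xte[is.na(xte[, j]), j] <- med
        }
      }
      pred <- .rf_train_predict_cpp(xtr, yi[sp$train], nlevels(d$y), xte,
                                    as.integer(n_trees), as.integer(mtry))
      100 * mean(pred == yi[sp$test])
    }, numeric(1))
    structure(list(model_name = model_name %||%
                     paste(length(columns), "columns"),
                   columns = columns, cv_accuracies = acc,
                   mean = mean(acc), sd = stats::sd(acc),
                   n_trees = n_trees, scheme_id = scheme$scheme_id),
              class = "model_result")
  })
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("%s: CV accuracy %.1f%% +/- %.1f%% over %d splits\n",
              x$model_name, x$mean, x$sd, length(x$cv_accuracies)))
  invisible(x)
}

#' Paired comparison of two models evaluated on shared splits
#'
#' Two-sided paired t-test on the per-split accuracy differences `a - b`.
#' Refuses to compare results from different schemes (the pairing would be
#' invalid). When all per-split differences are equal the variance is
#' degenerate: the result is flagged, with p = 0 for a non-zero constant
#' shift and p undefined for identical results.
#'
#' @param a,b `model_result` objects from [evaluate_model()] on the same
#'   scheme.
#' @return object of class `comparison_result`: `mean_difference`
#'   (percentage points), `ci95`, `p_value`, `test`, `degenerate`.
#' @export
compare_models <- function(a, b) {
  stopifnot(inherits(a, "model_result"), inherits(b, "model_result"))
  if (!identical(a$scheme_id, b$scheme_id))
    stop("models were not evaluated on the same cross-validation scheme")
  d <- a$cv_accuracies - b$cv_accuracies
  md <- mean(d)
  s <- stats::sd(d)
  if (length(d) < 2 || s == 0) {
    res <- list(mean_difference = md, ci95 = c(md, md),
                p_value = if (md == 0) NA_real_ else 0,
                test = "paired t", degenerate = TRUE, n = length(d))
  } else {
    se <- s / sqrt(length(d))
    tval <- md / se
    df <- length(d) - 1
    res <- list(mean_difference = md,
                ci95 = md + stats::qt(c(0.025, 0.975), df) * se,
                p_value = 2 * stats::pt(-abs(tval), df),
                test = "paired t", degenerate = FALSE, n = length(d))
  }
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Paired t: mean difference %.2f%% (95%% CI %.2f%%-%.2f%%), p = %.3g%s\n",
              x$mean_difference, x$ci95[1], x$ci95[2], x$p_value,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' OOB permutation importance of each parameter
#'
#' The Random-Forest-native estimate of the decrease in classification
#' accuracy attributable to each column: for every tree, its out-of-bag
#' accuracy is recomputed after permuting the column among the OOB samples,
#' and the per-tree decreases are averaged.
#'
#' @inheritParams fit_forest
#' @return data.frame `column`, `importance` (percentage points of OOB
#'   accuracy lost), sorted in input column order.
#' @export
parameter_importance <- function(table, columns, n_trees = 2000,
                                 seed = NULL) {
  fit <- fit_forest(table, columns, n_trees = n_trees, importance = TRUE,
                    seed = seed)
  data.frame(column = columns, importance = unname(fit$importance),
             stringsAsFactors = FALSE)
}

#' Exhaustive parameter-subset accuracy sweep
#'
#' For every subset size `k` in `k_range`, evaluates all `choose(p, k)`
#' combinations of the given IHC parameter columns under the shared scheme,
#' summarises mean accuracy per `k` (mean and SD over combination-level mean
#' accuracies) and tests consecutive subset sizes against each other with
#' Welch's two-sample t-test (combinations differ between sizes, so pairing
#' is undefined).
#'
#' @param table data.frame (imputed).
#' @param ihc_columns the parameter columns swept (the study design uses the
#'   9 IHC parameters, see [ihc_parameter_names()]).
#' @param k_range subset sizes (default `1:8`).
#' @param scheme shared [make_cv_scheme()].
#' @param n_trees trees per model (reduced counts, e.g. 100-500, keep the
#'   510-model sweep tractable).
#' @param seed integer seed.
#' @return list of class `sweep_result`: `combinations` (data.frame `k`,
#'   `columns`, `mean_accuracy`), `by_k` (`k`, `n_models`, `mean`, `sd`),
#'   `tests` (`k`, `p_value` vs `k-1`).
#' @export
subset_sweep <- function(table, ihc_columns, k_range = 1:8, scheme,
                         n_trees = 200, seed = NULL) {
  p <- length(ihc_columns)
  if (any(k_range < 1 | k_range > p - 1))
    stop("k_range must lie in 1..", p - 1)
  with_seed(seed, {
    rows <- list()
    acc_by_k <- list()
    for (k in k_range) {
      combos <- utils::combn(ihc_columns, k, simplify = FALSE)
      means <- vapply(combos, function(cols) {
        evaluate_model(table, cols, scheme, n_trees = n_trees)$mean
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        k = k,
        columns = vapply(combos, paste, "", collapse = "+"),
        mean_accuracy = means, stringsAsFactors = FALSE)
      acc_by_k[[as.character(k)]] <- means
    }
    combinations <- do.call(rbind, rows)
    by_k <- data.frame(
      k = k_range,
      n_models = vapply(acc_by_k, length, 0L),
      mean = vapply(acc_by_k, mean, 0),
      sd = vapply(acc_by_k, stats::sd, 0))
    tests <- data.frame(k = numeric(0), p_value = numeric(0))
    for (i in seq_along(k_range)[-1]) {
      a <- acc_by_k[[i]]; b <- acc_by_k[[i - 1L]]
      pv <- if (length(a) > 1 && length(b) > 1 &&
                (stats::sd(a) > 0 || stats::sd(b) > 0))
        stats::t.test(a, b)$p.value else NA_real_
      tests <- rbind(tests, data.frame(k = k_range[i], p_value = pv))
    }
    structure(list(combinations = combinations, by_k = by_k, tests = tests),
              class = "sweep_result")
  })
}
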