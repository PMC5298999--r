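# Ligand-type classification from per-atom buried-surface asymmetry:
# a shallow decision tree over (bsa_avg_Ag, bsa_avg_Ig), evaluated by
# repeated stratified 5-fold cross-validation, with a label-permutation
# baseline and a naive interface-size baseline.

.LIGAND_CLASSES <- c("chemical", "peptide", "protein")

#' Fit the ligand-type decision tree
#'
#' An axis-aligned CART tree (Gini impurity) on the two average-BSA features.
#' `max_depth = 2` allows at most three internal splits, i.e., three
#' separating lines partitioning the plane into rectangular regions.
#'
#' @param points data frame with the feature columns and a `label` column
#' @param features feature column names
#' @param label_col label column name
#' @param max_depth maximum tree depth
#' @param min_split minimum node size eligible for splitting
#' @param cp rpart complexity parameter
#' @return object of class `igvor_tree`
#' @export
fit_tree <- function(points, features = c("bsa_avg_Ag", "bsa_avg_Ig"),
                     label_col = "label", max_depth = 2, min_split = 2,
                     cp = 0) {
  stopifnot(all(c(features, label_col) %in% names(points)))
  y <- factor(as.character(points[[label_col]]))
  if (nlevels(y) < 2) {
    warning("single-class input: degenerate constant predictor", call. = FALSE)
    return(structure(list(fit = NULL, constant = levels(y),
                          features = features, classes = levels(y)),
                     class = "igvor_tree"))
  }
  dat <- points[, features, drop = FALSE]
  dat$.label <- y
  fit <- rpart::rpart(
    .label ~ ., data = dat, method = "class",
    control = rpart::rpart.control(maxdepth = max_depth, minsplit = min_split,
                                   minbucket = 1, cp = cp, xval = 0)
  )
  structure(list(fit = fit, constant = NULL, features = features,
                 classes = levels(y)),
            class = "igvor_tree")
}

#' @export
predict.igvor_tree <- function(object, newdata, ...) {
  if (!is.null(object$constant)) {
    return(factor(rep(object$constant, nrow(newdata)),
                  levels = object$classes))
  }
  predict(object$fit, newdata = newdata, type = "class")
}

#' Splits of a fitted tree
#'
#' @param model an `igvor_tree`
#' @return data frame of internal splits: `feature`, `threshold`
#' @export
tree_splits <- function(model) {
  stopifnot(inherits(model, "igvor_tree"))
  if (is.null(model$fit)) {
    return(data.frame(feature = character(), threshold = numeric(),
                      stringsAsFactors = FALSE))
  }
  fr <- model$fit$frame
  sp <- model$fit$splits
  internal <- fr$var != "<leaf>"
  if (!any(internal)) {
    return(data.frame(feature = character(), threshold = numeric(),
                      stringsAsFactors = FALSE))
  }
  # primary split of each internal node, in node order
  idx <- cumsum(c(1, fr$ncompete[internal] + fr$nsurrogate[internal] + 1))
  idx <- idx[seq_len(sum(internal))]
  data.frame(
    feature = as.character(fr$var[internal]),
    threshold = sp[idx, "index"],
    stringsAsFactors = FALSE
  )
}

#' Serialize a fitted tree to JSON
#'
#' @param model an `igvor_tree`
#' @param path output path
#' @return the path, invisibly
#' @export
write_tree_json <- function(model, path) {
  sp <- tree_splits(model)
  jsonlite::write_json(
    list(features = model$features, classes = model$classes,
         constant = model$constant, splits = sp),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

.class_errors <- function(truth, pred, classes) {
  per_class <- vapply(classes, function(cl) {
    sel <- truth == cl
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] != cl)
  }, numeric(1))
  list(overall = mean(pred != truth), per_class = per_class)
}

.new_eval <- function(protocol, overall_errors, per_class_errors, classes,
                      confusion = NULL, extra = list()) {
  structure(c(list(
    protocol = protocol,
    median_error = .median_low(overall_errors),
    per_class_median = apply(per_class_errors, 2, function(x)
      .median_low(x[!is.na(x)])),
    n_repetitions = length(overall_errors),
    overall_errors = overall_errors,
    confusion = confusion,
    classes = classes
  ), extra), class = "igvor_eval")
}

#' @export
print.igvor_eval <- function(x, ...) {
  cat(sprintf("Evaluation report [%s], %d repetitions\n", x$protocol,
              x$n_repetitions))
  cat(sprintf("  median overall error: %.4f\n", x$median_error))
  for (cl in names(x$per_class_median)) {
    cat(sprintf("  median error (%s): %.4f\n", cl, x$per_class_median[[cl]]))
  }
  invisible(x)
}

# Stratified (or plain) fold assignment for one repetition.
.fold_assign <- function(y, k, stratified) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold <- rep_len(seq_len(k), n)[sample.int(n)]
  }
  fold
}

#' Repeated k-fold cross-validation of the ligand-type tree
#'
#' For each repetition the data are split into `k_folds` random
#' (class-stratified by default) folds; each fold is predicted by a tree
#' fitted on the others. Reports lower-median overall and per-class errors
#' over repetitions, and the confusion matrix of the first repetition.
#'
#' @inheritParams fit_tree
#' @param k_folds number of folds
#' @param n_reps number of cross-validation repetitions
#' @param seed RNG seed
#' @param stratified stratify folds by class
#' @param protocol protocol tag stored in the report
#' @param ... passed to [fit_tree()]
#' @return an `igvor_eval` report
#' @export
cross_validate <- function(points, features = c("bsa_avg_Ag", "bsa_avg_Ig"),
                           label_col = "label", k_folds = 5, n_reps = 1000,
                           seed = 1, stratified = TRUE,
                           protocol = "tree-cv", ...) {
  y <- factor(as.character(points[[label_col]]))
  classes <- levels(y)
  if (min(table(y)) < k_folds) {
    warning("fewer points than folds in some class; folds degenerate",
            call. = FALSE)
  }
  overall <- numeric(n_reps)
  per_class <- matrix(NA_real_, n_reps, length(classes),
                      dimnames = list(NULL, classes))
  confusion <- NULL
  .with_seed(seed, {
    for (r in seq_len(n_reps)) {
      fold <- .fold_assign(y, k_folds, stratified)
      pred <- factor(rep(NA_character_, length(y)), levels = classes)
      for (f in seq_len(k_folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2) next
        model <- fit_tree(points[tr, , drop = FALSE], features = features,
                          label_col = label_col, ...)
        pred[!tr] <- predict(model, points[!tr, , drop = FALSE])
      }
      ok <- !is.na(pred)
      err <- .class_errors(y[ok], pred[ok], classes)
      overall[r] <- err$overall
      per_class[r, ] <- err$per_class
      if (r == 1) confusion <- table(truth = y[ok], predicted = pred[ok])
    }
  })
  .new_eval(protocol, overall, per_class, classes, confusion,
            extra = list(k_folds = k_folds, stratified = stratified,
                         features = features, seed = seed))
}

#' Label-permutation baseline
#'
#' Random predictions obtained by permuting the label vector, preserving the
#' number of complexes per class. The per-permutation error is the fraction
#' of positions whose permuted label differs from the true label.
#'
#' @param labels vector of class labels
#' @param n_perms number of random permutations
#' @param seed RNG seed
#' @return an `igvor_eval` report
#' @export
permutation_test <- function(labels, n_perms = 10000, seed = 1) {
  y <- factor(as.character(labels))
  classes <- levels(y)
  if (length(classes) < 2) stop("permutation test needs >= 2 classes")
  n <- length(y)
  overall <- numeric(n_perms)
  per_class <- matrix(NA_real_, n_perms, length(classes),
                      dimnames = list(NULL, classes))
  confusion <- NULL
  .with_seed(seed, {
    for (r in seq_len(n_perms)) {
      pred <- y[sample.int(n)]
      err <- .class_errors(y, pred, classes)
      overall[r] <- err$overall
      per_class[r, ] <- err$per_class
      if (r == 1) confusion <- table(truth = y, predicted = pred)
    }
  })
  .new_eval("permutation", overall, per_class, classes, confusion,
            extra = list(seed = seed))
}

#' Closed-form expected permutation error
#'
#' For class counts `n_c` out of `n`, a uniform count-preserving label
#' permutation misclassifies in expectation `1 - sum n_c (n_c - 1) / (n (n - 1))`
#' of the positions overall and `1 - (n_c - 1) / (n - 1)` within class `c`.
#'
#' @param counts named vector of class counts
#' @return list with `overall` and `per_class`
#' @export
expected_permutation_error <- function(counts) {
  n <- sum(counts)
  list(
    overall = 1 - sum(counts * (counts - 1)) / (n * (n - 1)),
    per_class = setNames(1 - (counts - 1) / (n - 1), names(counts))
  )
}

#' Naive baseline: classify from interface size only
#'
#' Same protocol as [cross_validate()], with the single feature
#' `|I| = |I_Ig| + |I_Ag|` (column `n_interface`).
#'
#' @inheritParams cross_validate
#' @param feature the interface-size column name
#' @return an `igvor_eval` report with protocol `"naive"`
#' @export
naive_classifier <- function(points, feature = "n_interface",
                             label_col = "label", k_folds = 5, n_reps = 1000,
                             seed = 1, ...) {
  cross_validate(points, features = feature, label_col = label_col,
                 k_folds = k_folds, n_reps = n_reps, seed = seed,
                 protocol = "naive", ...)
}
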