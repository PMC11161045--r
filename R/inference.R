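ASSEMBLY_MODELS <- c("neutral", "filtering", "mean", "pairwise", "beta")

# resolve an axis mask ("sad+gen" style shorthands accepted) to feature columns
resolve_axes <- function(axes) {
  axes <- tolower(axes)
  shorthand <- list("sad+gen" = c("abundance", "genetic"),
                    "trait+gen" = c("trait", "genetic"),
                    "all" = c("abundance", "genetic", "trait"))
  if (length(axes) == 1 && axes %in% names(shorthand))
    axes <- shorthand[[axes]]
  bad <- setdiff(axes, c("abundance", "genetic", "trait"))
  if (length(bad))
    stop("unknown data axes: ", paste(bad, collapse = ", "))
  axes
}

#' Feature columns available under an axis mask
#'
#' @param axes character vector of available data axes (subset of
#'   `"abundance"`, `"genetic"`, `"trait"`), or one of the shorthands
#'   `"sad+gen"`, `"trait+gen"`, `"all"`.
#' @return Character vector of feature column names (richness `S` is always
#'   included; `lambda` never is).
#' @export
mask_features <- function(axes = "all") {
  axes <- resolve_axes(axes)
  sch <- sumstats_schema()
  keep <- vapply(strsplit(sch$axes, ","), function(req) {
    if (identical(req, "any")) TRUE
    else if (identical(req, "meta")) FALSE
    else all(req %in% axes)
  }, logical(1))
  sch$column[keep]
}

prepare_features <- function(table, axes, label_col = "model",
                             require_labels = TRUE) {
  feats <- mask_features(axes)
  missing <- setdiff(feats, names(table))
  if (length(missing))
    stop("input table is missing feature columns: ",
         paste(missing, collapse = ", "))
  x <- table[, feats, drop = FALSE]
  all_na <- vapply(x, function(v) all(is.na(v)), logical(1))
  if (any(all_na)) {
    message("dropping all-sentinel feature columns: ",
            paste(names(x)[all_na], collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
  }
  ok <- stats::complete.cases(x)
  y <- NULL
  if (require_labels) {
    if (!label_col %in% names(table))
      stop("no '", label_col, "' column in the training table")
    y <- factor(table[[label_col]],
                levels = intersect(ASSEMBLY_MODELS,
                                   unique(table[[label_col]])))
    ok <- ok & !is.na(y)
  }
  if (!all(ok))
    message(sum(!ok), " row(s) with sentinel feature values dropped")
  list(x = x[ok, , drop = FALSE],
       y = if (!is.null(y)) droplevels(y[ok]) else NULL,
       features = names(x), kept = which(ok))
}

#' Train the assembly-model classifier
#'
#' Fits a random forest (1000 trees by default) on the summary-statistic
#' table restricted to the given axis mask.  Feature columns that are
#' entirely sentinel-valued under the mask are dropped (never imputed), as
#' are the few rows with sporadic sentinel features (e.g. skewness of a
#' two-species community).  Class probabilities are tree-vote fractions.
#'
#' @param table summary-statistic table with a `model` label column (as
#'   produced by [run_batch()], or any table matching [sumstats_schema()]).
#' @param axes data axes available to the classifier; see [mask_features()].
#' @param num_trees forest size.
#' @param seed integer seed (forests are deterministic under it).
#' @param label_col name of the label column.
#' @return An object of class `assembly_classifier`.
#' @export
train_classifier <- function(table, axes = "all", num_trees = 1000,
                             seed = 1, label_col = "model") {
  prep <- prepare_features(table, axes, label_col)
  if (nlevels(prep$y) < 2)
    stop("training needs at least 2 distinct model labels")
  fit <- ranger::ranger(x = prep$x, y = prep$y, num.trees = num_trees,
                        probability = TRUE, seed = seed, num.threads = 1)
  oob <- colnames(fit$predictions)[max.col(fit$predictions)]
  structure(list(fit = fit, features = prep$features,
                 axes = resolve_axes(axes), levels = levels(prep$y),
                 num_trees = num_trees, seed = seed,
                 oob_accuracy = mean(oob == as.character(prep$y))),
            class = "assembly_classifier")
}

#' @export
print.assembly_classifier <- function(x, ...) {
  cat("Assembly-model random forest:", x$num_trees, "trees,",
      length(x$features), "features [", paste(x$axes, collapse = "+"), "]\n")
  cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  cat("  out-of-bag accuracy:", round(x$oob_accuracy, 3), "\n")
  invisible(x)
}

#' Predict assembly-model class probabilities
#'
#' @param classifier an [train_classifier()] fit.
#' @param table summary-statistic rows matching the training schema (the
#'   mask's feature columns must all be present).
#' @param collapse_competition merge the pairwise and beta competition
#'   classes into one `pairwise+beta` column (their probabilities add
#'   exactly, as the two models are near-indistinguishable).
#' @return Data frame of per-row class probabilities (rows sum to 1), of
#'   class `class_probabilities`.
#' @export
classify <- function(classifier, table, collapse_competition = FALSE) {
  stopifnot(inherits(classifier, "assembly_classifier"))
  missing <- setdiff(classifier$features, names(table))
  extra <- setdiff(mask_features(classifier$axes), classifier$features)
  if (length(missing))
    stop("input table is missing feature columns: ",
         paste(missing, collapse = ", "),
         if (length(extra)) paste0(" (columns dropped in training: ",
                                   paste(extra, collapse = ", "), ")") else "")
  x <- table[, classifier$features, drop = FALSE]
  if (any(!stats::complete.cases(x)))
    stop("input rows contain sentinel (NA) values in mask features")
  p <- predict(classifier$fit, data = x)$predictions
  p <- as.data.frame(p)
  if (collapse_competition &&
      all(c("pairwise", "beta") %in% names(p))) {
    p[["pairwise+beta"]] <- p$pairwise + p$beta
    p <- p[, setdiff(names(p), c("pairwise", "beta")), drop = FALSE]
  }
  class(p) <- c("class_probabilities", "data.frame")
  p
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Out-of-fold predictions are pooled into a single confusion matrix
#' (rows = true model, columns = predicted).  Overall accuracy is the
#' diagonal sum over the total; the pairwise+beta-collapsed accuracy
#' additionally counts confusions within the competition pair as correct.
#'
#' @param table labelled summary-statistic table.
#' @param axes data axes available; see [mask_features()].
#' @param k number of folds; must not exceed the smallest class count.
#' @param num_trees,seed,label_col as in [train_classifier()].
#' @return An object of class `assembly_cv`: `confusion` (counts),
#'   `confusion_pct` (row percentages), `accuracy`,
#'   `accuracy_collapsed`, `k`, `n`.
#' @export
cross_validate <- function(table, axes = "all", k = 5, num_trees = 1000,
                           seed = 1, label_col = "model") {
  prep <- prepare_features(table, axes, label_col)
  y <- prep$y
  counts <- table(y)
  if (k > min(counts))
    stop("k = ", k, " exceeds the smallest class count (", min(counts), ")")
  if (max(counts) / min(counts) > 2)
    warning("class sizes are unbalanced (max/min > 2); ",
            "stratified folds keep proportions but accuracy may mislead")
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  pred <- character(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- ranger::ranger(x = prep$x[tr, , drop = FALSE], y = y[tr],
                          num.trees = num_trees, probability = TRUE,
                          seed = seed + f, num.threads = 1)
    p <- predict(fit, data = prep$x[!tr, , drop = FALSE])$predictions
    pred[!tr] <- colnames(p)[max.col(p)]
  }
  pred <- factor(pred, levels = levels(y))
  conf <- table(true = y, predicted = pred)
  acc <- sum(diag(conf)) / sum(conf)
  comp <- intersect(c("pairwise", "beta"), levels(y))
  acc_coll <- (sum(diag(conf)) +
                 sum(conf[comp, comp]) - sum(diag(conf[comp, comp, drop = FALSE]))) /
    sum(conf)
  structure(list(confusion = conf,
                 confusion_pct = prop.table(conf, 1) * 100,
                 accuracy = acc, accuracy_collapsed = acc_coll,
                 k = k, n = length(y), axes = resolve_axes(axes)),
            class = "assembly_cv")
}

#' @export
print.assembly_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV on %d simulations [%s]\n", x$k, x$n,
              paste(x$axes, collapse = "+")))
  cat(sprintf("  accuracy: %.1f%% (pairwise+beta collapsed: %.1f%%)\n",
              100 * x$accuracy, 100 * x$accuracy_collapsed))
  print(round(x$confusion_pct, 1))
  invisible(x)
}

#' PCA projection of simulation summary statistics
#'
#' Column-standardized principal components of the feature matrix, used to
#' visualize how the assembly models separate as communities approach
#' equilibrium.  Zero-variance columns are dropped with a warning before
#' standardization.
#'
#' @param table summary-statistic table.
#' @param axes data axes to include.
#' @param labels optional model labels (defaults to the `model` column if
#'   present).
#' @param lambda_bins break points used to bin the `lambda` column for
#'   plotting; `NULL` for no binning.
#' @return An object of class `assembly_pca`: `scores` (data frame with
#'   PC1, PC2, label, lambda_bin), `explained` (per-component variance
#'   ratios), and the `prcomp` fit.
#' @export
pca_projection <- function(table, axes = "all", labels = NULL,
                           lambda_bins = c(0, 0.25, 0.5, 0.75, 1)) {
  feats <- mask_features(axes)
  missing <- setdiff(feats, names(table))
  if (length(missing))
    stop("input table is missing feature columns: ",
         paste(missing, collapse = ", "))
  x <- table[, feats, drop = FALSE]
  ok <- stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]
  if (nrow(x) < 3) stop("PCA needs at least 3 complete rows")
  v <- vapply(x, function(col) stats::var(col), numeric(1))
  if (any(v == 0)) {
    warning("dropping zero-variance columns: ",
            paste(names(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("PCA needs at least 2 informative features")
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  labels <- labels %||% if ("model" %in% names(table))
    table$model[ok] else rep(NA_character_, nrow(x))
  lb <- rep(NA_character_, nrow(x))
  if (!is.null(lambda_bins) && "lambda" %in% names(table)) {
    lam <- table$lambda[ok]
    lb <- as.character(cut(lam, breaks = lambda_bins,
                           include.lowest = TRUE))
  }
  structure(list(scores = data.frame(PC1 = fit$x[, 1], PC2 = fit$x[, 2],
                                     label = labels, lambda_bin = lb),
                 explained = explained, fit = fit),
            class = "assembly_pca")
}

#' @export
print.assembly_pca <- function(x, ...) {
  cat("PCA of summary statistics:",
      sprintf("PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' @export
plot.assembly_pca <- function(x, ...) {
  sc <- x$scores
  lv <- factor(sc$label)
  graphics::plot(sc$PC1, sc$PC2, col = as.integer(lv), pch = 16,
                 cex = 0.5,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
  graphics::legend("topright", legend = levels(lv), col = seq_along(levels(lv)),
                   pch = 16, cex = 0.8)
  invisible(x)
}

#' Write a confusion matrix as delimited text
#'
#' Counts and row percentages side by side.
#'
#' @param cv an [cross_validate()] result.
#' @param file output path.
#' @export
write_confusion <- function(cv, file) {
  cnt <- as.data.frame.matrix(cv$confusion)
  pct <- as.data.frame.matrix(round(cv$confusion_pct, 2))
  names(pct) <- paste0(names(pct), "_pct")
  out <- cbind(true = rownames(cnt), cnt, pct)
  write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
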