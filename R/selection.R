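# Two-step feature selection: SVM-based recursive feature elimination ranked
# by linear-SVM weight magnitude with a cross-validated stopping criterion,
# followed by Pearson-correlation redundancy pruning.

#' Extract the feature matrix and labels from a feature table
#'
#' @param table An `hs_feature_table` (or plain data frame) containing
#'   feature columns and a `label` column (1 = hot spot).
#' @param features Feature column names; defaults to every 24-encoding column
#'   present, or all numeric non-key columns.
#' @return List with matrix `x` and numeric vector `y`.
#' @export
table_xy <- function(table, features = NULL) {
  if (is.null(features)) {
    features <- intersect(FEATURE_NAMES, names(table))
    if (!length(features)) {
      features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          c("label", "resnum"))
    }
  }
  stopifnot(all(features %in% names(table)), "label" %in% names(table))
  list(x = as.matrix(as.data.frame(table, check.names = FALSE)[, features,
                                                               drop = FALSE]),
       y = as.numeric(table$label))
}

# min-max scaling to [0,1]; constant columns map to 0
minmax_fit <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  list(lo = lo, hi = hi)
}
minmax_apply <- function(scaler, x) {
  rng <- scaler$hi - scaler$lo
  rng[rng == 0] <- 1
  sweep(sweep(x, 2, scaler$lo), 2, rng, "/")
}

# per-column median imputation
impute_fit <- function(x) apply(x, 2, function(col) median(col, na.rm = TRUE))
impute_apply <- function(medians, x) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- medians[[j]]
  }
  x
}

#' SVM-based recursive feature elimination
#'
#' Iteratively fits a linear-kernel SVM on the (min-max scaled) surviving
#' features and eliminates the feature with the smallest absolute weight, one
#' per iteration. At each subset size the working RBF classifier is scored by
#' stratified k-fold cross-validated AUC (pooled out-of-fold decision
#' values); the selected subset is the size maximizing CV AUC, ties going to
#' the smaller subset.
#'
#' @param table Feature table with labels (see [table_xy()]).
#' @param folds Number of CV folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param features Optional explicit feature set.
#' @param C_linear Cost of the ranking linear SVM (default 1).
#' @param C,gamma RBF parameters for the CV scoring model (defaults 4.5,
#'   0.05).
#' @return List: `ranking` (best-first feature names), `elimination_order`
#'   (worst-first), `cv_curve` (data frame size/auc/features), `best_subset`.
#' @export
svm_rfe <- function(table, folds = 10, seed = 1, features = NULL,
                    C_linear = 1, C = 4.5, gamma = 0.05) {
  xy <- table_xy(table, features)
  stopifnot(ncol(xy$x) >= 2, length(unique(xy$y)) == 2)
  x <- impute_apply(impute_fit(xy$x), xy$x)
  scaler <- minmax_fit(x)
  xs <- minmax_apply(scaler, x)
  y <- xy$y
  folds_id <- stratified_folds(y, folds, seed)

  surviving <- colnames(xs)
  eliminated <- character(0)
  curve <- data.frame(size = integer(0), auc = numeric(0),
                      features = character(0), stringsAsFactors = FALSE)
  while (length(surviving) >= 1) {
    cv <- cv_rbf(xs[, surviving, drop = FALSE], y, C, gamma, folds_id)
    curve <- rbind(curve, data.frame(
      size = length(surviving), auc = cv$auc,
      features = paste(surviving, collapse = ","), stringsAsFactors = FALSE))
    if (length(surviving) == 1) break
    lin <- svm_fit(xs[, surviving, drop = FALSE], y, kernel = "linear",
                   C = C_linear)
    drop_i <- which.min(abs(lin$w))   # ties -> first in column order
    eliminated <- c(eliminated, surviving[drop_i])
    surviving <- surviving[-drop_i]
  }

  ranking <- rev(c(eliminated, surviving))  # best-first
  best_row <- with(curve, which(auc == max(auc)))
  best_row <- best_row[which.min(curve$size[best_row])]
  best_size <- curve$size[best_row]
  best_subset <- ranking[seq_len(best_size)]

  list(ranking = ranking, elimination_order = eliminated,
       cv_curve = curve, best_subset = best_subset, seed = seed)
}

#' Pearson-correlation redundancy pruning
#'
#' Repeatedly finds the surviving feature pair with the largest correlation
#' above `threshold` and drops its worse-RFE-ranked member, until no pair
#' exceeds the threshold. Correlations are computed on unscaled feature
#' values; a zero-variance feature correlates 0 with everything. By default
#' only positive correlations count (`use_abs = FALSE`).
#'
#' @param table Feature table with labels.
#' @param subset Features to prune (the step-1 subset).
#' @param ranking Best-first feature ranking from [svm_rfe()].
#' @param threshold Correlation threshold (default 0.65, strict `>`).
#' @param use_abs Prune on `|r|` instead of signed `r`.
#' @return List: `final_subset`, `pruned` (data frame of dropped/kept/r),
#'   `cor_matrix` (correlations of the step-1 subset).
#' @export
pearson_prune <- function(table, subset, ranking, threshold = 0.65,
                          use_abs = FALSE) {
  stopifnot(length(subset) >= 1, all(subset %in% ranking))
  xy <- table_xy(table, subset)
  x <- impute_apply(impute_fit(xy$x), xy$x)
  cm <- suppressWarnings(cor(x))
  cm[!is.finite(cm)] <- 0          # zero-variance features
  full_cm <- cm
  rank_of <- setNames(seq_along(ranking), ranking)

  surviving <- subset
  pruned <- data.frame(dropped = character(0), kept = character(0),
                       r = numeric(0), stringsAsFactors = FALSE)
  repeat {
    if (length(surviving) < 2) break
    sub_cm <- cm[surviving, surviving, drop = FALSE]
    val <- if (use_abs) abs(sub_cm) else sub_cm
    diag(val) <- -Inf
    if (max(val) <= threshold) break
    ij <- which(val == max(val), arr.ind = TRUE)[1, ]
    f1 <- surviving[ij[1]]; f2 <- surviving[ij[2]]
    drop_f <- if (rank_of[[f1]] > rank_of[[f2]]) f1 else f2
    keep_f <- setdiff(c(f1, f2), drop_f)
    pruned <- rbind(pruned, data.frame(dropped = drop_f, kept = keep_f,
                                       r = sub_cm[ij[1], ij[2]],
                                       stringsAsFactors = FALSE))
    surviving <- setdiff(surviving, drop_f)
  }

  list(final_subset = surviving, pruned = pruned, cor_matrix = full_cm)
}

#' Two-step feature selection
#'
#' Step 1: recursive feature elimination ([svm_rfe()]). Step 2: correlation
#' pruning of the step-1 subset ([pearson_prune()]).
#'
#' @param table Feature table with labels.
#' @param folds,seed,features,C,gamma Passed to [svm_rfe()].
#' @param threshold,use_abs Passed to [pearson_prune()].
#' @return Object of class `hs_selection`: `ranking`, `cv_curve`,
#'   `step1_subset`, `cor_matrix`, `pruned`, `final_subset`, `seed`.
#' @export
two_step_select <- function(table, folds = 10, seed = 1, features = NULL,
                            threshold = 0.65, use_abs = FALSE,
                            C = 4.5, gamma = 0.05) {
  rfe <- svm_rfe(table, folds = folds, seed = seed, features = features,
                 C = C, gamma = gamma)
  stopifnot(length(rfe$best_subset) >= 1)
  pr <- pearson_prune(table, rfe$best_subset, rfe$ranking,
                      threshold = threshold, use_abs = use_abs)
  structure(list(ranking = rfe$ranking, cv_curve = rfe$cv_curve,
                 step1_subset = rfe$best_subset, cor_matrix = pr$cor_matrix,
                 pruned = pr$pruned, final_subset = pr$final_subset,
                 threshold = threshold, seed = seed),
            class = "hs_selection")
}

#' @export
print.hs_selection <- function(x, ...) {
  cat("<hs_selection> ", length(x$ranking), " features -> step 1: ",
      length(x$step1_subset), " -> final: ", length(x$final_subset), "\n",
      "final subset: ", paste(x$final_subset, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a selection result
#'
#' JSON for the ranking, CV curve and pruning audit trail; TSV for the
#' correlation matrix.
#'
#' @param sel An `hs_selection`.
#' @param json_path Output JSON path.
#' @param cor_path Optional TSV path for the step-1 correlation matrix.
#' @return `json_path`, invisibly.
#' @export
write_selection <- function(sel, json_path, cor_path = NULL) {
  jsonlite::write_json(list(
    ranking = sel$ranking, cv_curve = sel$cv_curve,
    step1_subset = sel$step1_subset, pruned = sel$pruned,
    final_subset = sel$final_subset, threshold = sel$threshold,
    seed = sel$seed
  ), json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(cor_path)) {
    write.table(sel$cor_matrix, cor_path, sep = "\t", quote = FALSE)
  }
  invisible(json_path)
}
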