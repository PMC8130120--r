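# Final classifier: grid-searched RBF-kernel SVM with stratified tenfold CV,
# Platt-calibrated probabilities, persistence.

#' Model training configuration
#'
#' @param C_grid Cost grid; spans 0.1-10 and includes the reference optimum
#'   4.5.
#' @param gamma_grid Kernel width grid; spans 0.005-0.5 and includes the
#'   reference optimum 0.05.
#' @param folds CV folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return List of class `hs_model_config`.
#' @export
model_config <- function(C_grid = c(0.1, 0.5, 1, 2, 3, 4, 4.5, 5, 7, 10),
                         gamma_grid = c(0.005, 0.01, 0.05, 0.1, 0.2, 0.5),
                         folds = 10, seed = 1) {
  stopifnot(length(C_grid) >= 1, all(C_grid > 0),
            length(gamma_grid) >= 1, all(gamma_grid > 0), folds >= 2)
  structure(list(C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 folds = folds, seed = seed), class = "hs_model_config")
}

#' Grid-search training of the hot spot classifier
#'
#' Exhaustive search over `(C, gamma)` scored by stratified k-fold
#' cross-validated AUC (pooled out-of-fold decision values). Ties are broken
#' toward the smaller `C`, then the smaller `gamma`. The winning parameters
#' are refit on the full training table; a Platt sigmoid fitted to the
#' winner's out-of-fold decision values maps decisions to probabilities.
#' Median imputation and min-max scaling are fitted on the training table and
#' persisted with the model.
#'
#' @param table Feature table with a `label` column.
#' @param config An [model_config()].
#' @param features Feature columns to use (default: all 24-encoding columns
#'   present).
#' @return Object of class `hs_model`.
#' @export
grid_search_train <- function(table, config = model_config(), features = NULL) {
  xy <- table_xy(table, features)
  if (length(unique(xy$y)) < 2) stop("training table must contain both classes")
  medians <- impute_fit(xy$x)
  x <- impute_apply(medians, xy$x)
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite feature value at row ", bad[1, 1], ", column '",
         colnames(x)[bad[1, 2]], "'")
  }
  scaler <- minmax_fit(x)
  xs <- minmax_apply(scaler, x)
  y <- xy$y
  if (min(table(y)) < config$folds) {
    stop("need at least ", config$folds, " samples per class for ",
         config$folds, "-fold stratified CV")
  }
  folds_id <- stratified_folds(y, config$folds, config$seed)

  grid <- expand.grid(gamma = config$gamma_grid, C = config$C_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("C", "gamma")]
  grid$auc <- NA_real_
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    cv <- cv_rbf(xs, y, grid$C[g], grid$gamma[g], folds_id)
    grid$auc[g] <- cv$auc
    # grid is sorted by (C, gamma); strict > keeps the smallest winners
    if (is.null(best) || cv$auc > best$auc + 1e-12) {
      best <- list(C = grid$C[g], gamma = grid$gamma[g], auc = cv$auc,
                   dec = cv$decisions)
    }
  }

  fit <- svm_fit(xs, y, kernel = "rbf", C = best$C, gamma = best$gamma)
  platt <- platt_fit(best$dec, y)

  structure(list(fit = fit, platt = platt, scaler = scaler,
                 medians = medians, features = colnames(xs),
                 C = best$C, gamma = best$gamma, cv_auc = best$auc,
                 cv_grid = grid, config = config),
            class = "hs_model")
}

#' @export
print.hs_model <- function(x, ...) {
  cat("<hs_model> RBF SVM: C = ", x$C, ", gamma = ", x$gamma,
      "; CV AUC = ", round(x$cv_auc, 3), "; ", length(x$features),
      " features\n", sep = "")
  invisible(x)
}

#' Predict hot spot probabilities
#'
#' @param object An `hs_model`.
#' @param table Feature table carrying the model's feature columns.
#' @param threshold Probability threshold for the hard label (default 0.5).
#' @param ... Unused.
#' @return Data frame with `score` (Platt probability of being a hot spot),
#'   `decision` (raw SVM decision value) and `label` (0/1 at `threshold`).
#' @export
predict.hs_model <- function(object, table, threshold = 0.5, ...) {
  missing <- setdiff(object$features, names(table))
  if (length(missing)) {
    stop("feature column(s) missing from input: ",
         paste(missing, collapse = ", "))
  }
  x <- as.matrix(as.data.frame(table, check.names = FALSE)[, object$features,
                                                           drop = FALSE])
  x <- impute_apply(object$medians, x)
  xs <- minmax_apply(object$scaler, x)
  dec <- svm_decision(object$fit, xs)
  score <- platt_prob(object$platt, dec)
  data.frame(score = score, decision = dec,
             label = as.integer(score >= threshold))
}

#' Persist a trained model
#'
#' Single-archive serialization (RDS) of the support-vector state, scaler,
#' imputation vector, feature list and configuration.
#'
#' @param model An `hs_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' Load a persisted model
#'
#' @param path Path written by [save_model()].
#' @return An `hs_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "hs_model"))
  model
}
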