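#' Baseline probabilistic classifiers
#'
#' The comparison models of the study: L2-regularized logistic regression and
#' an ensemble of 512 extremely randomized trees, both fit on the
#' demographics-plus-code-words features (and logistic regression also on the
#' low-dimensional topic features). Hyperparameters are selected by grid
#' search maximizing validation AUC. Probabilities are used uncalibrated:
#' every downstream evaluation (AUC, ranking, quartiles) is rank-based.
#'
#' @name baselines
NULL

#' Default hyperparameter grids
#'
#' Logistic regression: L2 penalty strength. Extra trees: tree depth
#' (0 = unlimited) crossed with minimum leaf size, 512 trees throughout.
#'
#' @param family `"logistic"` or `"extra_trees"`.
#' @return data.frame of grid points, one row each, in search order.
#' @export
default_grid <- function(family) {
  switch(family,
    logistic = data.frame(lambda = c(0.01, 0.1, 1, 10)),
    extra_trees = expand.grid(max_depth = c(8L, 16L, 0L),
                              min_node = c(1L, 5L, 25L)),
    stop("unknown family: ", family))
}

fit_one <- function(family, X, y, point, seed) {
  if (family == "logistic") {
    glmnet::glmnet(X, factor(y), family = "binomial", alpha = 0,
                   lambda = point$lambda)
  } else {
    ranger::ranger(x = as.matrix(X), y = factor(y), probability = TRUE,
                   num.trees = 512L, splitrule = "extratrees",
                   num.random.splits = 1L, replace = FALSE,
                   sample.fraction = 1, max.depth = point$max_depth,
                   min.node.size = point$min_node, seed = seed,
                   num.threads = 1L)
  }
}

predict_one <- function(family, model, X) {
  if (family == "logistic") {
    drop(predict(model, as.matrix(X), type = "response"))
  } else {
    p <- predict(model, data = as.matrix(X), num.threads = 1L)$predictions
    drop(p[, "TRUE"])
  }
}

#' Train one classifier with validation-AUC grid search
#'
#' Each grid point is fit on the training rows and scored by AUC on the
#' validation rows; the argmax is returned (ties go to the first point in
#' grid order). All fits are seeded.
#'
#' @param family `"logistic"` or `"extra_trees"`.
#' @param X_train,X_val feature matrices with patient-id rownames.
#' @param y_train,y_val binary labels aligned with the rows.
#' @param grid data.frame of hyperparameter points; defaults to
#'   [default_grid()].
#' @param seed integer seed.
#' @return a `stablerx_classifier`: list with `family`, `model`, `chosen`
#'   (grid row), `val_auc`, `grid_aucs`. Returns NULL (with a warning) when
#'   the training labels have a single class.
#' @export
train_classifier <- function(family, X_train, y_train, X_val, y_val,
                             grid = default_grid(family), seed = 1L) {
  stopifnot(nrow(grid) >= 1L)
  y_train <- as.logical(y_train); y_val <- as.logical(y_val)
  if (length(unique(y_train)) < 2L) {
    warning("single-class training labels; skipping ", family, " fit")
    return(NULL)
  }
  aucs <- numeric(nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- fit_one(family, X_train, y_train, grid[i, , drop = FALSE], seed)
    s <- predict_one(family, fits[[i]], X_val)
    aucs[i] <- if (length(unique(y_val)) > 1L) auc(s, y_val) else NA_real_
  }
  best <- if (all(is.na(aucs))) 1L else which.max(aucs)  # which.max: first tie
  structure(list(family = family, model = fits[[best]],
                 chosen = grid[best, , drop = FALSE],
                 val_auc = aucs[best], grid_aucs = aucs, seed = seed),
            class = "stablerx_classifier")
}

#' Predicted stability probabilities from a fitted classifier
#' @param fit a `stablerx_classifier`.
#' @param X feature matrix.
#' @return named numeric vector (rownames of `X` carried over).
#' @export
predict_classifier <- function(fit, X) {
  p <- predict_one(fit$family, fit$model, X)
  names(p) <- rownames(X)
  p
}

registry_key <- function(family, feature_set, target) {
  paste(family, feature_set, target, sep = "|")
}

#' Train the full model registry
#'
#' One general-stability classifier plus one drug-specific classifier per
#' target drug, for every requested (family, feature set) combination.
#' Drug-specific fits use only patients with a known outcome for that drug;
#' a target with a single class in training is skipped with a warning.
#'
#' @param feature_sets named list: feature-set name -> list(`train`,
#'   `validation`) of matrices with patient-id rownames.
#' @param general named logical vector (patient id -> general stability)
#'   covering train and validation patients.
#' @param per_drug long data.frame (patient_id, drug_name, stable) of known
#'   outcomes covering train and validation patients.
#' @param target_drugs drugs requiring drug-specific models.
#' @param families classifier families per feature set; a named list
#'   (feature set -> character vector) or a character vector applied to all.
#' @param seed integer seed.
#' @param grids optional named list (family -> grid) overriding
#'   [default_grid()].
#' @return a `stablerx_registry`: list with `models` (keyed
#'   `family|feature_set|target`), `target_drugs`, `skipped`.
#' @export
train_all_models <- function(feature_sets, general, per_drug, target_drugs,
                             families = c("logistic", "extra_trees"),
                             seed = 1L, grids = NULL) {
  models <- list(); skipped <- character(0)
  for (fs in names(feature_sets)) {
    fam_fs <- if (is.list(families)) families[[fs]] else families
    Xtr <- feature_sets[[fs]]$train
    Xva <- feature_sets[[fs]]$validation
    for (family in fam_fs) {
      grid <- if (!is.null(grids) && family %in% names(grids)) grids[[family]]
              else default_grid(family)
      targets <- c("general", target_drugs)
      for (target in targets) {
        if (target == "general") {
          tr_ids <- rownames(Xtr); va_ids <- rownames(Xva)
          ytr <- general[tr_ids]; yva <- general[va_ids]
        } else {
          kn <- per_drug[per_drug$drug_name == target, , drop = FALSE]
          lab <- stats::setNames(kn$stable, kn$patient_id)
          tr_ids <- intersect(rownames(Xtr), kn$patient_id)
          va_ids <- intersect(rownames(Xva), kn$patient_id)
          ytr <- lab[tr_ids]; yva <- lab[va_ids]
        }
        fit <- train_classifier(family, Xtr[tr_ids, , drop = FALSE], ytr,
                                Xva[va_ids, , drop = FALSE], yva,
                                grid = grid, seed = seed)
        key <- registry_key(family, fs, target)
        if (is.null(fit)) skipped <- c(skipped, key) else models[[key]] <- fit
      }
    }
  }
  structure(list(models = models, target_drugs = target_drugs,
                 skipped = skipped, seed = seed),
            class = "stablerx_registry")
}

#' Look up a model in the registry
#' @param registry a `stablerx_registry`.
#' @param family,feature_set,target model coordinates.
#' @export
get_model <- function(registry, family, feature_set, target = "general") {
  registry$models[[registry_key(family, feature_set, target)]]
}

#' Per-drug probability matrix from a registry
#'
#' @param registry a `stablerx_registry`.
#' @param family,feature_set model coordinates.
#' @param X feature matrix for the evaluation patients.
#' @return patients x drugs matrix of predicted stability probabilities;
#'   drugs whose model was skipped give NA columns.
#' @export
predict_per_drug <- function(registry, family, feature_set, X) {
  drugs <- registry$target_drugs
  out <- matrix(NA_real_, nrow(X), length(drugs),
                dimnames = list(rownames(X), drugs))
  for (dr in drugs) {
    fit <- get_model(registry, family, feature_set, dr)
    if (!is.null(fit)) out[, dr] <- predict_classifier(fit, X)
  }
  out
}

#' Save / load a model registry
#'
#' Runtime serialization of fitted model objects (RDS); intended for run
#' directories, not for distribution.
#' @param registry a `stablerx_registry`.
#' @param path file path.
#' @export
save_registry <- function(registry, path) {
  saveRDS(registry, path)
  invisible(path)
}

#' @rdname save_registry
#' @export
load_registry <- function(path) readRDS(path)
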