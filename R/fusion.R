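## Combined imaging + serum model: VIF multicollinearity screening with a
## univariable-logistic |beta| representative rule, Select-From-Model feature
## selection by random-forest Gini importance, and a grid-searched random
## forest fitted with stratified fivefold cross-validation.

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the least-squares
#' regression (with intercept) of feature j on all other features. Exact
#' linear dependence is reported as `Inf`.
#'
#' @param X numeric matrix or data.frame of features (>= 2 columns, n > p)
#' @return `vif_report` list: `vif` (named), `flagged` (VIF > 5)
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X)
  if (p < 2) stop("VIF needs at least 2 features")
  if (n <= p) stop("VIF needs n > p")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  vif <- vapply(seq_len(p), function(j) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    fit <- lm.fit(Zj, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss <= 0) return(Inf)              # constant feature
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(vif) <- colnames(X)
  structure(list(vif = vif, flagged = names(vif)[vif > 5]),
            class = "vif_report")
}

## standardized univariable logistic slope |beta| per feature
.univariable_beta <- function(X, labels) {
  vapply(colnames(X), function(nm) {
    x <- X[, nm]
    s <- sd(x)
    if (s == 0) return(0)
    z <- (x - mean(x)) / s
    fit <- suppressWarnings(glm(labels ~ z, family = binomial()))
    b <- coef(fit)[2]
    ## perfect separation: slope diverges, fitted probabilities degenerate
    if (!fit$converged || any(abs(fit$fitted.values - labels) < 1e-8) &&
        abs(b) > 10) return(Inf)
    abs(b)
  }, 0)
}

#' Resolve multicollinearity by VIF and univariable logistic |beta|
#'
#' While any VIF exceeds `threshold`: among the flagged features, groups are
#' the connected components of pairwise |r| >= 0.7; within each group the
#' feature with the largest standardized univariable logistic |beta| is
#' kept and the rest dropped, then VIFs are recomputed. Idempotent; every
#' action is recorded.
#'
#' @param X feature matrix/data.frame
#' @param labels 0/1 labels (both classes present)
#' @param threshold VIF threshold (default 5)
#' @return list: `X` (reduced), `report` (`vif_report` with `dropped`,
#'   `kept_representative`, `steps`, and the initial + final VIFs)
#' @export
resolve_collinearity <- function(X, labels, threshold = 5) {
  .check_binary(labels)
  X <- as.data.frame(X)
  initial <- compute_vif(X)
  dropped <- character(0)
  kept <- list()
  steps <- list()
  repeat {
    rep_now <- compute_vif(X)
    flagged <- rep_now$vif[rep_now$vif > threshold]
    if (!length(flagged)) break
    fl <- names(flagged)
    ## connected components of |r| >= 0.7 among flagged features
    R <- abs(suppressWarnings(stats::cor(as.matrix(X[, fl, drop = FALSE]))))
    R[is.na(R)] <- 1                       # duplicated/constant columns
    comp <- rep(NA_integer_, length(fl))
    cid <- 0
    for (i in seq_along(fl)) {
      if (!is.na(comp[i])) next
      cid <- cid + 1
      queue <- i
      while (length(queue)) {
        k <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[k])) next
        comp[k] <- cid
        queue <- c(queue, which(R[k, ] >= 0.7 & is.na(comp)))
      }
    }
    beta <- .univariable_beta(as.matrix(X[, fl, drop = FALSE]), labels)
    changed <- FALSE
    for (g in unique(comp)) {
      members <- fl[comp == g]
      if (length(members) < 2) next        # isolated high-VIF feature stays
      rep_feat <- members[which.max(beta[members])]
      losers <- setdiff(members, rep_feat)
      X <- X[, setdiff(names(X), losers), drop = FALSE]
      dropped <- c(dropped, losers)
      kept[[rep_feat]] <- beta[members]
      steps[[length(steps) + 1]] <- list(group = members, kept = rep_feat,
                                         beta = beta[members])
      changed <- TRUE
    }
    if (!changed) break                    # no reducible group left
    if (ncol(X) < 2) break
  }
  final <- if (ncol(X) >= 2) compute_vif(X) else NULL
  report <- structure(
    list(vif = initial$vif, flagged = initial$flagged, dropped = dropped,
         kept_representative = kept, steps = steps,
         vif_after = if (is.null(final)) NULL else final$vif),
    class = "vif_report")
  list(X = X, report = report)
}

#' Select-From-Model feature selection by Gini importance
#'
#' Fits a random forest and retains the features whose Gini importance
#' (mean decrease impurity, normalized to sum 1) exceeds the mean
#' importance across features - the conventional Select-From-Model default.
#'
#' @param X feature matrix/data.frame
#' @param labels 0/1 labels
#' @param seed forest seed
#' @param ntree trees
#' @param max_depth depth cap (0 = unlimited)
#' @param min_leaf minimum leaf size
#' @return list: `selected` (names), `importance` (named, sums to 1),
#'   `threshold` (the mean)
#' @export
select_features_gini <- function(X, labels, seed = 1, ntree = 300,
                                 max_depth = 0, min_leaf = 1) {
  X <- as.matrix(X)
  fit <- rf_fit(X, as.integer(labels), as.integer(ntree), -1L,
                as.integer(max_depth), as.integer(min_leaf), as.integer(seed))
  imp <- rf_importance(fit)
  names(imp) <- colnames(X)
  thr <- mean(imp)
  sel <- names(imp)[imp > thr]
  if (!length(sel)) {
    warning("all importances tied at the mean; retaining every feature")
    sel <- names(imp)
  }
  list(selected = sel, importance = imp, threshold = thr)
}

#' Default random-forest hyperparameter grid
#'
#' Trees x max depth (0 = unlimited) x minimum leaf size. The published
#' pipeline states only that a grid search was used.
#' @return data.frame grid
#' @export
default_rf_grid <- function() {
  expand.grid(ntree = c(100, 300, 500), max_depth = c(3, 5, 0),
              min_leaf = c(1, 5))
}

#' Fit the combined model
#'
#' Stratified fivefold cross-validation; within each fold the forest
#' hyperparameters are chosen by an inner 3-fold grid search on AUC, the
#' forest is fitted on the fold-training cases, and the held-out cases get
#' their out-of-fold probability. New-case prediction averages the five
#' fold forests. The operating cutoff is the Youden cutoff on the pooled
#' out-of-fold probabilities.
#'
#' @param X feature matrix/data.frame (e.g. cnn_prob + clinical panel)
#' @param labels 0/1 labels
#' @param grid hyperparameter data.frame (columns ntree, max_depth,
#'   min_leaf)
#' @param folds outer folds
#' @param seed seed for fold assignment and forests
#' @param inner_folds folds of the inner grid-search CV
#' @return `combined_model`: `folds` (exported forests), `oof_prob`,
#'   `best_hyperparams` per fold, `selected_features`, `importances`,
#'   `training_cutoff`
#' @export
fit_combined <- function(X, labels, grid = default_rf_grid(), folds = 5,
                         seed = 1, inner_folds = 3) {
  .check_binary(labels)
  X <- as.matrix(as.data.frame(X))
  if (!nrow(grid)) stop("hyperparameter grid is empty")
  n <- nrow(X)
  fold <- stratified_folds(labels, folds, derive_seed(seed, 31))
  oof <- rep(NA_real_, n)
  fold_models <- vector("list", folds)
  best_hp <- vector("list", folds)
  importances <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); va <- which(fold == f)
    if (length(unique(labels[tr])) < 2 || length(unique(labels[va])) < 2)
      stop("single-class fold; choose fewer folds or more cases")
    ## inner grid search
    if (nrow(grid) > 1) {
      inner <- stratified_folds(labels[tr], inner_folds, derive_seed(seed, 100 + f))
      cvauc <- vapply(seq_len(nrow(grid)), function(g) {
        aucs <- vapply(seq_len(inner_folds), function(k) {
          itr <- tr[inner != k]; iva <- tr[inner == k]
          if (length(unique(labels[iva])) < 2) return(NA_real_)
          fit <- rf_fit(X[itr, , drop = FALSE], as.integer(labels[itr]),
                        as.integer(grid$ntree[g]), -1L,
                        as.integer(grid$max_depth[g]),
                        as.integer(grid$min_leaf[g]),
                        derive_seed(seed, 1000 + f * 10 + k))
          roc_auc(rf_predict(fit, X[iva, , drop = FALSE]), labels[iva])$auc
        }, 0)
        mean(aucs, na.rm = TRUE)
      }, 0)
      gbest <- which.max(cvauc)
    } else gbest <- 1L
    best_hp[[f]] <- grid[gbest, , drop = FALSE]
    fit <- rf_fit(X[tr, , drop = FALSE], as.integer(labels[tr]),
                  as.integer(grid$ntree[gbest]), -1L,
                  as.integer(grid$max_depth[gbest]),
                  as.integer(grid$min_leaf[gbest]),
                  derive_seed(seed, 2000 + f))
    oof[va] <- rf_predict(fit, X[va, , drop = FALSE])
    imp <- rf_importance(fit)
    names(imp) <- colnames(X)
    importances[[f]] <- imp
    fold_models[[f]] <- rf_export(fit)
  }
  cutoff <- youden_cutoff(roc_auc(oof, labels))
  structure(list(folds = fold_models, oof_prob = oof, fold_id = fold,
                 labels = labels, best_hyperparams = best_hp,
                 selected_features = colnames(X), importances = importances,
                 training_cutoff = cutoff),
            class = "combined_model")
}

#' Predict with the combined model
#' @param model `combined_model`
#' @param X feature matrix with the model's `selected_features` columns
#' @return mean probability over the five fold forests
#' @export
predict_combined <- function(model, X) {
  X <- as.matrix(as.data.frame(X)[, model$selected_features, drop = FALSE])
  probs <- lapply(model$folds, function(fm) rf_predict(rf_import(fm), X))
  Reduce(`+`, probs) / length(probs)
}

#' Build the full combined model from features
#'
#' The complete published recipe: VIF screening (threshold 5) with the
#' univariable-|beta| representative rule, Select-From-Model by Gini
#' importance, then the grid-searched cross-validated forest on the
#' selected features.
#'
#' @inheritParams fit_combined
#' @return `combined_model` with `vif_report` and `selection` attached
#' @export
build_combined_model <- function(X, labels, grid = default_rf_grid(),
                                 folds = 5, seed = 1) {
  rc <- resolve_collinearity(X, labels)
  sel <- select_features_gini(rc$X, labels, seed = derive_seed(seed, 7))
  Xs <- as.data.frame(rc$X)[, sel$selected, drop = FALSE]
  model <- fit_combined(Xs, labels, grid = grid, folds = folds, seed = seed)
  model$vif_report <- rc$report
  model$selection <- sel
  model
}
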