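# Independent oracles used across test files. Each is a deliberately naive
# implementation (full enumeration / brute force) kept separate from the
# package's own code paths.

# AUC by exhaustive pair counting, ties 1/2
oracle_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# DeLong variance of a single AUC via the full psi matrix
oracle_delong_var <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi); v01 <- colMeans(psi)
  var(v10) / m + var(v01) / n
}

# paired DeLong z statistic via full psi matrices
oracle_delong_z <- function(sa, sb, labels) {
  comp <- function(s) {
    x <- s[labels == 1]; y <- s[labels == 0]
    psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
         m = length(x), n = length(y))
  }
  a <- comp(sa); b <- comp(sb)
  vr <- var(a$v10 - b$v10) / a$m + var(a$v01 - b$v01) / a$n
  (a$auc - b$auc) / sqrt(vr)
}

# brute-force Youden scan over observed thresholds (positive iff >= t)
oracle_youden <- function(scores, labels) {
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
  }, 0)
  list(threshold = max(thr[j >= max(j) - 1e-12]), j = max(j))
}

# VIF via explicit normal equations
oracle_vif <- function(X) {
  X <- as.matrix(X)
  vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    beta <- solve(t(Z) %*% Z, t(Z) %*% yj)
    res <- yj - Z %*% beta
    r2 <- 1 - sum(res^2) / sum((yj - mean(yj))^2)
    1 / (1 - r2)
  }, 0)
}

# tiny deterministic phantom study cache (shared across test files)
.fixture_env <- new.env(parent = emptyenv())

fixture_study <- function(label = 1, seed = 5) {
  key <- paste0("study_", label, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    p <- phantom_params(n_cases = 2, seed = seed)
    .fixture_env[[key]] <- generate_volume(label, p, seed = seed,
                                           case_id = paste0("fx", label))
  }
  .fixture_env[[key]]
}

# small strong-signal trained fold (cached): 32-px packs, n = 90
fixture_trained <- function() {
  if (is.null(.fixture_env$trained)) {
    params <- phantom_params(n_cases = 90, prevalence = 0.5,
                             nodularity_amp = 0.15, seed = 401)
    cases <- generate_cohort(params)
    labels <- vapply(cases, `[[`, 0L, "label")
    packs <- lapply(cases, function(cs)
      preprocess_stack(register_study(cs$study), size = 32))
    ## liver+spleen region of the center slice, in pack geometry
    regions <- lapply(cases, function(cs) {
      st <- cs$study
      z <- select_slices(st$mask)[3]
      reg <- (st$mask[z, , ] + st$spleen[z, , ]) > 0
      resize2d(reg * 1, 32, 32, method = "nearest")
    })
    set.seed(402)
    va <- c(sample(which(labels == 1), 12), sample(which(labels == 0), 12))
    tr <- setdiff(seq_along(labels), va)
    cfg <- cnn_config(profile = "ci", seed = 403)
    cfg$image_size <- 32L
    cfg$max_epochs <- 25L
    cfg$early_stop_patience <- 8L
    fr <- train_fold(packs, labels, tr, va, cfg)
    .fixture_env$trained <- list(fold = fr, packs = packs, labels = labels,
                                 regions = regions, train_idx = tr, val_idx = va)
  }
  .fixture_env$trained
}
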