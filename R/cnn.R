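## ResNet-18 slice-stack classifier: model construction, fold training with
## Adam + plateau LR schedule + best-AUC checkpointing, stratified fivefold
## cross-validation with out-of-fold probabilities, ensemble prediction by
## probability averaging, and Grad-CAM activation maps.

#' Training configuration for the CNN
#'
#' Defaults mirror the published training recipe (Adam, initial LR 1e-3,
#' weight decay 1e-5, batch size 32, dropout 0.3, up to 500 epochs with
#' early stopping on validation AUC, LR halved on an AUC plateau). The
#' plateau/early-stop patiences are not published; the defaults here are
#' conventional and configurable. `profile = "ci"` is the desk-scale
#' profile used by the test suite (64-px inputs, at most 60 epochs).
#'
#' @param lr initial learning rate
#' @param weight_decay L2 penalty added to the Adam gradient
#' @param batch_size minibatch size
#' @param dropout dropout rate before the 1-unit head
#' @param max_epochs epoch cap
#' @param early_stop_patience epochs without validation-AUC improvement
#'   before stopping
#' @param lr_factor,lr_patience,min_lr ReduceLROnPlateau parameters (on
#'   validation AUC)
#' @param folds cross-validation folds
#' @param image_size input H = W in pixels
#' @param sequences sequences stacked as input (default pre-contrast T1 +
#'   T2, the published final model)
#' @param augment `augment_config()` or `NULL` to disable online
#'   augmentation
#' @param seed integer seed (fold assignment, init, shuffling, dropout)
#' @param profile `"parity"` (published scale) or `"ci"` (desk scale)
#' @return `train_config` list
#' @export
cnn_config <- function(lr = 1e-3, weight_decay = 1e-5, batch_size = 32,
                       dropout = 0.3, max_epochs = 500,
                       early_stop_patience = 30, lr_factor = 0.5,
                       lr_patience = 10, min_lr = 1e-6, folds = 5,
                       image_size = 512, sequences = c("T1pre", "T2"),
                       augment = NULL, seed = 1,
                       profile = c("parity", "ci")) {
  profile <- match.arg(profile)
  if (profile == "ci") {
    image_size <- 64; max_epochs <- 60
    early_stop_patience <- 10; lr_patience <- 5
  }
  stopifnot(lr > 0, folds >= 2, batch_size >= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 min_lr = min_lr, folds = as.integer(folds),
                 image_size = as.integer(image_size), sequences = sequences,
                 augment = augment, seed = as.integer(seed),
                 profile = profile),
            class = "train_config")
}

#' Build a ResNet-18 binary classifier
#'
#' Standard ResNet-18 topology (7x7 stem, 3x3 max-pool, four stages of two
#' basic blocks, global average pooling) with the first convolution widened
#' to `in_channels`, dropout before a single-logit head, and sigmoid output.
#'
#' @param in_channels input channels (sequences x 5 slices x image+mask)
#' @param dropout dropout rate
#' @param seed init seed
#' @return `resnet18` handle
#' @export
build_model <- function(in_channels, dropout = 0.3, seed = 1) {
  stopifnot(in_channels >= 1)
  structure(list(ptr = nn_create(as.integer(in_channels), dropout,
                                 as.integer(seed)),
                 in_channels = as.integer(in_channels), dropout = dropout),
            class = "resnet18")
}

#' Number of trainable parameters
#' @param model `resnet18`
#' @return parameter count
#' @export
n_parameters <- function(model) nn_param_count(model$ptr)

## A ResNet-18 instance costs ~180 MB (parameters + Adam state + grads), so
## prediction paths reuse one cached net per (in_channels, dropout) instead
## of instantiating a fresh one per fold model.
.net_cache <- new.env(parent = emptyenv())

.net_for <- function(in_channels, dropout) {
  key <- sprintf("c%d_d%g", in_channels, dropout)
  if (is.null(.net_cache[[key]]))
    .net_cache[[key]] <- build_model(in_channels, dropout, seed = 1)
  .net_cache[[key]]
}

## packs (list of slice_pack) -> flat vector in the engine's layout
.packs_to_vec <- function(packs) {
  unlist(lapply(packs, function(p) as.numeric(aperm(p$slices, c(3, 2, 1)))),
         use.names = FALSE)
}

.pack_dims <- function(packs) {
  d <- dim(packs[[1]]$slices)
  c(length(packs), d[1], d[2], d[3])
}

#' Upload slice packs to the training engine
#' @param packs list of `slice_pack` with identical channel layout
#' @return opaque dataset handle
#' @export
cnn_dataset <- function(packs) {
  dims <- .pack_dims(packs)
  structure(list(ptr = nn_data(.packs_to_vec(packs), as.integer(dims)),
                 n = dims[1], channels = dims[2], size = dims[3],
                 channel_names = packs[[1]]$channels),
            class = "cnn_dataset")
}

#' Predict probabilities with a single model
#' @param model `resnet18`
#' @param packs list of `slice_pack`
#' @return numeric probabilities
#' @export
model_predict <- function(model, packs) {
  dims <- .pack_dims(packs)
  if (dims[2] != model$in_channels)
    stop("channel mismatch: model expects ", model$in_channels,
         " channels, packs have ", dims[2])
  nn_predict_raw(model$ptr, .packs_to_vec(packs), as.integer(dims))
}

#' Train one cross-validation fold
#'
#' Adam with BCE loss; LR multiplied by `lr_factor` after `lr_patience`
#' epochs without validation-AUC improvement; training stops at
#' `max_epochs` or after `early_stop_patience` stale epochs; the weights of
#' the best-validation-AUC epoch are retained.
#'
#' @param data `cnn_dataset` (or list of packs)
#' @param labels 0/1 per case in `data`
#' @param train_idx,val_idx disjoint 1-based case indices
#' @param config [cnn_config()]
#' @param model optional pre-built `resnet18` (a fresh one is created
#'   otherwise)
#' @return `fold_result`: `weights`, `best_val_auc`, `epoch_of_best`,
#'   `trace` (per-epoch loss/val AUC/LR), `train_idx`, `val_idx`
#' @export
train_fold <- function(data, labels, train_idx, val_idx, config = cnn_config(),
                       model = NULL) {
  if (inherits(data, "cnn_dataset")) ds <- data
  else if (is.null(config$augment)) ds <- cnn_dataset(data)
  else ds <- cnn_dataset_packs(data)
  if (length(intersect(train_idx, val_idx)))
    stop("train and validation sets must be disjoint")
  if (length(unique(labels[val_idx])) < 2)
    stop("validation fold contains a single class; AUC undefined")
  if (length(unique(labels[train_idx])) < 2)
    stop("training fold contains a single class")
  if (is.null(model))
    model <- build_model(ds$channels, config$dropout, config$seed)

  if (is.null(config$augment)) {
    res <- nn_train(model$ptr, ds$ptr, as.numeric(labels),
                    as.integer(train_idx), as.integer(val_idx),
                    list(lr = config$lr, weight_decay = config$weight_decay,
                         batch_size = config$batch_size,
                         max_epochs = config$max_epochs,
                         lr_factor = config$lr_factor,
                         lr_patience = config$lr_patience,
                         min_lr = config$min_lr,
                         early_stop_patience = config$early_stop_patience,
                         seed = config$seed))
  } else {
    res <- .train_fold_augmented(model, ds, labels, train_idx, val_idx, config)
  }
  structure(list(weights = nn_get_weights(model$ptr),
                 in_channels = ds$channels, dropout = config$dropout,
                 best_val_auc = res$best_val_auc,
                 epoch_of_best = res$epoch_of_best,
                 trace = data.frame(epoch = seq_along(res$loss),
                                    loss = res$loss, val_auc = res$val_auc,
                                    lr = res$lr),
                 train_idx = train_idx, val_idx = val_idx),
            class = "fold_result")
}

## R-side epoch loop used only when online augmentation is enabled: batches
## are augmented, uploaded per step, and the plateau/early-stop logic runs
## here. Slower than the in-engine loop; intended for the parity profile.
.train_fold_augmented <- function(model, ds, labels, train_idx, val_idx, config) {
  packs <- attr(ds, "packs")
  if (is.null(packs)) stop("augmented training needs the original packs; ",
                           "build the dataset with cnn_dataset_packs()")
  lr <- config$lr
  best <- list(auc = -Inf, epoch = 0, weights = NULL)
  since_best <- 0; lr_since <- 0
  loss_hist <- auc_hist <- lr_hist <- numeric(0)
  aug_seed <- derive_seed(config$seed, 77)
  for (epoch in seq_len(config$max_epochs)) {
    set.seed(derive_seed(config$seed, epoch))
    ord <- sample(train_idx)
    ep_loss <- 0; nb <- 0
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[b0:min(length(ord), b0 + config$batch_size - 1)]
      if (length(idx) < 2) next
      aug <- lapply(seq_along(idx), function(k)
        augment(packs[[idx[k]]], config$augment,
                derive_seed(aug_seed, epoch * 100000 + b0 * 100 + k)))
      dims <- .pack_dims(aug)
      ep_loss <- ep_loss + nn_step(model$ptr, .packs_to_vec(aug),
                                   as.integer(dims),
                                   as.numeric(labels[idx]), lr,
                                   config$weight_decay)
      nb <- nb + 1
    }
    pv <- nn_predict(model$ptr, ds$ptr, as.integer(val_idx))
    va <- roc_auc(pv, labels[val_idx])$auc
    loss_hist <- c(loss_hist, ep_loss / max(1, nb))
    auc_hist <- c(auc_hist, va)
    lr_hist <- c(lr_hist, lr)
    if (va > best$auc + 1e-6) {
      best <- list(auc = va, epoch = epoch, weights = nn_get_weights(model$ptr))
      since_best <- 0; lr_since <- 0
    } else {
      since_best <- since_best + 1; lr_since <- lr_since + 1
    }
    if (lr_since >= config$lr_patience) {
      lr <- max(config$min_lr, lr * config$lr_factor); lr_since <- 0
    }
    if (since_best >= config$early_stop_patience) break
  }
  if (!is.null(best$weights)) nn_set_weights(model$ptr, best$weights)
  list(best_val_auc = best$auc, epoch_of_best = best$epoch,
       loss = loss_hist, val_auc = auc_hist, lr = lr_hist)
}

#' Upload packs keeping them attached (needed for augmented training)
#' @param packs list of `slice_pack`
#' @return `cnn_dataset` with the packs attached
#' @export
cnn_dataset_packs <- function(packs) {
  ds <- cnn_dataset(packs)
  attr(ds, "packs") <- packs
  ds
}

#' Stratified fold assignment
#' @param labels 0/1 labels
#' @param folds number of folds
#' @param seed shuffle seed
#' @return integer fold id (1..folds) per case
#' @export
stratified_folds <- function(labels, folds = 5, seed = 1) {
  if (length(labels) < folds) stop("fewer cases than folds")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ids <- which(labels == cl)
    ids <- ids[sample.int(length(ids))]
    fold[ids] <- rep(seq_len(folds), length.out = length(ids))
  }
  fold
}

#' Fivefold cross-validated CNN training
#'
#' Stratified fold assignment by label with `config$seed`; each fold trains
#' on the remaining folds and validates on its own cases, storing the
#' best-epoch weights and the out-of-fold probability of every case.
#'
#' @param data `cnn_dataset` (or list of packs)
#' @param labels 0/1 per case
#' @param config [cnn_config()]
#' @param case_ids optional ids recorded in the fold results
#' @param verbose print per-fold progress
#' @return `cnn_ensemble`: `folds` (list of `fold_result`), `oof_prob`,
#'   `fold_id`, `config`
#' @export
crossval_train <- function(data, labels, config = cnn_config(), case_ids = NULL,
                           verbose = FALSE) {
  if (inherits(data, "cnn_dataset")) ds <- data else ds <- cnn_dataset_packs(data)
  if (length(unique(labels)) < 2) stop("cohort must contain both classes")
  n <- ds$n
  if (n < config$folds) stop("fewer cases than folds")
  fold <- stratified_folds(labels, config$folds, config$seed)
  oof <- rep(NA_real_, n)
  folds <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    tr <- which(fold != f); va <- which(fold == f)
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, f)
    fr <- train_fold(ds, labels, tr, va, cfg_f)
    fr$fold_id <- f
    if (!is.null(case_ids)) {
      fr$train_case_ids <- case_ids[tr]
      fr$val_case_ids <- case_ids[va]
    }
    ## out-of-fold probabilities from the retained best weights
    mdl <- .net_for(ds$channels, config$dropout)
    nn_set_weights(mdl$ptr, fr$weights)
    oof[va] <- nn_predict(mdl$ptr, ds$ptr, as.integer(va))
    folds[[f]] <- fr
    gc(verbose = FALSE)                  # release the fold's training net
    if (verbose)
      message(sprintf("fold %d: best val AUC %.3f (epoch %d)",
                      f, fr$best_val_auc, fr$epoch_of_best))
  }
  structure(list(folds = folds, oof_prob = oof, fold_id = fold,
                 labels = labels, config = config, channels = ds$channels),
            class = "cnn_ensemble")
}

#' Ensemble probability for new cases
#'
#' Arithmetic mean of the five fold models' sigmoid outputs.
#'
#' @param ensemble `cnn_ensemble`
#' @param packs list of `slice_pack` (or a `cnn_dataset`)
#' @return numeric probabilities
#' @export
predict_proba <- function(ensemble, packs) {
  if (inherits(packs, "cnn_dataset")) {
    ds <- packs
    idx <- seq_len(ds$n)
    get <- function(mdl) nn_predict(mdl$ptr, ds$ptr, as.integer(idx))
    channels <- ds$channels
  } else {
    dims <- .pack_dims(packs)
    channels <- dims[2]
    vec <- .packs_to_vec(packs)
    get <- function(mdl) nn_predict_raw(mdl$ptr, vec, as.integer(dims))
  }
  if (channels != ensemble$channels)
    stop("channel mismatch: ensemble expects ", ensemble$channels,
         " channels, input has ", channels)
  mdl <- .net_for(ensemble$channels, ensemble$config$dropout)
  probs <- lapply(ensemble$folds, function(fr) {
    nn_set_weights(mdl$ptr, fr$weights)
    get(mdl)
  })
  Reduce(`+`, probs) / length(probs)
}

#' Grad-CAM activation map for one slice pack
#'
#' Channel weights are the spatially averaged gradients of the cirrhosis
#' logit at the chosen stage; the ReLU of the weighted feature-map sum is
#' bilinearly upsampled to the input size. Values are >= 0; `heat_norm`
#' rescales the maximum to 1 for display (all-zero maps trigger a warning).
#'
#' @param fold `fold_result` (or `resnet18` model)
#' @param pack `slice_pack`
#' @param stage convolutional stage 1-4 (default 4, the last)
#' @return `activation_map`: `heat` (H x W), `heat_norm`, `prob`, `stage`
#' @export
gradcam <- function(fold, pack, stage = 4) {
  if (inherits(fold, "fold_result")) {
    mdl <- .net_for(fold$in_channels, fold$dropout)
    nn_set_weights(mdl$ptr, fold$weights)
  } else mdl <- fold
  dims <- .pack_dims(list(pack))
  res <- nn_gradcam(mdl$ptr, .packs_to_vec(list(pack)), as.integer(dims),
                    as.integer(stage))
  hm <- matrix(res$heat, res$h, res$w, byrow = TRUE)  # row = y
  heat <- resize2d(hm, dims[3], dims[4])
  heat[heat < 0] <- 0
  mx <- max(heat)
  if (mx <= 0) {
    warning("zero gradient everywhere: all-zero activation map")
    hn <- heat
  } else hn <- heat / mx
  structure(list(heat = heat, heat_norm = hn, prob = res$prob,
                 stage = stage, target_class = "cirrhosis"),
            class = "activation_map")
}
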