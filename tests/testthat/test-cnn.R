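ns <- asNamespace("hepascan")

random_pack <- function(channels = 4, size = 16, seed = 1) {
  set.seed(seed)
  p <- list(slices = array(runif(channels * size * size),
                           c(channels, size, size)),
            slice_indices = 1:5, size = size,
            channels = c(paste0("T1pre.s", 1:(channels / 2), ".image"),
                         paste0("T1pre.s", 1:(channels / 2), ".mask")),
            sequences = "T1pre")
  class(p) <- "slice_pack"
  p
}

test_that("build_model: output range, parameter count, zeroed head", {
  m <- build_model(4, dropout = 0.3, seed = 1)
  pk <- random_pack(4, 16)
  pr <- model_predict(m, list(pk))
  expect_length(pr, 1)
  expect_true(pr >= 0 && pr <= 1)

  # parameter count against the layer-by-layer arithmetic of the published
  # 18-layer architecture with a 1-unit head (in_channels = 3)
  conv <- function(cin, cout, k) cin * cout * k * k
  bn <- function(c) 2 * c
  blk <- function(cin, cout, down) {
    n <- conv(cin, cout, 3) + bn(cout) + conv(cout, cout, 3) + bn(cout)
    if (down) n <- n + conv(cin, cout, 1) + bn(cout)
    n
  }
  expected <- conv(3, 64, 7) + bn(64) +
    blk(64, 64, FALSE) + blk(64, 64, FALSE) +
    blk(64, 128, TRUE) + blk(128, 128, FALSE) +
    blk(128, 256, TRUE) + blk(256, 256, FALSE) +
    blk(256, 512, TRUE) + blk(512, 512, FALSE) +
    512 + 1
  m3 <- build_model(3, seed = 1)
  expect_equal(n_parameters(m3), expected)
  expect_equal(expected, 11177025)   # standard count with a 1-unit head

  # zeroed head -> sigmoid(0) = 0.5 for any input
  w <- ns$nn_get_weights(m$ptr)
  w$fc.weight[] <- 0; w$fc.bias[] <- 0
  ns$nn_set_weights(m$ptr, w)
  expect_equal(model_predict(m, list(pk)), 0.5, tolerance = 1e-7)
})

test_that("analytic gradients match directional finite differences", {
  net <- ns$nn_create(2L, 0.0, 42L)
  set.seed(1)
  B <- 4L; C <- 2L; H <- 16L
  x <- runif(B * C * H * H); y <- c(1, 0, 1, 0)
  dims <- c(B, C, H, H)
  invisible(ns$nn_loss_backward(net, x, dims, y, TRUE))
  g <- ns$nn_get_grads(net)
  w <- ns$nn_get_weights(net)
  set.seed(2)
  # layers whose finite-difference path avoids the max-pool kinks; float32
  # forward noise bounds what a difference quotient can resolve, hence the
  # absolute fallback for small-gradient tensors
  for (nm in c("fc.weight", "fc.bias", "layer4.1.conv2", "layer4.0.conv1",
               "layer3.0.conv2", "layer3.0.bn2.gamma", "layer2.1.conv2")) {
    u <- array(rnorm(length(w[[nm]])), dim(as.matrix(w[[nm]])))
    u <- u / sqrt(sum(u^2))
    h <- 2e-3
    w2 <- w; w2[[nm]] <- w[[nm]] + h * u
    ns$nn_set_weights(net, w2)
    lp <- ns$nn_loss_backward(net, x, dims, y, FALSE)
    w2[[nm]] <- w[[nm]] - h * u
    ns$nn_set_weights(net, w2)
    lm <- ns$nn_loss_backward(net, x, dims, y, FALSE)
    fd <- (lp - lm) / (2 * h)
    an <- sum(u * g[[nm]])
    expect_true(abs(fd - an) < 0.1 * max(abs(fd), abs(an)) ||
                  abs(fd - an) < 2e-3,
                label = sprintf("%s: fd=%.5g an=%.5g", nm, fd, an))
    ns$nn_set_weights(net, w)
  }
})

test_that("stratified folds: counts, partition, determinism", {
  labels <- rep(c(1, 0), c(60, 40))
  f1 <- stratified_folds(labels, 5, seed = 3)
  for (k in 1:5) {
    expect_equal(sum(labels == 1 & f1 == k), 12)
    expect_equal(sum(f1 == k), 20)
  }
  expect_equal(sort(unique(f1)), 1:5)
  f2 <- stratified_folds(labels, 5, seed = 3)
  expect_identical(f1, f2)
  f3 <- stratified_folds(labels, 5, seed = 4)
  expect_false(identical(f1, f3))
  expect_error(stratified_folds(c(0, 1, 1), 5), "fewer cases")
})

test_that("ensemble probability is the fold mean and fold-order invariant", {
  packs <- lapply(1:3, function(s) random_pack(4, 16, seed = s))
  folds <- lapply(1:5, function(s) {
    m <- build_model(4, dropout = 0.3, seed = 10 + s)
    structure(list(weights = ns$nn_get_weights(m$ptr), in_channels = 4L,
                   dropout = 0.3, fold_id = s), class = "fold_result")
  })
  ens <- structure(list(folds = folds, config = cnn_config(profile = "ci"),
                        channels = 4L), class = "cnn_ensemble")
  p <- predict_proba(ens, packs)
  expect_true(all(p >= 0 & p <= 1))
  m <- build_model(4, dropout = 0.3, seed = 1)
  indiv <- sapply(folds, function(fr) {
    ns$nn_set_weights(m$ptr, fr$weights)
    model_predict(m, packs)
  })
  expect_equal(p, rowMeans(indiv), tolerance = 1e-7)
  ens2 <- ens; ens2$folds <- ens$folds[c(3, 5, 1, 2, 4)]
  expect_equal(predict_proba(ens2, packs), p, tolerance = 1e-12)
  # all folds identical -> ensemble equals the single model
  ens3 <- ens; ens3$folds <- ens$folds[c(1, 1, 1, 1, 1)]
  expect_equal(predict_proba(ens3, packs), indiv[, 1], tolerance = 1e-7)
  # channel mismatch rejected
  expect_error(predict_proba(ens, list(random_pack(6, 16))), "channel mismatch")
})

test_that("train_fold learns the strong-signal phantom and stops early", {
  fx <- fixture_trained()
  expect_gte(fx$fold$best_val_auc, 0.8)
  expect_lte(nrow(fx$fold$trace), 25)
  # trace bookkeeping
  expect_equal(fx$fold$epoch_of_best,
               which.max(fx$fold$trace$val_auc))
})

test_that("early stopping with patience 1 halts quickly on a null problem", {
  packs <- lapply(1:8, function(s) random_pack(4, 16, seed = 100 + s))
  labels <- rep(c(0, 1), 4)
  cfg <- cnn_config(profile = "ci", seed = 5)
  cfg$image_size <- 16L
  cfg$max_epochs <- 30L
  cfg$early_stop_patience <- 1L
  cfg$batch_size <- 4L
  fr <- train_fold(packs, labels, 1:6, 7:8, cfg)
  expect_lt(nrow(fr$trace), 30)
  expect_error(train_fold(packs, labels, 1:6, c(6, 7), cfg), "disjoint")
  expect_error(train_fold(packs, c(rep(0, 7), 1), 1:6, c(7, 8)[1:1], cfg),
               "single class")
})

test_that("online augmentation path trains and reproduces under a seed", {
  packs <- lapply(1:12, function(s) random_pack(4, 16, seed = 300 + s))
  labels <- rep(c(0, 1), 6)
  cfg <- cnn_config(profile = "ci", seed = 8)
  cfg$image_size <- 16L; cfg$max_epochs <- 2L; cfg$batch_size <- 4L
  cfg$augment <- augment_config(noise_sd = 0.02, elastic_alpha = 0)
  fr1 <- train_fold(packs, labels, 1:8, 9:12, cfg)
  expect_equal(nrow(fr1$trace), 2)
  expect_true(all(is.finite(fr1$trace$loss)))
  fr2 <- train_fold(packs, labels, 1:8, 9:12, cfg)
  expect_equal(fr1$trace$loss, fr2$trace$loss, tolerance = 1e-6)
})

test_that("crossval_train: OOF partition property and determinism", {
  packs <- lapply(1:20, function(s) random_pack(4, 16, seed = 200 + s))
  labels <- rep(c(0, 1), 10)
  cfg <- cnn_config(profile = "ci", seed = 6)
  cfg$image_size <- 16L; cfg$max_epochs <- 2L; cfg$batch_size <- 8L
  ens <- crossval_train(packs, labels, cfg)
  expect_false(any(is.na(ens$oof_prob)))          # every case exactly once
  expect_true(all(ens$oof_prob >= 0 & ens$oof_prob <= 1))
  expect_equal(sort(unlist(lapply(ens$folds, function(f) f$val_idx))), 1:20)
  ids <- lapply(ens$folds, function(f) f$val_idx)
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(ids[[i]], ids[[j]]), 0)
  ens2 <- crossval_train(packs, labels, cfg)
  expect_identical(ens$fold_id, ens2$fold_id)
  expect_equal(ens$oof_prob, ens2$oof_prob, tolerance = 1e-6)
})

test_that("gradcam: nonnegative, input-sized, zero-grad warning, localization", {
  fx <- fixture_trained()
  pk <- fx$packs[[fx$val_idx[1]]]
  am <- gradcam(fx$fold, pk)
  expect_equal(dim(am$heat), c(32, 32))
  expect_true(all(am$heat >= 0))
  expect_equal(max(am$heat_norm), 1)

  # zeroed head -> zero gradient everywhere -> warning + all-zero map
  m0 <- build_model(pk_channels <- dim(pk$slices)[1], dropout = 0, seed = 2)
  w <- ns$nn_get_weights(m0$ptr)
  w$fc.weight[] <- 0
  ns$nn_set_weights(m0$ptr, w)
  expect_warning(am0 <- gradcam(m0, pk), "zero gradient")
  expect_true(all(am0$heat == 0))

  # localization: on correctly classified positives the mean heat inside
  # the liver+spleen region exceeds the outside mean for >= 70% of cases.
  # At 32-px inputs stage 4 is 1x1 (uniform after upsampling), so the map
  # is taken at stage 2 (4x4), the deepest stage with spatial resolution
  # at this scale.
  pos <- fx$val_idx[fx$labels[fx$val_idx] == 1]
  mdl <- hepascan:::.net_for(fx$fold$in_channels, fx$fold$dropout)
  ns$nn_set_weights(mdl$ptr, fx$fold$weights)
  pr <- model_predict(mdl, fx$packs[pos])
  correct <- pos[pr >= 0.5]
  expect_gte(length(correct), 3)
  hits <- 0
  for (i in correct) {
    region <- fx$regions[[i]]
    am <- gradcam(fx$fold, fx$packs[[i]], stage = 2)
    hits <- hits + (mean(am$heat[region > 0]) > mean(am$heat[region == 0]))
  }
  expect_gte(hits / length(correct), 0.7)
})
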