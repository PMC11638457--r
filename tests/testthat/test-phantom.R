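test_that("phantom parameter validation names the offending field", {
  expect_error(phantom_params(prevalence = 1.2), "prevalence")
  expect_error(phantom_params(grid_shape = c(8, 64, 64)), "grid_shape")
  expect_error(phantom_params(nodularity_amp = -0.1), "nodularity_amp")
  expect_error(phantom_params(spleen_ratio = 0.8), "spleen_ratio")
  sp <- default_biomarker_spec(); sp$sd0[3] <- 0
  expect_error(phantom_params(biomarker_spec = sp), "SD")
})

test_that("cohort label counts follow the half-up rounding rule exactly", {
  for (case in list(c(100, 0.65, 65), c(10, 0.65, 7), c(11, 0.5, 6),
                    c(20, 0.33, 7), c(10, 0, 0), c(10, 1, 10))) {
    p <- phantom_params(n_cases = case[1], prevalence = case[2], seed = 3)
    co <- generate_cohort(p, keep_volumes = FALSE)
    expect_equal(sum(vapply(co, `[[`, 0L, "label")), as.integer(case[3]))
  }
})

test_that("cohorts are byte-identical under the same seed", {
  skip_if_not_installed("digest")
  p <- phantom_params(n_cases = 4, seed = 99)
  h1 <- digest::digest(generate_cohort(p))
  h2 <- digest::digest(generate_cohort(p))
  expect_identical(h1, h2)
  p2 <- phantom_params(n_cases = 4, seed = 100)
  expect_false(identical(h1, digest::digest(generate_cohort(p2))))
})

test_that("stage is consistent with the label (S4 = cirrhosis)", {
  co <- generate_cohort(phantom_params(n_cases = 40, seed = 5),
                        keep_volumes = FALSE)
  for (cs in co) {
    if (cs$label == 1) expect_equal(cs$stage, 4L)
    else expect_true(cs$stage %in% 0:3)
  }
})

test_that("volumes express the designed contrasts and effects", {
  st0 <- fixture_study(label = 0, seed = 5)
  st1 <- fixture_study(label = 1, seed = 5)
  # liver brighter than surroundings on the reference (PV) channel
  expect_gt(mean(st1$sequences$PV[st1$mask > 0]),
            mean(st1$sequences$PV[st1$mask == 0]))
  expect_gt(mean(st0$sequences$T1pre[shift_volume(st0$mask, st0$shifts$T1pre) > 0]),
            mean(st0$sequences$T1pre))
  # same geometry seed: the cirrhotic mask differs from the smooth one only
  # through the added high-order boundary terms
  expect_false(identical(st0$mask, st1$mask))
  # boundary roughness: radial SD of the mask outline is higher when nodular
  roughness <- function(mask) {
    z <- which.max(apply(mask, 1, sum))
    sl <- mask[z, , ]
    pts <- which(sl > 0, arr.ind = TRUE)
    cy <- mean(pts[, 1]); cx <- mean(pts[, 2])
    th <- atan2(pts[, 1] - cy, pts[, 2] - cx)
    r <- sqrt((pts[, 1] - cy)^2 + (pts[, 2] - cx)^2)
    bins <- cut(th, breaks = seq(-pi, pi, length.out = 37))
    edge <- tapply(r, bins, max)
    sd(edge / mean(edge, na.rm = TRUE), na.rm = TRUE)
  }
  expect_gt(roughness(st1$mask), roughness(st0$mask))
  # spleen enlargement raises the non-liver bright area on T2
  t2_0 <- st0$sequences$T2; t2_1 <- st1$sequences$T2
  expect_gt(sum(t2_1 > 0.55), 0)
})

test_that("zero-effect parameters remove every imaging difference knob", {
  p <- phantom_params(n_cases = 2, nodularity_amp = 0, texture_sigma = 1,
                      spleen_ratio = 1, seed = 21)
  st0 <- generate_volume(0, p, seed = 33)
  st1 <- generate_volume(1, p, seed = 33)
  # identical seeds and no effect knobs: identical geometry and intensities
  expect_identical(st0$mask, st1$mask)
  expect_equal(st0$sequences$T1pre, st1$sequences$T1pre, tolerance = 1e-12)
})

test_that("biomarker directionality and the zero-effect symmetry hold", {
  b0 <- do.call(rbind, lapply(1:300, function(i) sample_biomarkers(0, seed = i)))
  b1 <- do.call(rbind, lapply(1:300, function(i) sample_biomarkers(1, seed = 5000 + i)))
  expect_lt(mean(b1$platelet), mean(b0$platelet))
  expect_lt(mean(b1$albumin), mean(b0$albumin))
  for (a in c("ast", "alt", "ggt", "alp", "total_bilirubin", "inr"))
    expect_gt(mean(b1[[a]]), mean(b0[[a]]))
  # null spec: difference in means within Monte-Carlo error
  sp <- null_biomarker_spec()
  n0 <- do.call(rbind, lapply(1:300, function(i) sample_biomarkers(0, sp, seed = i)))
  n1 <- do.call(rbind, lapply(1:300, function(i) sample_biomarkers(1, sp, seed = 9000 + i)))
  d <- (mean(n1$ast) - mean(n0$ast)) / sd(c(n0$ast, n1$ast))
  expect_lt(abs(d), 0.25)
  # missing analyte errors
  expect_error(sample_biomarkers(1, sp[sp$analyte != "inr", ]), "inr")
})

test_that("FIB-4 separates labels on a default-spec draw", {
  co <- generate_cohort(phantom_params(n_cases = 500, seed = 77),
                        keep_volumes = FALSE)
  tab <- do.call(rbind, lapply(co, function(cs)
    cbind(label = cs$label, cs$panel)))
  f <- fib4(tab$age, tab$ast, tab$platelet, tab$alt)
  expect_gt(roc_auc(f, tab$label)$auc, 0.5)
})

test_that("write_cohort emits the full file set and round-trips", {
  p <- phantom_params(n_cases = 3, seed = 13)
  co <- generate_cohort(p)
  dir <- file.path(tempdir(), "phantom_cohort_test")
  unlink(dir, recursive = TRUE)
  manifest <- write_cohort(co, dir)
  files <- list.files(dir)
  expect_equal(sum(grepl("\\.nii\\.gz$", files)), 3 * 4)  # 3 seq + mask per case
  expect_true("cohort.csv" %in% files)
  expect_true("manifest.json" %in% files)
  man <- jsonlite::read_json(manifest)
  expect_equal(man$seed, p$seed)
  tab <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(tab$label, vapply(co, `[[`, 0L, "label"))
  # volume round-trip through NIfTI
  st <- load_study(dir, "case_0001")
  expect_equal(st$mask, co[[1]]$study$mask, tolerance = 1e-6)
  expect_equal(st$sequences$T1pre, co[[1]]$study$sequences$T1pre,
               tolerance = 1e-6)
  # refuses to overwrite without force
  expect_error(write_cohort(co, dir), "not empty")
  unlink(dir, recursive = TRUE)
})

test_that("CNN signal is monotone in nodularity amplitude", {
  # scaled version of the monotone-signal property: one replicate seed,
  # single 70/30 training fold at n = 80 / 32 px / 6 epochs; the 3-point
  # trend must not invert beyond a small tolerance and the extremes must
  # order strictly
  auc_at <- function(amp) {
    params <- phantom_params(n_cases = 80, prevalence = 0.5,
                             nodularity_amp = amp,
                             texture_sigma = if (amp == 0) 1 else 1.5,
                             spleen_ratio = if (amp == 0) 1 else 1.4,
                             seed = 701)
    cases <- generate_cohort(params)
    labels <- vapply(cases, `[[`, 0L, "label")
    packs <- lapply(cases, function(cs)
      preprocess_stack(register_study(cs$study), size = 32))
    set.seed(702)
    va <- c(sample(which(labels == 1), 12), sample(which(labels == 0), 12))
    tr <- setdiff(seq_along(labels), va)
    cfg <- cnn_config(profile = "ci", seed = 703)
    cfg$image_size <- 32L; cfg$max_epochs <- 6L; cfg$early_stop_patience <- 6L
    fr <- train_fold(packs, labels, tr, va, cfg)
    fr$best_val_auc
  }
  aucs <- vapply(c(0, 0.05, 0.15), auc_at, 0)
  expect_gt(aucs[3], aucs[1])
  expect_gte(aucs[2], aucs[1] - 0.1)
  expect_gte(aucs[3], aucs[2] - 0.1)
})

test_that("NIfTI writer/reader round-trips arbitrary volumes", {
  set.seed(3)
  v <- array(rnorm(17 * 19 * 23), c(17, 19, 23))
  f <- tempfile(fileext = ".nii.gz")
  write_nifti(v, f, spacing = c(4, 1.25, 1.25))
  r <- read_nifti(f)
  expect_equal(dim(r$data), dim(v))
  expect_equal(r$data, v, tolerance = 1e-6)
  expect_equal(r$spacing, c(4, 1.25, 1.25), tolerance = 1e-7)
})
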