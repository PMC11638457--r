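## Synthetic liver-MR phantom cohorts.
##
## Each case carries three axial "sequences" (pre-contrast T1-like, T2-like,
## portal-venous-like), a binary liver mask defined in the portal-venous
## reference frame, and a serum panel drawn from class-conditional
## distributions. Cirrhosis (label 1) expresses the radiological signs the
## classifier is meant to learn: high-order boundary nodularity, stronger
## parenchymal texture heterogeneity, and an enlarged spleen; pre-contrast
## sequences are misaligned from the reference frame by a small rigid shift.

#' Phantom cohort parameters
#'
#' @param n_cases number of cases
#' @param prevalence fraction of cirrhotic (stage S4) cases in `[0, 1]`
#' @param grid_shape voxel grid `(z, y, x)`, all entries >= 16
#' @param nodularity_amp boundary perturbation amplitude as a fraction of the
#'   local liver radius (L2 norm of the high-order Fourier coefficients);
#'   applied to cirrhotic cases only
#' @param texture_sigma multiplier on the parenchymal texture SD of cirrhotic
#'   cases (1 = no effect)
#' @param spleen_ratio cirrhotic-to-normal spleen cross-section area ratio
#'   (>= 1)
#' @param misalign_max maximum inter-sequence rigid shift in voxels (integer
#'   shifts; through-plane component limited to 1)
#' @param biomarker_spec class-conditional serum distributions, see
#'   [default_biomarker_spec()]
#' @param seed integer master seed; every downstream draw derives from it
#' @return object of class `phantom_params`
#' @export
phantom_params <- function(n_cases = 100, prevalence = 0.65,
                           grid_shape = c(32, 64, 64),
                           nodularity_amp = 0.1, texture_sigma = 1.5,
                           spleen_ratio = 1.4, misalign_max = 2,
                           biomarker_spec = default_biomarker_spec(),
                           seed = 1) {
  p <- list(n_cases = as.integer(n_cases), prevalence = prevalence,
            grid_shape = as.integer(grid_shape),
            nodularity_amp = nodularity_amp, texture_sigma = texture_sigma,
            spleen_ratio = spleen_ratio, misalign_max = as.integer(misalign_max),
            biomarker_spec = biomarker_spec, seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (!is.numeric(p$n_cases) || p$n_cases < 1)
    stop_config("n_cases", "must be a positive integer")
  if (!is.numeric(p$prevalence) || p$prevalence < 0 || p$prevalence > 1)
    stop_config("prevalence", "must lie in [0, 1]")
  if (length(p$grid_shape) != 3 || any(p$grid_shape < 16))
    stop_config("grid_shape", "must be three axis lengths, each >= 16")
  if (p$nodularity_amp < 0)
    stop_config("nodularity_amp", "must be >= 0")
  if (p$texture_sigma <= 0)
    stop_config("texture_sigma", "must be > 0")
  if (p$spleen_ratio < 1)
    stop_config("spleen_ratio", "must be >= 1")
  if (p$misalign_max < 0)
    stop_config("misalign_max", "must be >= 0")
  sp <- p$biomarker_spec
  need <- c("analyte", "dist", "mean0", "sd0", "mean1", "sd1")
  if (!is.data.frame(sp) || !all(need %in% names(sp)))
    stop_config("biomarker_spec", "must be a data.frame with columns analyte, dist, mean0, sd0, mean1, sd1")
  if (any(sp$sd0 <= 0) || any(sp$sd1 <= 0))
    stop_config("biomarker_spec", "every SD must be > 0")
  invisible(p)
}

#' Default class-conditional serum biomarker distributions
#'
#' Age is Gaussian in years; the eight serum analytes are log-normal
#' (mean/SD given on the log scale). Direction of every class effect follows
#' the established clinical picture of cirrhosis: lower platelet count
#' (portal hypertension) and albumin (synthetic function); higher AST, ALT,
#' GGT (hepatocellular damage), ALP and bilirubin (cholestasis), and INR
#' (coagulopathy). The magnitudes are package defaults chosen to be
#' realistic for a surgical chronic-liver-disease cohort; they are not fitted
#' to any published table.
#'
#' @return data.frame with columns analyte, dist, mean0, sd0, mean1, sd1
#' @export
default_biomarker_spec <- function() {
  data.frame(
    analyte = c("age", "platelet", "total_bilirubin", "albumin", "ast",
                "alt", "alp", "ggt", "inr"),
    dist = c("normal", rep("lognormal", 8)),
    mean0 = c(50, log(210), log(13), log(44), log(34), log(38), log(82),
              log(38), log(1.03)),
    sd0 = c(11, 0.28, 0.35, 0.09, 0.35, 0.45, 0.30, 0.55, 0.05),
    mean1 = c(55, log(105), log(21), log(37), log(62), log(50), log(110),
              log(85), log(1.22)),
    sd1 = c(10, 0.38, 0.45, 0.11, 0.45, 0.50, 0.35, 0.60, 0.12),
    stringsAsFactors = FALSE)
}

#' Zero-effect biomarker spec (class-1 distributions equal class-0)
#' @return data.frame in the [default_biomarker_spec()] layout
#' @export
null_biomarker_spec <- function() {
  sp <- default_biomarker_spec()
  sp$mean1 <- sp$mean0
  sp$sd1 <- sp$sd0
  sp
}

#' Draw one serum panel
#'
#' @param label 0/1 cirrhosis label selecting the class-conditional column
#' @param spec biomarker spec data.frame
#' @param seed integer seed for this draw
#' @return one-row data.frame with age and the eight serum analytes
#' @export
sample_biomarkers <- function(label, spec = default_biomarker_spec(), seed = 1) {
  need <- c("age", "platelet", "total_bilirubin", "albumin", "ast", "alt",
            "alp", "ggt", "inr")
  missing <- setdiff(need, spec$analyte)
  if (length(missing))
    stop_config("biomarker_spec", paste("missing analyte(s):",
                                        paste(missing, collapse = ", ")))
  set.seed(seed)
  out <- lapply(need, function(a) {
    row <- spec[spec$analyte == a, ]
    mu <- if (label == 1) row$mean1 else row$mean0
    s <- if (label == 1) row$sd1 else row$sd0
    v <- rnorm(1, mu, s)
    if (row$dist == "lognormal") v <- exp(v)
    if (a == "age") v <- min(100, max(18, v))
    v
  })
  names(out) <- need
  as.data.frame(out)
}

## radial boundary of the liver/spleen cross-section at angles th
.boundary_radius <- function(th, base_r, anis, four_k, four_a, four_phi) {
  n <- 2.5                                 # superellipse exponent
  s <- (abs(cos(th) / anis[1])^n + abs(sin(th) / anis[2])^n)^(-1 / n)
  f <- rep(0, length(th))
  for (i in seq_along(four_k))
    f <- f + four_a[i] * cos(four_k[i] * th + four_phi[i])
  base_r * s * (1 + f)
}

## fill a star-convex blob on one slice
.fill_blob <- function(ny, nx, cy, cx, radius_fun) {
  yy <- rep(seq_len(ny), times = nx) - cy
  xx <- rep(seq_len(nx), each = ny) - cx
  r <- sqrt(yy^2 + xx^2)
  th <- atan2(yy, xx)
  matrix(r <= radius_fun(th), ny, nx)
}

#' Generate one phantom MR study
#'
#' Builds T1-like, T2-like and portal-venous-like volumes plus the binary
#' liver mask on the `grid_shape` grid. The mask and portal-venous volume
#' live in the reference frame; T1 and T2 are offset by a random integer
#' rigid shift of at most `misalign_max` voxels. Cirrhotic anatomy adds
#' high-order boundary nodularity, scales parenchymal texture SD by
#' `texture_sigma`, and scales spleen area by `spleen_ratio`.
#'
#' @param label 0/1 cirrhosis label
#' @param params [phantom_params()]
#' @param seed integer seed for this case
#' @param case_id id string stored in the study
#' @return `mri_study` list: `sequences` (named list of arrays `[z, y, x]`),
#'   `mask`, `spacing`, `case_id`, and the injected `shifts` per sequence
#' @export
generate_volume <- function(label, params, seed = 1, case_id = "case") {
  validate_phantom_params(params)
  set.seed(seed)
  gz <- params$grid_shape[1]; gy <- params$grid_shape[2]; gx <- params$grid_shape[3]

  ## case-level geometry jitter
  liver_c <- c(y = gy * 0.45 + runif(1, -1.5, 1.5),
               x = gx * 0.36 + runif(1, -1.5, 1.5))
  liver_r <- gx * 0.21 * runif(1, 0.92, 1.08)
  spleen_c <- c(y = gy * 0.52 + runif(1, -1, 1), x = gx * 0.78 + runif(1, -1, 1))
  spleen_r <- gx * 0.075 * runif(1, 0.9, 1.1) *
    (if (label == 1) sqrt(params$spleen_ratio) else 1)
  body_c <- c(y = gy * 0.52, x = gx * 0.5)
  body_r <- c(gy * 0.42, gx * 0.46)

  ## smooth low-order shape, shared by all slices
  lo_k <- c(2, 3); lo_a <- runif(2, 0.01, 0.05); lo_phi <- runif(2, 0, 2 * pi)
  ## high-order nodularity, cirrhotic cases only
  if (label == 1 && params$nodularity_amp > 0) {
    hi_k <- 8:14
    raw <- runif(7, 0.5, 1)
    hi_a <- raw / sqrt(sum(raw^2)) * params$nodularity_amp
    hi_phi <- runif(7, 0, 2 * pi)
  } else {
    hi_k <- integer(0); hi_a <- numeric(0); hi_phi <- numeric(0)
  }

  z_liver <- c(max(1, round(gz * 0.12)), min(gz, round(gz * 0.88)))
  z_spleen <- c(max(1, round(gz * 0.3)), min(gz, round(gz * 0.75)))
  zc_l <- mean(z_liver); zh_l <- diff(z_liver) / 2 + 0.5
  zc_s <- mean(z_spleen); zh_s <- diff(z_spleen) / 2 + 0.5

  mask <- array(FALSE, c(gz, gy, gx))
  spleen <- array(FALSE, c(gz, gy, gx))
  body <- array(FALSE, c(gz, gy, gx))
  body_sl <- {
    yy <- rep(seq_len(gy), times = gx); xx <- rep(seq_len(gx), each = gy)
    matrix(((yy - body_c[1]) / body_r[1])^2 + ((xx - body_c[2]) / body_r[2])^2 <= 1,
           gy, gx)
  }
  for (z in seq_len(gz)) {
    body[z, , ] <- body_sl
    pl <- 1 - ((z - zc_l) / zh_l)^2
    if (pl > 0.05) {
      sc <- sqrt(pl)
      mask[z, , ] <- .fill_blob(gy, gx, liver_c[1], liver_c[2], function(th)
        .boundary_radius(th, liver_r * sc, c(1.15, 0.9),
                         c(lo_k, hi_k), c(lo_a, hi_a), c(lo_phi, hi_phi)))
    }
    ps <- 1 - ((z - zc_s) / zh_s)^2
    if (ps > 0.05) {
      sc <- sqrt(ps)
      spleen[z, , ] <- .fill_blob(gy, gx, spleen_c[1], spleen_c[2], function(th)
        .boundary_radius(th, spleen_r * sc, c(1.1, 0.95), 2, 0.03, runif(1, 0, 2 * pi)))
    }
  }

  ## parenchymal Gaussian-random-field texture, correlation length ~4 voxels
  tex_sd <- 0.06 * (if (label == 1) params$texture_sigma else 1)
  tex <- array(0, c(gz, gy, gx))
  for (z in seq_len(gz)) {
    f <- gaussian_blur2d(matrix(rnorm(gy * gx), gy, gx), 4 / sqrt(2))
    f <- f / max(sd(f), 1e-9)
    tex[z, , ] <- f * tex_sd
  }

  levels <- list(T1pre = c(body = 0.30, liver = 0.70, spleen = 0.45),
                 T2    = c(body = 0.30, liver = 0.35, spleen = 0.70),
                 PV    = c(body = 0.32, liver = 0.60, spleen = 0.65))
  gain <- runif(1, 0.9, 1.1)

  m <- params$misalign_max
  shifts <- list(
    T1pre = c(sample(-min(1, m):min(1, m), 1), sample(-m:m, 1), sample(-m:m, 1)),
    T2    = c(sample(-min(1, m):min(1, m), 1), sample(-m:m, 1), sample(-m:m, 1)),
    PV    = c(0L, 0L, 0L))

  make_seq <- function(lv, shift) {
    vol <- array(0.02, c(gz, gy, gx))
    vol[body] <- lv["body"]
    vol[mask] <- lv["liver"]
    vol[spleen] <- lv["spleen"]
    vol <- vol + tex * (mask | spleen)
    vol <- vol * gain + array(rnorm(gz * gy * gx, 0, 0.03), c(gz, gy, gx))
    shift_volume(vol, shift)
  }
  sequences <- lapply(names(levels), function(nm) make_seq(levels[[nm]], shifts[[nm]]))
  names(sequences) <- names(levels)

  study <- list(sequences = sequences, mask = array(as.numeric(mask), dim(mask)),
                spleen = array(as.numeric(spleen), dim(spleen)),
                spacing = c(5, 1.5, 1.5), case_id = case_id, shifts = shifts)
  class(study) <- "mri_study"
  study
}

#' Shift a volume by integer voxels (zero fill)
#' @param vol array `[z, y, x]`
#' @param shift integer `(dz, dy, dx)`; positive moves content toward higher
#'   indices
#' @return shifted array
#' @export
shift_volume <- function(vol, shift) {
  d <- dim(vol)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { src[[a]] <- 1:(d[a] - s); dst[[a]] <- (1 + s):d[a] }
    else { src[[a]] <- (1 - s):d[a]; dst[[a]] <- 1:(d[a] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

## Deterministic cohort layout shared by generate_cohort() and the
## streaming cmd_simulate(): labels by stratified shuffling with exactly
## round(prevalence * n) positives (half-up), per-case derived seeds.
.cohort_plan <- function(params) {
  n <- params$n_cases
  n1 <- as.integer(round_half_up(params$prevalence * n))
  labels <- c(rep(1L, n1), rep(0L, n - n1))
  set.seed(derive_seed(params$seed, 0))
  labels <- labels[sample.int(n)]
  stages <- ifelse(labels == 1L, 4L, sample(0:3, n, replace = TRUE))
  list(ids = sprintf("case_%04d", seq_len(n)), labels = labels,
       stages = as.integer(stages),
       case_seeds = vapply(seq_len(n), function(i) derive_seed(params$seed, i), 1L),
       panel_seeds = vapply(seq_len(n), function(i)
         derive_seed(params$seed, i + 1000000), 1L))
}

#' Generate a seeded phantom cohort
#'
#' Labels are assigned by stratified shuffling with exactly
#' `round(prevalence * n_cases)` positives (half-up rounding); stage is 4 for
#' positives and uniform on 0-3 otherwise. Each case derives its own seed
#' from `params$seed`, so the cohort is reproducible case by case.
#'
#' @param params [phantom_params()]
#' @param keep_volumes if `FALSE`, drop the imaging study from each case
#'   (serum-only cohorts are much lighter)
#' @return list of `phantom_case` objects with fields `case_id`, `label`,
#'   `stage`, `study`, `panel`
#' @export
generate_cohort <- function(params, keep_volumes = TRUE) {
  validate_phantom_params(params)
  plan <- .cohort_plan(params)
  cases <- lapply(seq_len(params$n_cases), function(i) {
    case <- list(
      case_id = plan$ids[i], label = plan$labels[i], stage = plan$stages[i],
      study = if (keep_volumes)
        generate_volume(plan$labels[i], params, plan$case_seeds[i], plan$ids[i])
      else NULL,
      panel = sample_biomarkers(plan$labels[i], params$biomarker_spec,
                                plan$panel_seeds[i]))
    class(case) <- "phantom_case"
    case
  })
  attr(cases, "params") <- params
  attr(cases, "seed") <- params$seed
  cases
}

#' Write a cohort to disk
#'
#' One NIfTI volume per sequence and mask per case, a cohort CSV
#' (case_id, label, stage, analytes), and a JSON manifest recording files,
#' seed and parameters.
#'
#' @param cases list of `phantom_case` (with volumes)
#' @param out_dir output directory (created if missing)
#' @param force overwrite a non-empty directory
#' @return path of the manifest file
#' @export
write_cohort <- function(cases, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  suffix <- c(T1pre = "_t1.nii.gz", T2 = "_t2.nii.gz", PV = "_pv.nii.gz")
  files <- character(0)
  rows <- list()
  for (case in cases) {
    st <- case$study
    if (is.null(st)) stop("case ", case$case_id, " has no volumes")
    for (sq in names(st$sequences)) {
      f <- file.path(out_dir, paste0(case$case_id, suffix[[sq]]))
      write_nifti(st$sequences[[sq]], f, st$spacing)
      files <- c(files, basename(f))
    }
    f <- file.path(out_dir, paste0(case$case_id, "_mask.nii.gz"))
    write_nifti(st$mask, f, st$spacing)
    files <- c(files, basename(f))
    rows[[case$case_id]] <- cbind(
      data.frame(case_id = case$case_id, label = case$label, stage = case$stage),
      case$panel)
  }
  cohort <- do.call(rbind, rows)
  csv <- file.path(out_dir, "cohort.csv")
  write.csv(cohort, csv, row.names = FALSE)
  manifest <- file.path(out_dir, "manifest.json")
  params <- attr(cases, "params")
  pj <- if (is.null(params)) NULL else unclass(params)
  jsonlite::write_json(
    list(n_cases = length(cases), seed = attr(cases, "seed"),
         files = c(files, basename(csv)), params = pj),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
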