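## Mask-guided preprocessing: rigid co-registration of sequences to the
## portal-venous frame, liver-area slice selection, percentile clipping,
## zero-padding to square, resizing, per-sequence min-max normalization, and
## online training augmentation.

#' Rigid intensity-based registration of two volumes
#'
#' Coarse-to-fine search over integer translations (and optional axial
#' rotations) maximizing normalized cross-correlation. A classical stand-in
#' for a learned registration network: the phantom injects small rigid
#' shifts, and this recovers them. Images are resampled linearly, masks with
#' nearest neighbor.
#'
#' @param moving volume to align, array `[z, y, x]`
#' @param fixed reference volume of the same shape
#' @param max_shift translation search budget in voxels (in-plane; the
#'   through-plane budget is `min(max_shift, 2)`)
#' @param rotations axial rotation candidates in degrees (`0` only, by
#'   default; |rotation| <= 30)
#' @return list with `transform` (`translation` `(dz, dy, dx)`, `rotation`
#'   degrees), `ncc`, and `resampled` moving volume in the fixed frame
#' @export
register_rigid <- function(moving, fixed, max_shift = 3, rotations = 0) {
  stopifnot(all(dim(moving) == dim(fixed)))
  if (any(abs(rotations) > 30)) stop("|rotation| must be <= 30 degrees")
  if (sd(moving) == 0 || sd(fixed) == 0)
    stop("degenerate input: constant volume cannot be registered")

  ncc <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    d <- sqrt(sum(a^2) * sum(b^2))
    if (d == 0) return(-Inf)
    sum(a * b) / d
  }
  rot_vol <- function(vol, deg) {
    if (deg == 0) return(vol)
    out <- vol
    for (z in seq_len(dim(vol)[1]))
      out[z, , ] <- warp_affine(vol[z, , ], rotate_deg = deg)
    out
  }
  d <- dim(fixed)
  zmax <- min(max_shift, 2)

  ## coarse pass: the full circular cross-correlation surface from one FFT
  ## per rotation candidate, restricted to the shift budget
  Ff <- Conj(fft(fixed - mean(fixed)))
  lag_idx <- function(n, lags) ((lags %% n) + 1)
  zl <- -zmax:zmax; yl <- -max_shift:max_shift; xl <- -max_shift:max_shift
  best <- list(score = -Inf, lag = c(0, 0, 0), rot = 0)
  for (rot in rotations) {
    mv <- rot_vol(moving, rot)
    cc <- Re(fft(Ff * fft(mv - mean(mv)), inverse = TRUE))
    win <- cc[lag_idx(d[1], zl), lag_idx(d[2], yl), lag_idx(d[3], xl), drop = FALSE]
    w <- which(win == max(win), arr.ind = TRUE)[1, ]
    if (max(win) > best$score)
      best <- list(score = max(win), lag = c(zl[w[1]], yl[w[2]], xl[w[3]]),
                   rot = rot)
  }

  ## fine pass: exact zero-filled NCC on +-1 around the coarse optimum; the
  ## translation applied to `moving` is the negated content lag. The
  ## identity is always among the candidates.
  ctr <- -best$lag
  cand <- unique(rbind(expand.grid(
    dz = unique(pmax(-zmax, pmin(zmax, ctr[1] + -1:1))),
    dy = unique(pmax(-max_shift, pmin(max_shift, ctr[2] + -1:1))),
    dx = unique(pmax(-max_shift, pmin(max_shift, ctr[3] + -1:1)))),
    c(0, 0, 0)))
  mv <- rot_vol(moving, best$rot)
  fine <- list(score = -Inf, shift = c(0, 0, 0))
  for (k in seq_len(nrow(cand))) {
    s <- as.numeric(cand[k, ])
    v <- ncc(shift_volume(mv, s), fixed)
    if (v > fine$score) fine <- list(score = v, shift = s)
  }
  resampled <- shift_volume(mv, fine$shift)
  list(transform = list(translation = fine$shift, rotation = best$rot),
       ncc = fine$score, resampled = resampled)
}

#' Register all sequences of a study to the portal-venous frame
#'
#' @param study `mri_study`
#' @param reference name of the reference sequence (default `"PV"`)
#' @param max_shift translation budget in voxels
#' @return the study with sequences resampled into the reference frame and a
#'   `registration` element recording the recovered transforms
#' @export
register_study <- function(study, reference = "PV", max_shift = 3) {
  fixed <- study$sequences[[reference]]
  if (is.null(fixed)) stop("reference sequence ", reference, " missing")
  reg <- list()
  for (nm in names(study$sequences)) {
    if (nm == reference) next
    r <- register_rigid(study$sequences[[nm]], fixed, max_shift = max_shift)
    study$sequences[[nm]] <- r$resampled
    reg[[nm]] <- r$transform
  }
  study$registration <- reg
  study
}

#' Select the five model slices from a liver mask
#'
#' The center slice maximizes liver area (lowest index on ties). With N =
#' number of mask-intersecting slices, the offsets are round(0.15 N) and
#' round(0.25 N) above and below the center, clamped to the mask's slice
#' range; duplicates after clamping are shifted inward until distinct (if
#' N < 5 indices may repeat, with a warning).
#'
#' @param mask binary volume `[z, y, x]`
#' @return sorted integer vector of 5 slice indices (1-based)
#' @export
select_slices <- function(mask) {
  areas <- apply(mask, 1, sum)
  if (all(areas == 0)) stop("empty mask: no liver voxels")
  in_mask <- which(areas > 0)
  n_liver <- length(in_mask)
  ctr <- which.max(areas)                       # lowest index wins ties
  d15 <- round_half_up(0.15 * n_liver)
  d25 <- round_half_up(0.25 * n_liver)
  lo <- min(in_mask); hi <- max(in_mask)
  idx <- c(ctr - d25, ctr - d15, ctr, ctr + d15, ctr + d25)
  idx <- pmin(pmax(idx, lo), hi)
  if (n_liver >= 5) {
    ## resolve clamping duplicates by shifting inward
    for (pass in 1:10) {
      if (!anyDuplicated(idx)) break
      for (k in c(2, 1)) if (idx[k] %in% idx[(k + 1):5]) idx[k] <- idx[k] + 1
      for (k in c(4, 5)) if (idx[k] %in% idx[1:(k - 1)]) idx[k] <- idx[k] - 1
      idx <- pmin(pmax(idx, lo), hi)
    }
    if (anyDuplicated(idx)) warning("could not make slice indices distinct")
  } else if (anyDuplicated(idx)) {
    warning("mask spans fewer than 5 slices; slice indices repeat")
  }
  sort(idx)
}

#' Assemble the normalized slice stack for the CNN
#'
#' Per sequence: intensities are clipped at the volume-wise 99.9th
#' percentile, the 5 selected slices and their mask slices are zero-padded
#' symmetrically to square, resized to `size` x `size` (bilinear for images,
#' nearest neighbor for masks), and the 5-slice image group is min-max
#' normalized jointly to `[0, 1]`. Channels are ordered sequence-major,
#' slice-minor, image before mask.
#'
#' @param study `mri_study` (already registered)
#' @param indices 5 slice indices from [select_slices()]; `NULL` selects them
#'   from the study mask
#' @param size output height/width in pixels
#' @param sequences which sequences to stack (default pre-contrast T1 + T2)
#' @return `slice_pack` list: `slices` array `[channel, H, W]`,
#'   `slice_indices`, `size`, `norm_bounds`, `channels` (names)
#' @export
preprocess_stack <- function(study, indices = NULL, size = 64,
                             sequences = c("T1pre", "T2")) {
  if (is.null(indices)) indices <- select_slices(study$mask)
  stopifnot(length(indices) == 5)
  d <- dim(study$mask)
  if (any(indices < 1 | indices > d[1])) stop("slice indices out of range")
  missing <- setdiff(sequences, names(study$sequences))
  if (length(missing)) stop("study lacks sequence(s): ", paste(missing, collapse = ", "))

  pad_square <- function(m) {
    h <- nrow(m); w <- ncol(m)
    if (h == w) return(m)
    s <- max(h, w)
    out <- matrix(0, s, s)
    y0 <- floor((s - h) / 2); x0 <- floor((s - w) / 2)
    out[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)] <- m
    out
  }

  n_ch <- length(sequences) * 5 * 2
  slices <- array(0, c(n_ch, size, size))
  ch_names <- character(n_ch)
  norm_bounds <- list()
  ch <- 1
  for (sq in sequences) {
    vol <- study$sequences[[sq]]
    hi <- quantile(vol, 0.999, names = FALSE)
    vol[vol > hi] <- hi
    imgs <- lapply(indices, function(z) resize2d(pad_square(vol[z, , ]), size, size))
    msks <- lapply(indices, function(z) {
      mm <- resize2d(pad_square(study$mask[z, , ]), size, size, method = "nearest")
      (mm > 0.5) * 1
    })
    lo <- min(unlist(imgs)); up <- max(unlist(imgs))
    if (up - lo <= 0) {
      warning("constant image group in sequence ", sq, "; normalized to zeros")
      imgs <- lapply(imgs, function(m) m * 0)
    } else {
      imgs <- lapply(imgs, function(m) (m - lo) / (up - lo))
    }
    norm_bounds[[sq]] <- c(min = lo, max = up)
    for (k in 1:5) {
      slices[ch, , ] <- imgs[[k]]
      ch_names[ch] <- sprintf("%s.s%d.image", sq, k)
      ch <- ch + 1
      slices[ch, , ] <- msks[[k]]
      ch_names[ch] <- sprintf("%s.s%d.mask", sq, k)
      ch <- ch + 1
    }
  }
  pack <- list(slices = slices, slice_indices = indices, size = size,
               norm_bounds = norm_bounds, channels = ch_names,
               sequences = sequences)
  class(pack) <- "slice_pack"
  pack
}

#' Augmentation configuration
#'
#' Online training-time augmentation: rotation, zoom, contrast (gamma),
#' Gaussian noise, and elastic distortion. Geometric parameters are shared
#' between the image and mask channels of the same slice; masks are warped
#' with nearest neighbor and re-binarized. Never applied at inference.
#'
#' @param rotate_deg rotation range in degrees
#' @param zoom zoom factor range
#' @param contrast_gamma gamma range for contrast adjustment
#' @param noise_sd Gaussian noise SD as a fraction of the intensity range
#' @param elastic_alpha displacement amplitude in pixels
#' @param elastic_sigma smoothing of the displacement field in pixels
#' @param apply_prob per-transform application probability
#' @param enabled master switch
#' @return `augment_config` list
#' @export
augment_config <- function(rotate_deg = c(-10, 10), zoom = c(0.9, 1.1),
                           contrast_gamma = c(0.8, 1.25), noise_sd = 0.01,
                           elastic_alpha = 2, elastic_sigma = 8,
                           apply_prob = 0.5, enabled = TRUE) {
  stopifnot(rotate_deg[1] <= rotate_deg[2], zoom[1] <= zoom[2],
            contrast_gamma[1] <= contrast_gamma[2],
            apply_prob >= 0, apply_prob <= 1, noise_sd >= 0)
  structure(list(rotate_deg = rotate_deg, zoom = zoom,
                 contrast_gamma = contrast_gamma, noise_sd = noise_sd,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 apply_prob = apply_prob, enabled = enabled),
            class = "augment_config")
}

#' Apply online augmentation to a slice pack
#'
#' @param pack `slice_pack`
#' @param cfg [augment_config()]
#' @param seed integer seed for this draw
#' @return augmented `slice_pack` (values clipped back to `[0, 1]`, masks
#'   binary)
#' @export
augment <- function(pack, cfg = augment_config(), seed = 1) {
  if (!isTRUE(cfg$enabled)) return(pack)
  set.seed(seed)
  size <- pack$size
  rot <- if (runif(1) < cfg$apply_prob) runif(1, cfg$rotate_deg[1], cfg$rotate_deg[2]) else 0
  zm <- if (runif(1) < cfg$apply_prob) runif(1, cfg$zoom[1], cfg$zoom[2]) else 1
  gam <- if (runif(1) < cfg$apply_prob) runif(1, cfg$contrast_gamma[1], cfg$contrast_gamma[2]) else 1
  noise <- runif(1) < cfg$apply_prob
  elast <- runif(1) < cfg$apply_prob && cfg$elastic_alpha > 0
  dy <- dx <- NULL
  if (elast) {
    dy <- gaussian_blur2d(matrix(runif(size^2, -1, 1), size, size), cfg$elastic_sigma)
    dx <- gaussian_blur2d(matrix(runif(size^2, -1, 1), size, size), cfg$elastic_sigma)
    dy <- dy / max(abs(dy), 1e-9) * cfg$elastic_alpha
    dx <- dx / max(abs(dx), 1e-9) * cfg$elastic_alpha
  }
  out <- pack
  is_mask <- grepl("\\.mask$", pack$channels)
  for (ch in seq_along(pack$channels)) {
    m <- pack$slices[ch, , ]
    meth <- if (is_mask[ch]) "nearest" else "bilinear"
    if (rot != 0 || zm != 1 || elast)
      m <- warp_affine(m, rotate_deg = rot, zoom = zm, dy = dy, dx = dx, method = meth)
    if (!is_mask[ch]) {
      if (gam != 1) m <- pmax(m, 0)^gam
      if (noise && cfg$noise_sd > 0)
        m <- m + matrix(rnorm(size^2, 0, cfg$noise_sd), size, size)
      m <- pmin(pmax(m, 0), 1)
    } else {
      m <- (m > 0.5) * 1
    }
    out$slices[ch, , ] <- m
  }
  out
}
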