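#' Null-coalescing helper
#' @param a,b values; `b` when `a` is `NULL`
#' @return `a` unless it is `NULL`
#' @name null-coalesce
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Display rounding for percent cells: 0.5 always rounds up (base `round()`
#' rounds half to even).
#' @param x numeric
#' @param digits digits to keep
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Deterministic 31-bit sub-seed stream: keeps every derived seed in R's
## integer range regardless of the user's master seed.
derive_seed <- function(seed, i) {
  s <- (abs(as.numeric(seed)) %% 2147483647)
  as.integer((s * 48271 + (as.numeric(i) %% 65536) * 30269 + i) %% 2147483629 + 1)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

## ---- image resampling primitives (zero outside the support) --------------

## Bilinear sample of matrix `img` at continuous (row, col) positions.
sample_bilinear <- function(img, ys, xs) {
  h <- nrow(img); w <- ncol(img)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  val <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    out <- numeric(length(yy))
    out[ok] <- img[cbind(yy[ok], xx[ok])]
    out
  }
  val(y0, x0) * (1 - fy) * (1 - fx) +
    val(y0, x0 + 1) * (1 - fy) * fx +
    val(y0 + 1, x0) * fy * (1 - fx) +
    val(y0 + 1, x0 + 1) * fy * fx
}

sample_nearest <- function(img, ys, xs) {
  h <- nrow(img); w <- ncol(img)
  yy <- round(ys); xx <- round(xs)
  ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
  out <- numeric(length(yy))
  out[ok] <- img[cbind(yy[ok], xx[ok])]
  out
}

## Resize with pixel-center alignment (the scikit-image convention).
resize2d <- function(img, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  sy <- h / out_h; sx <- w / out_w
  ys <- (seq_len(out_h) - 0.5) * sy + 0.5
  xs <- (seq_len(out_w) - 0.5) * sx + 0.5
  yy <- rep(ys, times = out_w); xx <- rep(xs, each = out_h)
  v <- if (method == "bilinear") {
    ## clamp to border for resize (no zero halo at the frame)
    sample_bilinear(img, pmin(pmax(yy, 1), h), pmin(pmax(xx, 1), w))
  } else {
    sample_nearest(img, pmin(pmax(yy, 1), h), pmin(pmax(xx, 1), w))
  }
  matrix(v, out_h, out_w)
}

## Inverse-mapped affine resample: rotation (degrees, CCW) and zoom about the
## image center, optional additive displacement fields (elastic).
warp_affine <- function(img, rotate_deg = 0, zoom = 1, dy = NULL, dx = NULL,
                        method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- rep(seq_len(h), times = w) - cy
  xx <- rep(seq_len(w), each = h) - cx
  th <- -rotate_deg * pi / 180      # inverse rotation
  ys <- (cos(th) * yy - sin(th) * xx) / zoom + cy
  xs <- (sin(th) * yy + cos(th) * xx) / zoom + cx
  if (!is.null(dy)) ys <- ys + as.vector(dy)
  if (!is.null(dx)) xs <- xs + as.vector(dx)
  v <- if (method == "bilinear") sample_bilinear(img, ys, xs)
       else sample_nearest(img, ys, xs)
  matrix(v, h, w)
}

## Separable Gaussian blur, zero-padded borders.
gaussian_blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(0, h + 2 * r, w + 2 * r)
  pad[(r + 1):(r + h), (r + 1):(r + w)] <- img
  ## rows
  out <- matrix(0, h + 2 * r, w)
  for (j in seq_len(2 * r + 1))
    out <- out + k[j] * pad[, j:(j + w - 1)]
  out2 <- matrix(0, h, w)
  for (j in seq_len(2 * r + 1))
    out2 <- out2 + k[j] * out[j:(j + h - 1), ]
  out2
}
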