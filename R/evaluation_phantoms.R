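#' Specify a synthetic phantom
#'
#' Phantoms stand in for natural test images: piecewise-smooth scenes with
#' sharp structures whose ground truth is known exactly, so restoration
#' quality and constraint calibration can be measured without external data.
#' Four kinds are provided: `beads` (bright disks on a dark background,
#' emulating fluorescent microspheres), `filaments` (thin random-walk
#' curves, emulating cytoskeletal fibers), `blobs` (smoothed random fields,
#' emulating cell-like intensity patches) and `checkers` (alternating
#' squares, a worst case of sharp edges).
#'
#' @param kind One of `"beads"`, `"filaments"`, `"blobs"`, `"checkers"`.
#' @param shape Integer `c(height, width)`.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @param density Beads per 1000 pixels (beads) or filament count
#'   (filaments); ignored otherwise.
#' @param background Background intensity (0--255).
#' @param amplitude Peak foreground intensity (0--255).
#' @param block Square side for `checkers`.
#' @param smoothness Gaussian smoothing sigma for `blobs`, in pixels.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("beads", "filaments", "blobs", "checkers"),
                         shape = c(128L, 128L), seed = 1L,
                         density = 1.5, background = 20, amplitude = 230,
                         block = 8L, smoothness = NULL) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  if (is.null(smoothness)) smoothness <- max(2, min(shape) / 12)
  structure(list(kind = kind, shape = shape, seed = as.integer(seed),
                 density = density, background = background,
                 amplitude = amplitude, block = as.integer(block),
                 smoothness = smoothness),
            class = "phantom_spec")
}

#' Generate a synthetic phantom image
#'
#' @param spec A `phantom_spec` (or arguments forwarded to [phantom_spec()]).
#' @param ... Forwarded to [phantom_spec()] when `spec` is a kind string.
#' @return A numeric matrix with values in `[0, 255]`, deterministic given
#'   the spec.
#' @examples
#' x <- generate_phantom(phantom_spec("beads", c(64, 64), seed = 7))
#' range(x)
#' @export
generate_phantom <- function(spec, ...) {
  if (is.character(spec)) spec <- phantom_spec(spec, ...)
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$shape[1L]; w <- spec$shape[2L]
  img <- switch(spec$kind,
    checkers = phantom_checkers(h, w, spec$block, spec$background,
                                spec$amplitude),
    beads = with_seed(spec$seed, phantom_beads(h, w, spec$density,
                                               spec$background,
                                               spec$amplitude)),
    filaments = with_seed(spec$seed, phantom_filaments(h, w, spec$density,
                                                       spec$background,
                                                       spec$amplitude)),
    blobs = with_seed(spec$seed, phantom_blobs(h, w, spec$smoothness)),
    stop("unknown phantom kind '", spec$kind, "'", call. = FALSE)
  )
  pmin(pmax(img, 0), 255)
}

phantom_checkers <- function(h, w, block, lo, hi) {
  ri <- (seq_len(h) - 1L) %/% block
  ci <- (seq_len(w) - 1L) %/% block
  par <- outer(ri, ci, function(a, b) (a + b) %% 2L)
  lo + (hi - lo) * par
}

phantom_beads <- function(h, w, density, bg, amp) {
  img <- matrix(bg, h, w)
  n_beads <- max(0L, round(density * h * w / 1000))
  if (n_beads == 0L) return(img)
  cy <- stats::runif(n_beads, 1, h)
  cx <- stats::runif(n_beads, 1, w)
  rad <- stats::runif(n_beads, 2, max(3, min(h, w) / 25))
  val <- stats::runif(n_beads, 0.6 * amp, amp)
  rows <- seq_len(h); cols <- seq_len(w)
  for (i in seq_len(n_beads)) {
    d2 <- outer((rows - cy[i])^2, (cols - cx[i])^2, `+`)
    img[d2 <= rad[i]^2] <- pmax(img[d2 <= rad[i]^2], val[i])
  }
  img
}

phantom_filaments <- function(h, w, count, bg, amp) {
  img <- matrix(bg, h, w)
  count <- max(1L, round(count))
  steps <- 2L * max(h, w)
  for (i in seq_len(count)) {
    y <- stats::runif(1, 1, h); x <- stats::runif(1, 1, w)
    ang <- stats::runif(1, 0, 2 * pi)
    val <- stats::runif(1, 0.7 * amp, amp)
    for (s in seq_len(steps)) {
      ang <- ang + stats::rnorm(1, 0, 0.25)
      y <- y + sin(ang); x <- x + cos(ang)
      if (y < 1 || y > h || x < 1 || x > w) break
      yi <- round(y); xi <- round(x)
      for (dy in -1:1) for (dx in -1:1) {
        if (abs(dy) + abs(dx) <= 1L) {
          yy <- yi + dy; xx <- xi + dx
          if (yy >= 1L && yy <= h && xx >= 1L && xx <= w) {
            img[yy, xx] <- max(img[yy, xx], val)
          }
        }
      }
    }
  }
  img
}

phantom_blobs <- function(h, w, smoothness) {
  z <- matrix(stats::rnorm(h * w), h, w)
  op <- make_operator(gaussian_psf(smoothness), c(h, w))
  z <- blur_apply(op, z)
  rng <- range(z)
  30 + 195 * (z - rng[1L]) / max(rng[2L] - rng[1L], .Machine$double.eps)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in dB; identical images return `Inf`.
#'
#' @param x,ref Numeric matrices of the same shape.
#' @param peak Dynamic range (default 255, the intensity convention).
#' @return PSNR in dB.
#' @export
psnr <- function(x, ref, peak = 255) {
  if (!all(dim(x) == dim(ref))) stop("shape mismatch", call. = FALSE)
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# separable Gaussian filtering with half-sample-symmetric ("reflect")
# boundary padding, 11-tap window (sigma 1.5 truncated at 3.5 sigma)
ssim_filter <- function(m, kern) {
  r <- (length(kern) - 1L) / 2L
  pad_idx <- function(n) c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
  p <- m[pad_idx(nrow(m)), pad_idx(ncol(m)), drop = FALSE]
  out <- apply(p, 2L, function(col) as.numeric(
    stats::filter(col, kern, sides = 2L)))
  out <- t(apply(out, 1L, function(row) as.numeric(
    stats::filter(row, kern, sides = 2L))))
  out[r + seq_len(nrow(m)), r + seq_len(ncol(m)), drop = FALSE]
}

#' Structural similarity index
#'
#' Mean local SSIM with a Gaussian weighting window of 11 taps
#' (sigma = 1.5), constants `K1 = 0.01`, `K2 = 0.03`, sample-covariance
#' normalization, and the border (half a window) excluded from the average
#' -- the de-facto standard configuration.
#'
#' @param x,ref Numeric matrices of the same shape, min side >= 11.
#' @param peak Dynamic range (default 255).
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(x, ref, peak = 255) {
  if (!all(dim(x) == dim(ref))) stop("shape mismatch", call. = FALSE)
  win <- 11L
  if (min(dim(x)) < win) {
    stop("images must be at least ", win, " pixels per side", call. = FALSE)
  }
  sigma <- 1.5
  r <- (win - 1L) / 2L
  kern <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  c1 <- (0.01 * peak)^2
  c2 <- (0.03 * peak)^2
  np <- win^2
  cov_norm <- np / (np - 1)
  ux <- ssim_filter(x, kern)
  uy <- ssim_filter(ref, kern)
  uxx <- ssim_filter(x * x, kern)
  uyy <- ssim_filter(ref * ref, kern)
  uxy <- ssim_filter(x * ref, kern)
  vx <- cov_norm * (uxx - ux^2)
  vy <- cov_norm * (uyy - uy^2)
  vxy <- cov_norm * (uxy - ux * uy)
  s <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
    ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  core <- s[(r + 1L):(nrow(s) - r), (r + 1L):(ncol(s) - r), drop = FALSE]
  mean(core)
}
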