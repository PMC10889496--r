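#' Sample a normalized isotropic Gaussian point spread function
#'
#' Evaluates a discrete isotropic Gaussian on an odd-sided square grid,
#' truncates it at the grid boundary and renormalizes so the weights sum to
#' one. This is the blur kernel `A` of the degradation model `b = A x + eta`.
#'
#' @param sigma_a Standard deviation of the PSF in pixels (> 0).
#' @param size Odd side length of the kernel, or `"auto"` for the smallest
#'   odd integer >= `8 * sigma_a + 1` (about 4 sigma of support per side).
#' @return An object of class `psf_kernel`: a list with `weights` (a
#'   `size x size` matrix summing to 1) and `sigma_a`.
#' @examples
#' k <- gaussian_psf(0.8)
#' sum(k$weights)  # 1
#' @export
gaussian_psf <- function(sigma_a, size = "auto") {
  if (!is.numeric(sigma_a) || length(sigma_a) != 1L || !is.finite(sigma_a) ||
      sigma_a <= 0) {
    stop("`sigma_a` must be a single positive number", call. = FALSE)
  }
  if (identical(size, "auto")) {
    size <- ceiling(8 * sigma_a + 1)
    if (size %% 2L == 0L) size <- size + 1L
  }
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) {
    stop("`size` must be a positive odd integer", call. = FALSE)
  }
  half <- (size - 1L) / 2L
  g1 <- exp(-(seq(-half, half)^2) / (2 * sigma_a^2))
  w <- outer(g1, g1)
  w <- w / sum(w)
  structure(list(weights = w, sigma_a = sigma_a), class = "psf_kernel")
}

#' Delta (identity) kernel
#'
#' A degenerate PSF whose application leaves images unchanged; useful for
#' denoising-only problems and for testing.
#'
#' @param size Odd side length (default 1).
#' @return A `psf_kernel` with all mass at the center.
#' @export
delta_psf <- function(size = 1L) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) {
    stop("`size` must be a positive odd integer", call. = FALSE)
  }
  w <- matrix(0, size, size)
  w[(size + 1L) / 2L, (size + 1L) / 2L] <- 1
  structure(list(weights = w, sigma_a = 0), class = "psf_kernel")
}

# circular index shift: position i maps to i + s (mod n)
shift_index <- function(n, s) ((seq_len(n) - 1L + s) %% n) + 1L

#' Build the frequency-domain blur operator for a target image shape
#'
#' Embeds the (centered) kernel in an array of the image shape with periodic
#' wrap-around and takes its discrete Fourier transform, yielding the optical
#' transfer function (OTF). Application of the operator is then an exact
#' circular convolution, and `A' A` is diagonal in the Fourier basis --
#' the property that makes the CPnP x-update solvable in closed form.
#'
#' @param psf A `psf_kernel`, or a plain numeric matrix with odd side lengths
#'   used as a custom kernel.
#' @param shape Integer vector `c(height, width)` of the target images.
#' @return An object of class `blur_operator` with fields `otf` (complex
#'   matrix), `shape`, and `psf`.
#' @export
make_operator <- function(psf, shape) {
  if (is.matrix(psf) && is.numeric(psf)) {
    psf <- structure(list(weights = psf, sigma_a = NA_real_),
                     class = "psf_kernel")
  }
  stopifnot(inherits(psf, "psf_kernel"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) {
    stop("`shape` must be two positive integers", call. = FALSE)
  }
  w <- psf$weights
  if (nrow(w) > shape[1L] || ncol(w) > shape[2L]) {
    stop("kernel is larger than the image", call. = FALSE)
  }
  big <- matrix(0, shape[1L], shape[2L])
  big[seq_len(nrow(w)), seq_len(ncol(w))] <- w
  # shift so the kernel center sits at index (1, 1): periodic boundary
  cr <- (nrow(w) + 1L) / 2L
  cc <- (ncol(w) + 1L) / 2L
  big <- big[shift_index(shape[1L], cr - 1L), shift_index(shape[2L], cc - 1L),
             drop = FALSE]
  structure(list(otf = stats::fft(big), shape = shape, psf = psf),
            class = "blur_operator")
}

check_shape <- function(op, x) {
  if (!is.matrix(x) || !all(dim(x) == op$shape)) {
    stop("image shape does not match the operator (expected ",
         op$shape[1L], "x", op$shape[2L], ")", call. = FALSE)
  }
}

ifft_real <- function(z) Re(stats::fft(z, inverse = TRUE)) / length(z)

#' Apply the blur operator (circular convolution)
#'
#' @param op A `blur_operator`.
#' @param x A numeric matrix matching the operator shape.
#' @return The blurred image `A x`.
#' @export
blur_apply <- function(op, x) {
  check_shape(op, x)
  ifft_real(stats::fft(x) * op$otf)
}

#' Apply the adjoint of the blur operator (circular correlation)
#'
#' Satisfies `<A x, y> == <x, A' y>` for all images of matching shape.
#'
#' @param op A `blur_operator`.
#' @param y A numeric matrix matching the operator shape.
#' @return `A' y`.
#' @export
blur_adjoint <- function(op, y) {
  check_shape(op, y)
  ifft_real(stats::fft(y) * Conj(op$otf))
}

#' Simulate the degradation model b = A x + eta
#'
#' Blurs `x` with the Gaussian PSF of width `sigma_a` and adds i.i.d.
#' zero-mean Gaussian noise with standard deviation `sigma_eta` (on the
#' 0--255 intensity scale). No clipping is applied: clipping is a display
#' concern, the solvers operate on the unclipped model.
#'
#' @param x Ground-truth image (numeric matrix, 0--255 convention).
#' @param sigma_a PSF standard deviation in pixels (> 0); alternatively pass
#'   a prebuilt `blur_operator` via `op`.
#' @param sigma_eta Noise standard deviation (>= 0).
#' @param seed Integer RNG seed; the simulation is bit-reproducible given it.
#' @param op Optional `blur_operator` overriding `sigma_a`.
#' @return The degraded image `b`, a numeric matrix of the same shape.
#' @export
degrade <- function(x, sigma_a = 1, sigma_eta = 0, seed = 1L, op = NULL) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  if (sigma_eta < 0) stop("`sigma_eta` must be >= 0", call. = FALSE)
  if (is.null(op)) op <- make_operator(gaussian_psf(sigma_a), dim(x))
  b <- blur_apply(op, x)
  if (sigma_eta > 0) {
    eta <- with_seed(seed, matrix(stats::rnorm(length(x), 0, sigma_eta),
                                  nrow(x), ncol(x)))
    b <- b + eta
  }
  b
}

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Exact frequency-domain solve of the CPnP x-update
#'
#' Returns the unique minimizer of
#' `beta_r/2 ||A x - b - r + lam_r/beta_r||^2 + beta_v/2 ||x - v + lam_v/beta_v||^2`,
#' i.e. the solution of `((beta_r/beta_v) A'A + I) x = rhs` with
#' `rhs = (beta_r/beta_v) A'(b + r - lam_r/beta_r) + (v - lam_v/beta_v)`.
#' Because `A` is a circular convolution the system is diagonal in the
#' Fourier basis and is solved by pointwise division.
#'
#' @param op A `blur_operator`.
#' @param b,r,v,lam_r,lam_v Numeric matrices of the operator shape.
#' @param beta_r,beta_v Positive penalty parameters.
#' @return The minimizing image `x`.
#' @export
solve_x_update <- function(op, b, r, v, lam_r, lam_v, beta_r, beta_v) {
  if (!is.numeric(beta_r) || !is.numeric(beta_v) || beta_r <= 0 || beta_v <= 0) {
    stop("penalties `beta_r` and `beta_v` must be positive", call. = FALSE)
  }
  for (m in list(b, r, v, lam_r, lam_v)) check_shape(op, m)
  ratio <- beta_r / beta_v
  num <- ratio * Conj(op$otf) * stats::fft(b + r - lam_r / beta_r) +
    stats::fft(v - lam_v / beta_v)
  den <- ratio * Mod(op$otf)^2 + 1
  ifft_real(num / den)
}
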