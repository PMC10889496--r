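#' Tikhonov (quadratic) proximal denoiser
#'
#' Exact proximity operator of `(alpha/2) ||.||^2`: a rescaling
#' `u / (1 + alpha)`. As a plug-in denoiser it induces a quadratic implicit
#' prior, which makes the constrained solver's limit checkable against a
#' convex oracle.
#'
#' @param u Numeric matrix.
#' @param alpha Non-negative prox weight.
#' @return Denoised matrix.
#' @export
tikhonov_denoise <- function(u, alpha) {
  if (!is.numeric(alpha) || alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  u / (1 + alpha)
}

#' Soft-thresholding proximal denoiser
#'
#' Exact proximity operator of `t ||.||_1`:
#' `sign(u) * pmax(|u| - t, 0)` elementwise.
#'
#' @param u Numeric matrix.
#' @param t Non-negative threshold.
#' @return Denoised matrix.
#' @export
soft_threshold_denoise <- function(u, t) {
  if (!is.numeric(t) || t < 0) stop("`t` must be >= 0", call. = FALSE)
  sign(u) * pmax(abs(u) - t, 0)
}

# forward-difference gradient with Neumann boundary (last row/col zero)
tv_grad <- function(x) {
  gx <- rbind(x[-1L, , drop = FALSE], x[nrow(x), , drop = FALSE]) - x
  gy <- cbind(x[, -1L, drop = FALSE], x[, ncol(x), drop = FALSE]) - x
  list(gx = gx, gy = gy)
}

# negative adjoint of tv_grad (discrete divergence)
tv_div <- function(p1, p2) {
  n <- nrow(p1); m <- ncol(p1)
  dx <- p1
  dx[2:n, ] <- p1[2:n, , drop = FALSE] - p1[1:(n - 1L), , drop = FALSE]
  dx[n, ] <- -p1[n - 1L, ]
  dy <- p2
  dy[, 2:m] <- p2[, 2:m, drop = FALSE] - p2[, 1:(m - 1L), drop = FALSE]
  dy[, m] <- -p2[, m - 1L]
  dx + dy
}

#' Total-variation proximal denoiser
#'
#' Approximate proximity operator of `weight * TV(.)` (isotropic total
#' variation), computed with Chambolle's dual projection algorithm run until
#' the iterate changes by less than `tol` in relative l2 norm or `max_iter`
#' dual steps. TV denoising removes noise while preserving sharp edges,
#' which makes it the handcrafted prior of choice for piecewise-smooth
#' phantoms.
#'
#' @param u Numeric matrix.
#' @param weight Non-negative TV weight.
#' @param tol Relative-change stopping tolerance of the dual iteration.
#' @param max_iter Cap on dual iterations.
#' @return Denoised matrix.
#' @export
tv_denoise <- function(u, weight, tol = 1e-5, max_iter = 200L) {
  if (!is.numeric(weight) || weight < 0) stop("`weight` must be >= 0", call. = FALSE)
  if (weight == 0) return(u)
  p1 <- matrix(0, nrow(u), ncol(u))
  p2 <- p1
  step <- 0.248  # < 1/8, the dual step bound of the projection algorithm
  x_old <- u
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(u)
  for (k in seq_len(max_iter)) {
    d <- tv_div(p1, p2) - u / weight
    g <- tv_grad(d)
    den <- 1 + step * sqrt(g$gx^2 + g$gy^2)
    p1 <- (p1 + step * g$gx) / den
    p2 <- (p2 + step * g$gy) / den
    x <- u - weight * tv_div(p1, p2)
    if (sqrt(sum((x - x_old)^2)) <= tol * nu) {
      x_old <- x
      break
    }
    x_old <- x
  }
  x_old
}

box_filter <- function(m, k) {
  a <- stats::filter(m, rep(1 / k, k), circular = TRUE)
  a <- t(stats::filter(t(a), rep(1 / k, k), circular = TRUE))
  matrix(as.numeric(a), nrow(m), ncol(m))
}

circ_shift <- function(m, dr, dc) {
  m[shift_index(nrow(m), dr), shift_index(ncol(m), dc), drop = FALSE]
}

#' Non-local means denoiser
#'
#' Patch-based averaging: each pixel is replaced by a weighted mean of
#' pixels whose surrounding patches look similar, with weights
#' `exp(-max(d2 - 2 sigma^2, 0) / h^2)` where `d2` is the mean squared patch
#' difference, `sigma = strength` the assumed noise standard deviation
#' (0--255 scale) and `h = 0.75 * sigma` the filtering bandwidth. Patches
#' are `5 x 5`, the search window `11 x 11`, boundaries periodic.
#'
#' @param u Numeric matrix.
#' @param strength Assumed noise standard deviation (>= 0); 0 is identity.
#' @param patch_radius Patch half-width (default 2).
#' @param search_radius Search-window half-width (default 5).
#' @return Denoised matrix.
#' @export
nlm_denoise <- function(u, strength, patch_radius = 2L, search_radius = 5L) {
  if (!is.numeric(strength) || strength < 0) {
    stop("`strength` must be >= 0", call. = FALSE)
  }
  if (strength == 0) return(u)
  k <- 2L * patch_radius + 1L
  h2 <- (0.75 * strength)^2
  acc <- matrix(0, nrow(u), ncol(u))
  wsum <- acc
  for (dr in -search_radius:search_radius) {
    for (dc in -search_radius:search_radius) {
      us <- circ_shift(u, dr, dc)
      d2 <- box_filter((u - us)^2, k)
      w <- exp(-pmax(d2 - 2 * strength^2, 0) / h2)
      acc <- acc + w * us
      wsum <- wsum + w
    }
  }
  acc / wsum
}

#' BM3D denoiser plugin point
#'
#' Block-matching and 3D collaborative filtering is not bundled; this entry
#' dispatches to a backend registered with [register_denoiser_backend()]
#' under the name `"bm3d"` and raises an unavailable-denoiser error when no
#' backend is present.
#'
#' @param u Numeric matrix.
#' @param strength Assumed noise standard deviation (>= 0).
#' @return Denoised matrix from the registered backend.
#' @export
bm3d_denoise <- function(u, strength) {
  fn <- plugin_backend("bm3d")
  if (is.null(fn)) {
    stop("denoiser 'bm3d' is unavailable: register a BM3D backend with ",
         "register_denoiser_backend(\"bm3d\", fn)", call. = FALSE)
  }
  fn(u, strength)
}

# environment holding user-registered denoiser backends
.denoiser_plugins <- new.env(parent = emptyenv())

plugin_backend <- function(name) {
  if (exists(name, envir = .denoiser_plugins, inherits = FALSE)) {
    get(name, envir = .denoiser_plugins)
  } else {
    NULL
  }
}

#' Register a learned or external denoiser backend
#'
#' Installs a function `fn(u, strength)` under `name` so that
#' `make_denoiser(name)` (and the `bm3d`/`dncnn-plugin` entries) can use it.
#' The callable must be shape-preserving, return finite values, and be
#' deterministic for fixed input and strength.
#'
#' @param name Backend identifier (e.g. `"bm3d"`, `"dncnn-plugin"`).
#' @param fn Function of `(u, strength)` returning a matrix like `u`.
#' @return `name`, invisibly.
#' @export
register_denoiser_backend <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .denoiser_plugins)
  invisible(name)
}

denoiser_names <- c("tikhonov", "soft_threshold", "tv", "nlm", "bm3d",
                    "dncnn-plugin", "identity")

#' Construct a configured denoiser
#'
#' Returns a `denoiser` object bundling a name, a strength parameter (its
#' meaning depends on the denoiser: prox weight for `tikhonov`, threshold
#' for `soft_threshold`, TV weight for `tv`, assumed noise standard
#' deviation for `nlm`/`bm3d`) and a per-iteration strength schedule.
#'
#' With `schedule = "fixed"` the same strength is used at every solver
#' iteration. With `schedule = "scaled"` the strength applied at penalty
#' `beta_v` is `strength / sqrt(beta_v / beta_v0)`, consistent with the
#' denoiser standing in for the proximal map of the implicit prior under a
#' growing penalty.
#'
#' @param name One of `"tikhonov"`, `"soft_threshold"`, `"tv"`, `"nlm"`,
#'   `"bm3d"`, `"dncnn-plugin"`, `"identity"`.
#' @param strength Non-negative strength parameter.
#' @param schedule `"fixed"` or `"scaled"`.
#' @param ... Extra arguments passed to the underlying denoiser (e.g.
#'   `patch_radius` for `nlm`, `max_iter` for `tv`).
#' @return An object of class `denoiser`.
#' @export
make_denoiser <- function(name, strength = 0, schedule = c("fixed", "scaled"),
                          ...) {
  schedule <- match.arg(schedule)
  if (!is.character(name) || length(name) != 1L || !(name %in% denoiser_names)) {
    stop("unknown denoiser '", name, "'; available: ",
         paste(denoiser_names, collapse = ", "), call. = FALSE)
  }
  extra <- list(...)
  fn <- switch(name,
    tikhonov = function(u, s) tikhonov_denoise(u, s),
    soft_threshold = function(u, s) soft_threshold_denoise(u, s),
    tv = function(u, s) do.call(tv_denoise, c(list(u, s), extra)),
    nlm = function(u, s) do.call(nlm_denoise, c(list(u, s), extra)),
    bm3d = function(u, s) bm3d_denoise(u, s),
    "dncnn-plugin" = function(u, s) {
      backend <- plugin_backend("dncnn-plugin")
      if (is.null(backend)) {
        stop("denoiser 'dncnn-plugin' is unavailable: register a trained ",
             "backend with register_denoiser_backend(\"dncnn-plugin\", fn)",
             call. = FALSE)
      }
      backend(u, s)
    },
    identity = function(u, s) u
  )
  structure(list(name = name, strength = strength, schedule = schedule,
                 fn = fn),
            class = "denoiser")
}

#' Apply a denoiser, honoring its strength schedule
#'
#' @param D A `denoiser`.
#' @param u Numeric matrix.
#' @param beta_v,beta_v0 Current and initial quadratic penalty; only used by
#'   the `"scaled"` schedule.
#' @return Denoised matrix, same shape as `u`.
#' @export
apply_denoiser <- function(D, u, beta_v = 1, beta_v0 = 1) {
  stopifnot(inherits(D, "denoiser"))
  s <- D$strength
  if (identical(D$schedule, "scaled")) s <- s / sqrt(beta_v / beta_v0)
  out <- D$fn(u, s)
  if (!is.matrix(out) || !all(dim(out) == dim(u)) || !all(is.finite(out))) {
    stop("denoiser '", D$name,
         "' violated its contract (shape or finiteness)", call. = FALSE)
  }
  out
}

#' @export
print.denoiser <- function(x, ...) {
  cat("<denoiser>", x$name, " strength =", x$strength,
      " schedule =", x$schedule, "\n")
  invisible(x)
}
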