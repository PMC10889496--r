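#' Solver configuration
#'
#' Bundles the ADMM penalty initialization and schedule with the stopping
#' rule shared by all solvers. Defaults follow the calibrated regime:
#' `beta_r0 = beta_v0 = 1`, growth factor `gamma = 1.01` applied to both
#' penalties every iteration, relative-change tolerance `1e-4` and at most
#' 100 iterations.
#'
#' @param beta_r0,beta_v0 Initial penalties (> 0).
#' @param gamma Penalty growth factor (>= 1).
#' @param tol Relative-change stopping tolerance (> 0).
#' @param max_iter Iteration cap (>= 1).
#' @param x0 Optional starting image; defaults to the degraded data `b`.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(beta_r0 = 1, beta_v0 = 1, gamma = 1.01,
                          tol = 1e-4, max_iter = 100L, x0 = NULL) {
  if (beta_r0 <= 0 || beta_v0 <= 0) stop("penalties must be > 0", call. = FALSE)
  if (gamma < 1) stop("`gamma` must be >= 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  structure(list(beta_r0 = beta_r0, beta_v0 = beta_v0, gamma = gamma,
                 tol = tol, max_iter = max_iter, x0 = x0),
            class = "solver_config")
}

check_finite_step <- function(m, step) {
  if (!all(is.finite(m))) {
    stop("numerical failure: non-finite values produced in step '", step, "'",
         call. = FALSE)
  }
  m
}

#' Initialize the CPnP solver state
#'
#' Starts from `x0 = b` (unless overridden), `v0 = 0`, zero multipliers, and
#' a feasible slack `r0 = proj(A x0 - b)` onto the constraint ball.
#'
#' @param b Degraded image.
#' @param op A `blur_operator`.
#' @param constraint A `constraint_spec`.
#' @param cfg A `solver_config`.
#' @return A `solver_state` list with fields `x`, `v`, `r`, `lam_r`,
#'   `lam_v`, `beta_r`, `beta_v`, `beta_r0`, `beta_v0`, `k`.
#' @export
cpnp_init <- function(b, op, constraint, cfg = solver_config()) {
  check_shape(op, b)
  x0 <- if (is.null(cfg$x0)) b else cfg$x0
  check_shape(op, x0)
  zero <- matrix(0, nrow(b), ncol(b))
  r0 <- project_residual(blur_apply(op, x0) - b, constraint$radius)
  structure(list(x = x0, v = zero, r = r0, lam_r = zero, lam_v = zero,
                 beta_r = cfg$beta_r0, beta_v = cfg$beta_v0,
                 beta_r0 = cfg$beta_r0, beta_v0 = cfg$beta_v0, k = 0L),
            class = "solver_state")
}

#' One CPnP sweep
#'
#' Performs a single iteration of the constrained plug-and-play ADMM:
#' \enumerate{
#'   \item x-update: exact frequency-domain solve of the coupled quadratic
#'     (see [solve_x_update()]);
#'   \item v-update: `v = D(x + lam_v / beta_v)`, the denoiser standing in
#'     for the proximal map of the implicit prior;
#'   \item r-update: `r = proj_ball(A x - b + lam_r / beta_r)` onto the
#'     residual ball of radius `R = tau sqrt(n) sigma_eta`;
#'   \item dual ascent: `lam_r <- lam_r + beta_r (A x - b - r)`,
#'     `lam_v <- lam_v + beta_v (x - v)`.
#' }
#' Penalties are not changed here; see [update_penalties()].
#'
#' @param state A `solver_state`.
#' @param op A `blur_operator`.
#' @param b Degraded image.
#' @param constraint A `constraint_spec`.
#' @param D A `denoiser`.
#' @return The updated `solver_state` with `k` incremented.
#' @export
cpnp_step <- function(state, op, b, constraint, D) {
  x <- solve_x_update(op, b, state$r, state$v, state$lam_r, state$lam_v,
                      state$beta_r, state$beta_v)
  check_finite_step(x, "x-update")
  v <- apply_denoiser(D, x + state$lam_v / state$beta_v,
                      beta_v = state$beta_v, beta_v0 = state$beta_v0)
  check_finite_step(v, "v-update")
  ax <- blur_apply(op, x)
  r <- project_residual(ax - b + state$lam_r / state$beta_r,
                        constraint$radius)
  check_finite_step(r, "r-update")
  lam_r <- state$lam_r + state$beta_r * (ax - b - r)
  lam_v <- state$lam_v + state$beta_v * (x - v)
  check_finite_step(lam_r, "dual-update")
  check_finite_step(lam_v, "dual-update")
  state$x <- x; state$v <- v; state$r <- r
  state$lam_r <- lam_r; state$lam_v <- lam_v
  state$k <- state$k + 1L
  state
}

#' Grow the ADMM penalties
#'
#' Multiplies both penalties by `gamma` (>= 1), leaving the (unscaled)
#' multipliers unchanged.
#'
#' @param state A `solver_state`.
#' @param gamma Growth factor (>= 1).
#' @return The updated state.
#' @export
update_penalties <- function(state, gamma) {
  if (!is.numeric(gamma) || gamma < 1) {
    stop("`gamma` must be >= 1", call. = FALSE)
  }
  state$beta_r <- state$beta_r * gamma
  state$beta_v <- state$beta_v * gamma
  state
}

new_restoration_result <- function(x_star, history, converged, method, op, b,
                                   denoiser = NULL, config = NULL) {
  structure(list(
    x_star = x_star,
    iterations = nrow(history),
    converged = converged,
    history = history,
    sigma_x_star = residual_sigma(op, x_star, b),
    method = method,
    denoiser = denoiser,
    config = config
  ), class = "restoration_result")
}

#' @export
print.restoration_result <- function(x, ...) {
  cat("<restoration_result> method =", x$method,
      if (!is.null(x$denoiser)) paste0("denoiser = ", x$denoiser), "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  cat("  sigma_x*: ", format(x$sigma_x_star, digits = 6), "\n")
  invisible(x)
}

#' Constrained plug-and-play restoration (CPnP)
#'
#' Runs the full constrained ADMM: repeated [cpnp_step()] sweeps with both
#' penalties multiplied by `cfg$gamma` after every iteration, stopping when
#' the relative change `||x_{k+1} - x_k|| / max(||x_k||, eps)` drops below
#' `cfg$tol` or `cfg$max_iter` is reached. The run is deterministic: no
#' internal randomness.
#'
#' @param b Degraded image (numeric matrix, 0--255 convention).
#' @param op A `blur_operator`.
#' @param constraint A `constraint_spec` (see [make_constraint()]).
#' @param D A `denoiser` (see [make_denoiser()]).
#' @param cfg A `solver_config`.
#' @return A `restoration_result` with the restored image `x_star`, a
#'   per-iteration `history` data frame (relative change, residual norm,
#'   `sigma_x`, penalties) and the final discrepancy statistic
#'   `sigma_x_star`.
#' @export
cpnp_restore <- function(b, op, constraint, D, cfg = solver_config()) {
  stopifnot(inherits(constraint, "constraint_spec"), inherits(D, "denoiser"),
            inherits(cfg, "solver_config"))
  state <- cpnp_init(b, op, constraint, cfg)
  eps <- 1e-12
  hist <- vector("list", cfg$max_iter)
  converged <- FALSE
  for (k in seq_len(cfg$max_iter)) {
    x_prev <- state$x
    state <- cpnp_step(state, op, b, constraint, D)
    rel <- sqrt(sum((state$x - x_prev)^2)) / max(sqrt(sum(x_prev^2)), eps)
    resid <- sqrt(sum((blur_apply(op, state$x) - b)^2))
    hist[[k]] <- data.frame(
      iter = k, rel_change = rel, residual_norm = resid,
      sigma_x = resid / sqrt(length(b) - 1),
      beta_r = state$beta_r, beta_v = state$beta_v
    )
    state <- update_penalties(state, cfg$gamma)
    if (rel <= cfg$tol) {
      converged <- TRUE
      break
    }
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1L))])
  new_restoration_result(state$x, history, converged, "cpnp", op, b,
                         denoiser = D$name, config = cfg)
}

#' Unconstrained plug-and-play baseline via half-quadratic splitting
#'
#' Solves the unconstrained model `min 1/2 ||A x - b||^2 + mu rho(x)` with
#' the HQS alternation: an exact frequency-domain quadratic data-fit solve
#' `x = (A'A + beta I)^{-1} (A'b + beta z)` followed by the denoising step
#' `z = D(x)`. The penalty `beta` plays the role of the (inverse) prior
#' weight: with a proximal denoiser of weight `alpha` the fixed point solves
#' the quadratic model at effective weight `beta * alpha / (1 + alpha)`.
#'
#' @param b Degraded image.
#' @param op A `blur_operator`.
#' @param D A `denoiser`.
#' @param mu_schedule Penalty `beta` per iteration: a scalar (grown by
#'   `cfg$gamma` each iteration) or a numeric vector (last value reused
#'   beyond its length).
#' @param cfg A `solver_config` (its `beta_*` fields are ignored).
#' @return A `restoration_result` (method `"pnp-hqs"`).
#' @export
pnp_hqs_restore <- function(b, op, D, mu_schedule = 1, cfg = solver_config()) {
  stopifnot(inherits(D, "denoiser"), inherits(cfg, "solver_config"))
  check_shape(op, b)
  if (any(mu_schedule <= 0)) stop("penalties must be > 0", call. = FALSE)
  eps <- 1e-12
  x <- if (is.null(cfg$x0)) b else cfg$x0
  z <- x
  bhat_a <- Conj(op$otf) * stats::fft(b)
  a2 <- Mod(op$otf)^2
  hist <- vector("list", cfg$max_iter)
  converged <- FALSE
  beta1 <- mu_schedule[1L]
  for (k in seq_len(cfg$max_iter)) {
    beta <- if (length(mu_schedule) > 1L) {
      mu_schedule[min(k, length(mu_schedule))]
    } else {
      mu_schedule * cfg$gamma^(k - 1L)
    }
    x_prev <- x
    x <- ifft_real((bhat_a + beta * stats::fft(z)) / (a2 + beta))
    check_finite_step(x, "x-update")
    z <- apply_denoiser(D, x, beta_v = beta, beta_v0 = beta1)
    check_finite_step(z, "denoise")
    rel <- sqrt(sum((x - x_prev)^2)) / max(sqrt(sum(x_prev^2)), eps)
    resid <- sqrt(sum((blur_apply(op, x) - b)^2))
    hist[[k]] <- data.frame(
      iter = k, rel_change = rel, residual_norm = resid,
      sigma_x = resid / sqrt(length(b) - 1), beta_r = NA_real_, beta_v = beta
    )
    if (rel <= cfg$tol) {
      converged <- TRUE
      break
    }
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1L))])
  new_restoration_result(x, history, converged, "pnp-hqs", op, b,
                         denoiser = D$name, config = cfg)
}

#' Regularization-by-denoising baseline solved by ADMM
#'
#' Minimizes `1/2 ||A x - b||^2 + mu/2 x'(x - D(x))`, the explicit
#' denoiser-induced prior, by ADMM on the split `x = v`. The x-subproblem is
#' the exact frequency-domain solve; the v-subproblem uses the fixed-point
#' iteration `v <- (beta (x + lam/beta) + mu D(v)) / (beta + mu)` run
#' `inner_steps` times (1 is standard).
#'
#' @param b Degraded image.
#' @param op A `blur_operator`.
#' @param D A `denoiser`.
#' @param mu Prior weight (> 0).
#' @param cfg A `solver_config`; `beta_v0` seeds the ADMM penalty, grown by
#'   `gamma` each iteration.
#' @param inner_steps Fixed-point iterations for the v-subproblem (>= 1).
#' @return A `restoration_result` (method `"red-admm"`).
#' @export
red_admm_restore <- function(b, op, D, mu, cfg = solver_config(),
                             inner_steps = 1L) {
  stopifnot(inherits(D, "denoiser"), inherits(cfg, "solver_config"))
  check_shape(op, b)
  if (!is.numeric(mu) || mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  eps <- 1e-12
  x <- if (is.null(cfg$x0)) b else cfg$x0
  v <- x
  lam <- matrix(0, nrow(b), ncol(b))
  beta <- cfg$beta_v0
  bhat_a <- Conj(op$otf) * stats::fft(b)
  a2 <- Mod(op$otf)^2
  hist <- vector("list", cfg$max_iter)
  converged <- FALSE
  for (k in seq_len(cfg$max_iter)) {
    x_prev <- x
    x <- ifft_real((bhat_a + stats::fft(beta * v - lam)) / (a2 + beta))
    check_finite_step(x, "x-update")
    xt <- x + lam / beta
    for (j in seq_len(inner_steps)) {
      v <- (beta * xt + mu * apply_denoiser(D, v, beta_v = beta,
                                            beta_v0 = cfg$beta_v0)) /
        (beta + mu)
    }
    check_finite_step(v, "v-update")
    lam <- lam + beta * (x - v)
    rel <- sqrt(sum((x - x_prev)^2)) / max(sqrt(sum(x_prev^2)), eps)
    resid <- sqrt(sum((blur_apply(op, x) - b)^2))
    hist[[k]] <- data.frame(
      iter = k, rel_change = rel, residual_norm = resid,
      sigma_x = resid / sqrt(length(b) - 1), beta_r = NA_real_, beta_v = beta
    )
    beta <- beta * cfg$gamma
    if (rel <= cfg$tol) {
      converged <- TRUE
      break
    }
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1L))])
  new_restoration_result(x, history, converged, "red-admm", op, b,
                         denoiser = D$name, config = cfg)
}
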