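test_that("one cpnp_step matches an independent straight-line transcription", {
  set.seed(9)
  op <- make_operator(gaussian_psf(0.9, 3), c(4, 4))
  A <- dense_operator(op)
  x_gt <- matrix(stats::runif(16, 0, 255), 4, 4)
  b <- degrade(x_gt, sigma_eta = 5, seed = 2, op = op)
  C <- make_constraint(1, 5, 16)
  cfg <- solver_config(beta_r0 = 0.7, beta_v0 = 1.3)
  D <- make_denoiser("tikhonov", 0.4)
  st <- cpnp_init(b, op, C, cfg)
  out <- cpnp_step(st, op, b, C, D)

  # independent transcription with dense algebra
  br <- 0.7; bv <- 1.3
  bvec <- as.vector(b)
  v0 <- rep(0, 16); lr <- rep(0, 16); lv <- rep(0, 16)
  r0v <- as.vector(st$r)
  rhs <- (br / bv) * (t(A) %*% (bvec + r0v - lr / br)) + (v0 - lv / bv)
  x1 <- solve((br / bv) * crossprod(A) + diag(16), rhs)
  v1 <- (x1 + lv / bv) / (1 + 0.4)
  ax <- A %*% x1
  z <- ax - bvec + lr / br
  nz <- sqrt(sum(z^2))
  r1 <- if (nz <= C$radius) z else z * C$radius / nz
  lr1 <- lr + br * (ax - bvec - r1)
  lv1 <- lv + bv * (x1 - v1)

  expect_equal(as.vector(out$x), as.vector(x1), tolerance = 1e-10)
  expect_equal(as.vector(out$v), as.vector(v1), tolerance = 1e-10)
  expect_equal(as.vector(out$r), as.vector(r1), tolerance = 1e-10)
  expect_equal(as.vector(out$lam_r), as.vector(lr1), tolerance = 1e-10)
  expect_equal(as.vector(out$lam_v), as.vector(lv1), tolerance = 1e-10)
  expect_identical(out$k, 1L)
})

test_that("identity operator + identity denoiser at x = v = b is a fixed point", {
  op <- make_operator(delta_psf(), c(8, 8))
  b <- random_image(8, 8, 3)
  C <- make_constraint(1, 10, 64)
  st <- cpnp_init(b, op, C, solver_config())
  st$v <- b  # the fixed-point state: x = v = b, r = Ax - b = 0, zero duals
  out <- cpnp_step(st, op, b, C, make_denoiser("identity"))
  expect_equal(out$x, b, tolerance = 1e-10)
  expect_equal(out$v, b, tolerance = 1e-10)
  expect_equal(out$r, matrix(0, 8, 8), tolerance = 1e-10)
  expect_equal(out$lam_r, matrix(0, 8, 8), tolerance = 1e-10)
})

test_that("radius 0 forces data consistency on a full-rank instance", {
  op <- make_operator(gaussian_psf(0.6, 5), c(16, 16))
  x_gt <- generate_phantom(phantom_spec("checkers", c(16, 16), block = 4))
  b <- blur_apply(op, x_gt)
  res <- cpnp_restore(b, op, make_constraint(0, 15, 256),
                      make_denoiser("tikhonov", 0.05),
                      solver_config(gamma = 1, tol = 1e-13, max_iter = 4000))
  expect_lt(residual_norm(op, res$x_star, b) / sqrt(sum(b^2)), 1e-4)
})

test_that("update_penalties multiplies both penalties by gamma", {
  op <- make_operator(delta_psf(), c(4, 4))
  st <- cpnp_init(matrix(1, 4, 4), op, make_constraint(1, 1, 16),
                  solver_config(beta_r0 = 0.2, beta_v0 = 0.8))
  expect_equal(update_penalties(st, 1)[c("beta_r", "beta_v")],
               list(beta_r = 0.2, beta_v = 0.8))
  st2 <- update_penalties(st, 1.05)
  expect_equal(st2$beta_r, 0.21)
  expect_equal(st2$beta_v, 0.84)
  for (i in 1:100) st <- update_penalties(st, 1.01)
  expect_equal(st$beta_r / 0.2, 1.01^100, tolerance = 1e-12)
  expect_error(update_penalties(st, 0.9), ">= 1")
})

test_that("cpnp_restore honors the stopping contract and records diagnostics", {
  x <- generate_phantom(phantom_spec("blobs", c(32, 32), seed = 1))
  op <- make_operator(gaussian_psf(1), c(32, 32))
  b <- degrade(x, 1, 10, seed = 2, op = op)
  C <- make_constraint(1, 10, length(b))
  D <- make_denoiser("tv", 2)
  one <- cpnp_restore(b, op, C, D, solver_config(max_iter = 1))
  expect_identical(one$iterations, 1L)
  expect_false(one$converged)
  full <- cpnp_restore(b, op, C, D, solver_config())
  expect_identical(nrow(full$history), full$iterations)
  expect_true(all(c("rel_change", "residual_norm", "sigma_x", "beta_r",
                    "beta_v") %in% names(full$history)))
  expect_equal(full$sigma_x_star, residual_sigma(op, full$x_star, b))
  expect_true(all(is.finite(full$x_star)))
  # sigma_x history equals residual_norm / sqrt(n - 1) by construction
  expect_equal(full$history$sigma_x,
               full$history$residual_norm / sqrt(length(b) - 1))
})

test_that("restoration runs are deterministic (bit-identical results)", {
  x <- generate_phantom(phantom_spec("beads", c(32, 32), seed = 5))
  op <- make_operator(gaussian_psf(1), c(32, 32))
  b <- degrade(x, 1, 15, seed = 6, op = op)
  C <- make_constraint(1, 15, length(b))
  D <- make_denoiser("tv", 3)
  r1 <- cpnp_restore(b, op, C, D, solver_config(max_iter = 15))
  r2 <- cpnp_restore(b, op, C, D, solver_config(max_iter = 15))
  expect_identical(r1$x_star, r2$x_star)
  expect_identical(r1$history, r2$history)
})

test_that("CPnP with the Tikhonov denoiser reaches the constrained-quadratic
           oracle on a small instance", {
  x <- generate_phantom(phantom_spec("checkers", c(16, 16), block = 4))
  op <- make_operator(gaussian_psf(1, 9), c(16, 16))
  b <- degrade(x, 1, 15, seed = 5, op = op)
  C <- make_constraint(1, 15, length(b))
  x_or <- tikhonov_constrained_oracle(op, b, C$radius)
  res <- cpnp_restore(b, op, C, make_denoiser("tikhonov", 1),
                      solver_config(gamma = 1, tol = 1e-12, max_iter = 3000))
  expect_lt(rel_l2(res$x_star, x_or), 1e-3)
  # the constraint is active: residual on the ball boundary
  expect_equal(residual_norm(op, res$x_star, b) / C$radius, 1,
               tolerance = 1e-3)
})

test_that("pnp_hqs with a quadratic prox matches the Tikhonov-deblur closed form", {
  x <- generate_phantom(phantom_spec("blobs", c(32, 32), seed = 2))
  op <- make_operator(gaussian_psf(1.2), c(32, 32))
  b <- degrade(x, 1.2, 10, seed = 4, op = op)
  alpha <- 0.5; beta <- 2
  res <- pnp_hqs_restore(b, op, make_denoiser("tikhonov", alpha),
                         mu_schedule = beta,
                         cfg = solver_config(gamma = 1, tol = 1e-12,
                                             max_iter = 3000))
  # fixed point solves (A'A + w I) x = A'b with w = beta * alpha / (1 + alpha)
  w <- beta * alpha / (1 + alpha)
  n <- length(b)
  xcf <- Re(stats::fft(Conj(op$otf) * stats::fft(b) / (Mod(op$otf)^2 + w),
                       inverse = TRUE)) / n
  expect_lt(rel_l2(res$x_star, xcf), 1e-6)
})

test_that("pnp_hqs with identity operator and denoiser converges to b", {
  op <- make_operator(delta_psf(), c(8, 8))
  b <- random_image(8, 8, 9)
  res <- pnp_hqs_restore(b, op, make_denoiser("identity"), mu_schedule = 1,
                         cfg = solver_config(gamma = 1))
  expect_equal(res$x_star, b, tolerance = 1e-8)
})

test_that("grid-tuned pnp_hqs lands within 1 dB of CPnP on a matched task", {
  x <- generate_phantom(phantom_spec("blobs", c(32, 32), seed = 6))
  op <- make_operator(gaussian_psf(1), c(32, 32))
  b <- degrade(x, 1, 15, seed = 3, op = op)
  D <- make_denoiser("tv", 2)
  p_cpnp <- psnr(cpnp_restore(b, op, make_constraint(1, 15, length(b)), D,
                              solver_config())$x_star, x)
  p_hqs <- max(vapply(c(0.5, 1, 2, 5, 10), function(mu) {
    psnr(pnp_hqs_restore(b, op, D, mu_schedule = mu,
                         cfg = solver_config(gamma = 1))$x_star, x)
  }, numeric(1L)))
  expect_lt(abs(p_cpnp - p_hqs), 1)
})

test_that("red_admm with a quadratic denoiser matches its closed form", {
  x <- generate_phantom(phantom_spec("blobs", c(32, 32), seed = 2))
  op <- make_operator(gaussian_psf(1.2), c(32, 32))
  b <- degrade(x, 1.2, 10, seed = 4, op = op)
  mu <- 3; alpha <- 0.7
  res <- red_admm_restore(b, op, make_denoiser("tikhonov", alpha), mu = mu,
                          cfg = solver_config(gamma = 1, tol = 1e-12,
                                              max_iter = 5000),
                          inner_steps = 30)
  # RED prior with D = u/(1+a) is (a/(1+a)) ||x||^2 / 2
  cc <- mu * alpha / (1 + alpha)
  n <- length(b)
  xcf <- Re(stats::fft(Conj(op$otf) * stats::fft(b) / (Mod(op$otf)^2 + cc),
                       inverse = TRUE)) / n
  expect_lt(rel_l2(res$x_star, xcf), 1e-6)
})

test_that("red_admm with the identity denoiser reduces to least squares", {
  op <- make_operator(gaussian_psf(0.6, 5), c(16, 16))
  x_gt <- generate_phantom(phantom_spec("checkers", c(16, 16), block = 4))
  b <- blur_apply(op, x_gt)
  res <- red_admm_restore(b, op, make_denoiser("identity"), mu = 1e-6,
                          cfg = solver_config(gamma = 1, tol = 1e-14,
                                              max_iter = 3000))
  expect_lt(residual_norm(op, res$x_star, b) / sqrt(sum(b^2)), 1e-8)
  expect_s3_class(res, "restoration_result")
  expect_identical(res$method, "red-admm")
})

test_that("solver_config validates its fields", {
  expect_error(solver_config(beta_r0 = 0), "> 0")
  expect_error(solver_config(gamma = 0.5), ">= 1")
  expect_error(solver_config(tol = 0), "> 0")
  expect_error(solver_config(max_iter = 0), ">= 1")
})
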