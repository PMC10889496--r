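# Shared fixtures and independent oracles used across test files.

# Dense matrix realization of a blur operator, assembled column by column
# by applying the operator to canonical basis images. Used as the oracle
# for circulant structure, adjoints and the frequency-domain x-update.
dense_operator <- function(op) {
  n <- prod(op$shape)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- matrix(0, op$shape[1L], op$shape[2L])
    e[j] <- 1
    A[, j] <- as.vector(blur_apply(op, e))
  }
  A
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

residual_norm <- function(op, x, b) sqrt(sum((blur_apply(op, x) - b)^2))

random_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(stats::rnorm(h * w, 100, 40), h, w)
}

# Constrained quadratic oracle: min ||x||^2 s.t. ||Ax - b|| <= R, solved by
# dense SVD plus bisection on the Lagrange multiplier of the residual term.
# Entirely independent of the ADMM path it is used to check.
tikhonov_constrained_oracle <- function(op, b, radius, tol = 1e-6) {
  A <- dense_operator(op)
  sv <- svd(A)
  bt <- crossprod(sv$u, as.vector(b))
  resid_of <- function(mu) {
    coef <- mu * sv$d / (mu * sv$d^2 + 1)
    sqrt(sum(((sv$d * coef - 1) * bt)^2))
  }
  lo <- 1e-10; hi <- 1e10
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (resid_of(mid) > radius) lo <- mid else hi <- mid
    if (hi / lo < 1 + tol * 1e-3) break
  }
  mu <- sqrt(lo * hi)
  coef <- mu * sv$d / (mu * sv$d^2 + 1)
  matrix(sv$v %*% (coef * bt), op$shape[1L], op$shape[2L])
}

# Constrained l1 oracle: min ||x||_1 s.t. ||Ax - b|| <= R, solved by FISTA
# (accelerated proximal gradient, an algorithm family disjoint from ADMM)
# on the penalized form with bisection on the data weight.
l1_constrained_oracle <- function(op, b, radius, bisect_steps = 50,
                                  final_iters = 20000) {
  fista <- function(mu, x0, iters) {
    L <- mu  # the normalized kernel has unit spectral norm
    xk <- x0; yk <- x0; tk <- 1
    for (i in seq_len(iters)) {
      g <- mu * blur_adjoint(op, blur_apply(op, yk) - b)
      xn <- soft_threshold_denoise(yk - g / L, 1 / L)
      tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
      yk <- xn + ((tk - 1) / tn) * (xn - xk)
      xk <- xn; tk <- tn
    }
    xk
  }
  lo <- 1e-6; hi <- 1e4; x0 <- b
  for (i in seq_len(bisect_steps)) {
    mid <- sqrt(lo * hi)
    xm <- fista(mid, x0, 300)
    if (residual_norm(op, xm, b) > radius) lo <- mid else hi <- mid
    x0 <- xm
  }
  fista(sqrt(lo * hi), x0, final_iters)
}
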