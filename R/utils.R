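# Shared helpers: seeded RNG scoping, vector frames, weighted ECDF tests.

# Evaluate code under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr::with_seed(as.integer(seed), code)
}

# One RNG stream per pipeline stage: stage seeds derive from the master seed
# by fixed affine hashing modulo 2^31 - 1, so changing one stage's settings
# never perturbs another stage's draws.
.STAGES <- c(emission = 1L, detection = 2L, lut = 3L, dispersion = 4L,
             scatter = 5L, survival = 6L)

derive_seed <- function(seed, stage) {
  k <- .STAGES[[stage]]
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

# Orthonormal basis (e1, e2) perpendicular to a unit vector v.
perp_basis <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Deflect unit vectors (matrix n x 3) by independent Gaussian angles of width
# sigma (vector) in two transverse directions.
smear_directions <- function(dirs, sigma) {
  n <- nrow(dirs)
  t1 <- rnorm(n, 0, 1) * sigma
  t2 <- rnorm(n, 0, 1) * sigma
  out <- dirs
  for (i in seq_len(n)) {
    if (sigma[i] <= 0) next
    b <- perp_basis(dirs[i, ])
    v <- dirs[i, ] + t1[i] * b$e1 + t2[i] * b$e2
    out[i, ] <- v / sqrt(sum(v^2))
  }
  out
}

#' Two-sample Kolmogorov-Smirnov test with weights
#'
#' Weighted-ECDF version of the two-sample KS test, with effective sample
#' sizes from the Kish formula and the asymptotic Kolmogorov distribution for
#' the p-value. With unit weights it reduces to the classical test.
#'
#' @param x,y numeric samples.
#' @param wx,wy per-observation weights (default 1).
#' @return list with `statistic` (D), `p.value`, `n_eff`.
#' @export
ks_test_weighted <- function(x, y, wx = NULL, wy = NULL) {
  wx <- wx %||% rep(1, length(x))
  wy <- wy %||% rep(1, length(y))
  grid <- sort(unique(c(x, y)))
  ex <- weighted_ecdf(x, wx); ey <- weighted_ecdf(y, wy)
  D <- max(abs(ex(grid) - ey(grid)))
  nx <- sum(wx)^2 / sum(wx^2)
  ny <- sum(wy)^2 / sum(wy^2)
  n_eff <- nx * ny / (nx + ny)
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(statistic = D, p.value = max(min(p, 1), 0), n_eff = n_eff)
}

weighted_ecdf <- function(x, w) {
  o <- order(x)
  xs <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  function(q) {
    i <- findInterval(q, xs)
    c(0, cw)[i + 1]
  }
}
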