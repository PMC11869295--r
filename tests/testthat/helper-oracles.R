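# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: finite differences for gradients, dense
# quadrature for biased moments, brute-force grid scans for stationary
# points, and matrix exponentials for master-equation solutions.

# central finite-difference gradient of a surface
fd_gradient <- function(surface, x, eps = 1e-6) {
  g <- numeric(2)
  for (k in 1:2) {
    dp <- c(0, 0); dp[k] <- eps
    g[k] <- (surface_energy(surface, x + dp) -
               surface_energy(surface, x - dp)) / (2 * eps)
  }
  g
}

# mean and covariance of exp(-(U + harmonic bias)/kBT) by brute quadrature
oracle_biased_moments <- function(surface, center, k, half_width, n = 201,
                                  temperature = 310) {
  beta <- 1 / (0.0019872041 * temperature)
  xs <- seq(center[1] - half_width, center[1] + half_width, length.out = n)
  ys <- seq(center[2] - half_width, center[2] + half_width, length.out = n)
  pts <- cbind(rep(xs, times = n), rep(ys, each = n))
  k <- rep(k, length.out = 2)
  bias <- 0.5 * k[1] * (pts[, 1] - center[1])^2 +
    0.5 * k[2] * (pts[, 2] - center[2])^2
  U <- surface_energy(surface, pts) + bias
  w <- exp(-beta * (U - min(U)))
  mu <- c(sum(w * pts[, 1]), sum(w * pts[, 2])) / sum(w)
  v <- c(sum(w * (pts[, 1] - mu[1])^2), sum(w * (pts[, 2] - mu[2])^2)) / sum(w)
  list(mean = mu, var = v)
}

# brute-force local minima of a surface on a dense grid (no refinement
# beyond a local 8-neighbour comparison; merge radius for duplicates)
oracle_grid_minima <- function(surface, n = 401) {
  d <- surface$domain
  xs <- seq(d[1], d[2], length.out = n)
  ys <- seq(d[3], d[4], length.out = n)
  E <- matrix(surface_energy(surface, cbind(rep(xs, times = n),
                                            rep(ys, each = n))), n, n)
  mins <- NULL
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    if (E[i, j] < min(E[(i - 1):(i + 1), (j - 1):(j + 1)][-5])) {
      mins <- rbind(mins, c(xs[i], ys[j]))
    }
  }
  mins
}

# exact master-equation solution P(t) = expm(A t) %*% p0
oracle_master_equation <- function(network, times) {
  A <- t(network$K)
  diag(A) <- diag(A) - rowSums(network$K)
  t(vapply(times, function(tt) {
    as.numeric(Matrix::expm(A * tt) %*% network$p0)
  }, numeric(length(network$p0))))
}

# closed-form arclength of the parabola y = x^2 from 0 to x
parabola_arclength <- function(x) {
  (x * sqrt(1 + 4 * x^2) + asinh(2 * x) / 2) / 2
}
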