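## Restrained stochastic sampling on surrogate surfaces. Emulates short
## restrained simulations at umbrella windows: overdamped Langevin dynamics
## with a Metropolis acceptance step so that the stationary distribution is
## exactly exp(-(U + bias)/kBT).

#' Define a harmonic restraint window
#'
#' A window restrains the two reaction coordinates about `center` with
#' per-coordinate harmonic force constants, `bias(x) = sum(k/2 (x - c)^2)`.
#'
#' @param center length-2 window center (RC1, RC2), Angstrom.
#' @param k force constant(s), kcal/mol/Angstrom^2; scalar or length 2.
#'   Typical restrained-sampling values lie in 50-200.
#' @param steps number of sampling steps taken when the window is simulated.
#' @param temperature temperature in Kelvin.
#' @return a `restraint_window` object.
#' @export
restraint_window <- function(center, k = 200, steps = 200, temperature = 310) {
  k <- rep(as.numeric(k), length.out = 2)
  if (any(k <= 0)) stop("restraint force constants must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  stopifnot(length(center) == 2, all(is.finite(center)))
  structure(list(center = as.numeric(center), k = k,
                 steps = as.integer(steps), temperature = temperature),
            class = "restraint_window")
}

.bias_energy <- function(window, x) {
  x <- .as_points(x)
  0.5 * window$k[1] * (x[, 1] - window$center[1])^2 +
    0.5 * window$k[2] * (x[, 2] - window$center[2])^2
}

.bias_gradient <- function(window, x) {
  x <- .as_points(x)
  cbind(window$k[1] * (x[, 1] - window$center[1]),
        window$k[2] * (x[, 2] - window$center[2]), deparse.level = 0)
}

#' Sample a restrained window on a surface
#'
#' Draws `n` correlated samples from the biased Boltzmann density
#' `exp(-(U(x) + bias(x))/kBT)` by Metropolis-adjusted overdamped Langevin
#' dynamics (Euler-Maruyama proposals, exact acceptance correction). The
#' chain starts at the window center unless `x0` is given. If the proposal
#' step diverges (non-finite energy), the step size is halved and the chain
#' restarted deterministically; after `max_halvings` failures an error
#' reports the offending step index.
#'
#' @param surface a `model_surface`.
#' @param window a `restraint_window`.
#' @param n number of samples; defaults to `window$steps`.
#' @param seed integer seed; identical seed, window and surface give
#'   bit-identical samples.
#' @param dt integrator step size, Angstrom^2/(kcal/mol) units (mobility 1).
#' @param x0 optional starting point.
#' @param max_halvings maximum number of automatic step-size halvings.
#' @return a `biased_trajectory`: list with `samples` (n-by-2 matrix),
#'   `window`, `seed`, `dt` (the step size actually used), and the Metropolis
#'   `accept_rate`.
#' @export
sample_window <- function(surface, window, n = window$steps, seed,
                          dt = 1e-3, x0 = window$center, max_halvings = 12) {
  stopifnot(n >= 1)
  if (missing(seed)) stop("an explicit seed is required")
  beta <- 1 / kBT(window$temperature)
  for (h in 0:max_halvings) {
    res <- .mala_chain(surface, window, n, seed, dt, x0, beta)
    if (is.null(res$fail_step)) {
      res$n_halvings <- h
      return(res)
    }
    if (h == max_halvings) {
      stop(sprintf("sampler diverged at step %d even at dt = %g", res$fail_step, dt))
    }
    dt <- dt / 2
  }
}

.mala_chain <- function(surface, window, n, seed, dt, x0, beta) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pot <- function(p) {
    surface_energy(surface, p) + .bias_energy(window, p)
  }
  grad <- function(p) {
    surface_gradient(surface, p) + .bias_gradient(window, p)
  }
  samples <- matrix(NA_real_, n, 2)
  x <- as.numeric(x0)
  Ux <- pot(x); gx <- as.numeric(grad(x))
  if (!is.finite(Ux)) stop("non-finite energy at the starting point")
  sig <- sqrt(2 * dt / beta)  # noise scale; drift uses mobility 1
  n_acc <- 0L
  for (i in seq_len(n)) {
    xi <- stats::rnorm(2)
    y <- x - dt * gx + sig * xi
    Uy <- pot(y)
    if (!is.finite(Uy)) {
      return(list(fail_step = i))
    }
    gy <- as.numeric(grad(y))
    if (any(!is.finite(gy))) {
      return(list(fail_step = i))
    }
    # log q(x|y) - log q(y|x) for the Gaussian EM proposal
    fwd <- y - (x - dt * gx)
    rev <- x - (y - dt * gy)
    logq <- (sum(fwd^2) - sum(rev^2)) / (2 * sig^2)
    log_alpha <- -beta * (Uy - Ux) + logq
    if (log(stats::runif(1)) < log_alpha) {
      x <- y; Ux <- Uy; gx <- gy
      n_acc <- n_acc + 1L
    }
    samples[i, ] <- x
  }
  structure(list(samples = samples, window = window, seed = seed, dt = dt,
                 accept_rate = n_acc / n, fail_step = NULL),
            class = "biased_trajectory")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.biased_trajectory <- function(x, ...) {
  cat(sprintf("<biased_trajectory> %d samples at window (%.3f, %.3f), k = (%g, %g), accept %.2f\n",
              nrow(x$samples), x$window$center[1], x$window$center[2],
              x$window$k[1], x$window$k[2], x$accept_rate))
  invisible(x)
}

#' Mean of the biased density by direct quadrature
#'
#' Computes the mean (and covariance) of `exp(-(U + bias)/kBT)` on a local
#' quadrature grid around the window center. Serves as the deterministic
#' ("noiseless") counterpart of [sample_window()] for drift estimation and
#' for validating sampled moments.
#'
#' @inheritParams sample_window
#' @param half_width half-width of the quadrature box (defaults to 6 thermal
#'   standard deviations of the restraint).
#' @param n_quad quadrature points per axis.
#' @return list with `mean` (length 2), `cov` (2x2) and the normalization
#'   weight `Z` (unnormalized).
#' @export
window_quadrature <- function(surface, window, half_width = NULL, n_quad = 121) {
  beta <- 1 / kBT(window$temperature)
  if (is.null(half_width)) {
    half_width <- 6 * sqrt(1 / (beta * min(window$k)))
  }
  xs <- seq(window$center[1] - half_width, window$center[1] + half_width,
            length.out = n_quad)
  ys <- seq(window$center[2] - half_width, window$center[2] + half_width,
            length.out = n_quad)
  pts <- cbind(rep(xs, times = n_quad), rep(ys, each = n_quad))
  U <- surface_energy(surface, pts) + .bias_energy(window, pts)
  w <- exp(-beta * (U - min(U)))
  Z <- sum(w)
  mu <- c(sum(w * pts[, 1]), sum(w * pts[, 2])) / Z
  dxy <- cbind(pts[, 1] - mu[1], pts[, 2] - mu[2])
  cv <- crossprod(dxy, dxy * w) / Z
  list(mean = mu, cov = cv, Z = Z * exp(-beta * min(U)))
}

#' Write a biased trajectory to CSV
#'
#' Columns: step, RC1, RC2.
#' @param traj a `biased_trajectory`.
#' @param file output path.
#' @export
write_trajectory_csv <- function(traj, file) {
  df <- data.frame(step = seq_len(nrow(traj$samples)),
                   RC1 = traj$samples[, 1], RC2 = traj$samples[, 2])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
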