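## Seeded synthetic trajectory generators. Each generator plants a known
## ground truth (membrane partition ratio, binding-site dwell fraction,
## radial cluster position, telegraph binding) so that every ensemble
## statistic can be validated exactly. These emulate the distributional
## features of membrane simulations - partitioning, site binding, bound/
## unbound switching - not their dynamics.

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Synthetic membrane-partitioning trajectory
#'
#' Particles are distributed along the membrane normal with a piecewise-
#' uniform density: `ratio` times denser inside the core
#' (`|z| < core_halfwidth`) than outside, uniform in the plane. The planted
#' core/bulk partition ratio is exactly `ratio`.
#'
#' @param n particles per frame.
#' @param ratio planted core/bulk density ratio.
#' @param box length-3 box, Angstrom.
#' @param core_halfwidth membrane-core half-width, Angstrom.
#' @param n_frames frames.
#' @param species species label.
#' @param seed integer seed.
#' @return a `particle_trajectory`.
#' @export
make_partition_trajectory <- function(n = 10000, ratio = 12,
                                      box = c(60, 60, 80),
                                      core_halfwidth = 10, n_frames = 1,
                                      species = "O2", seed = 1) {
  L <- box[3]
  w_core <- 2 * core_halfwidth
  w_bulk <- L - w_core
  p_core <- ratio * w_core / (ratio * w_core + w_bulk)
  .with_seed(seed, {
    coords <- array(NA_real_, c(n, 3, n_frames))
    for (f in seq_len(n_frames)) {
      in_core <- stats::runif(n) < p_core
      z <- ifelse(in_core,
                  stats::runif(n, -core_halfwidth, core_halfwidth),
                  sample(c(-1, 1), n, replace = TRUE) *
                    stats::runif(n, core_halfwidth, L / 2))
      coords[, , f] <- cbind(stats::runif(n, -box[1] / 2, box[1] / 2),
                             stats::runif(n, -box[2] / 2, box[2] / 2), z)
    }
    particle_trajectory(coords, rep(species, n), box)
  })
}

#' Synthetic radial-shell cluster trajectory
#'
#' A fraction of the particles form a Gaussian shell at radius `r0` about
#' the box center; the rest are an ideal gas. The planted g(r) peak sits at
#' `r0`.
#'
#' @param n particles per frame.
#' @param r0 shell radius, Angstrom.
#' @param shell_sd radial spread of the shell, Angstrom.
#' @param frac_shell fraction of particles in the shell.
#' @inheritParams make_partition_trajectory
#' @return a `particle_trajectory`.
#' @export
make_shell_trajectory <- function(n = 4000, r0 = 9, shell_sd = 0.5,
                                  frac_shell = 0.5, box = c(50, 50, 50),
                                  n_frames = 5, species = "SOX", seed = 1) {
  .with_seed(seed, {
    coords <- array(NA_real_, c(n, 3, n_frames))
    n_shell <- round(frac_shell * n)
    for (f in seq_len(n_frames)) {
      u <- matrix(stats::rnorm(3 * n_shell), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      r <- stats::rnorm(n_shell, r0, shell_sd)
      gas <- cbind(stats::runif(n - n_shell, -box[1] / 2, box[1] / 2),
                   stats::runif(n - n_shell, -box[2] / 2, box[2] / 2),
                   stats::runif(n - n_shell, -box[3] / 2, box[3] / 2))
      coords[, , f] <- rbind(u * r, gas)
    }
    particle_trajectory(coords, rep(species, n), box)
  })
}

#' Synthetic site-dwell trajectory
#'
#' A single particle dwells inside a spherical site for exactly
#' `round(dwell * n_frames)` frames (uniform within the cutoff sphere) and
#' is otherwise uniform outside it, planting an exact frame-fraction
#' occupancy.
#'
#' @param n_frames frames.
#' @param dwell planted dwell (frame) fraction.
#' @param site length-3 site center.
#' @param cutoff site radius, Angstrom.
#' @inheritParams make_partition_trajectory
#' @return a `particle_trajectory`.
#' @export
make_dwell_trajectory <- function(n_frames = 1000, dwell = 0.4,
                                  site = c(0, 0, 0), cutoff = 5,
                                  box = c(40, 40, 40), species = "SOX",
                                  seed = 1) {
  n_in <- round(dwell * n_frames)
  .with_seed(seed, {
    inside <- sample(rep(c(TRUE, FALSE), c(n_in, n_frames - n_in)))
    coords <- array(NA_real_, c(1, 3, n_frames))
    for (f in seq_len(n_frames)) {
      repeat {
        p <- stats::runif(3, -box / 2, box / 2)
        d <- sqrt(sum((.min_image(matrix(p - site, 1, 3), box))^2))
        if (inside[f] && d <= cutoff * 0.95) break
        if (!inside[f] && d > cutoff * 1.05) break
      }
      coords[, , f] <- p
    }
    particle_trajectory(coords, species, box)
  })
}

#' Synthetic telegraph binding trajectory
#'
#' Two single-atom groups alternate deterministically between a bound
#' distance and an unbound distance with the given period, planting exact
#' switch points for bound/unbound segmentation.
#'
#' @param n_frames frames.
#' @param d_bound,d_unbound the two separations, Angstrom.
#' @param period frames per half-cycle.
#' @param box length-3 box.
#' @return a `particle_trajectory` with species "A" and "B".
#' @export
make_telegraph_trajectory <- function(n_frames = 200, d_bound = 8,
                                      d_unbound = 20, period = 25,
                                      box = c(60, 60, 60)) {
  coords <- array(0, c(2, 3, n_frames))
  bound <- ((seq_len(n_frames) - 1) %/% period) %% 2 == 0
  coords[2, 1, ] <- ifelse(bound, d_bound, d_unbound)
  particle_trajectory(coords, c("A", "B"), box)
}

#' Ideal-gas trajectory
#'
#' Uniform random particles; every ensemble statistic has a flat/known
#' expectation.
#'
#' @inheritParams make_partition_trajectory
#' @return a `particle_trajectory`.
#' @export
make_uniform_gas <- function(n = 5000, box = c(50, 50, 50), n_frames = 5,
                             species = "GAS", seed = 1) {
  .with_seed(seed, {
    coords <- array(stats::runif(n * 3 * n_frames), c(n, 3, n_frames))
    for (k in 1:3) coords[, k, ] <- (coords[, k, ] - 0.5) * box[k]
    particle_trajectory(coords, rep(species, n), box)
  })
}
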