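## Reconstruction of the unbiased 2D free-energy landscape from harmonic
## umbrella windows, by three estimators: 2D WHAM (self-consistent histogram
## reweighting), MBAR (per-sample self-consistent window free energies) and
## a variational maximum-likelihood profile on a coarse bilinear basis.
## Landscapes are referenced so that the minimum over occupied bins is zero.

#' Bundle biased trajectories into a window set
#'
#' @param trajectories list of `biased_trajectory` objects sharing one
#'   temperature.
#' @return a `window_set`.
#' @export
window_set <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  temps <- vapply(trajectories, function(t) t$window$temperature, numeric(1))
  if (diff(range(temps)) > 1e-9) stop("all windows must share one temperature")
  structure(list(trajectories = trajectories, temperature = temps[1]),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  ns <- vapply(x$trajectories, function(t) nrow(t$samples), numeric(1))
  cat(sprintf("<window_set> %d windows, %d samples total, T = %g K\n",
              length(x$trajectories), sum(ns), x$temperature))
  invisible(x)
}

#' Regular 2D grid of umbrella windows
#'
#' Window centers form an `n_per_axis` x `n_per_axis` lattice inclusive of
#' the bounds; the customary free-energy-sampling force constant of 200
#' kcal/mol/A^2 is the default. A 13-per-axis grid gives the standard
#' 169-window umbrella protocol.
#'
#' @param bounds numeric length-4: (RC1 min, RC1 max, RC2 min, RC2 max).
#' @param n_per_axis lattice points per axis (>= 2).
#' @param k harmonic force constant, kcal/mol/A^2.
#' @param steps per-window sample count when simulated.
#' @param temperature Kelvin.
#' @return list of `restraint_window` objects (length `n_per_axis^2`).
#' @examples
#' length(make_umbrella_grid(c(-1, 1, -1, 1), 13))  # 169
#' @export
make_umbrella_grid <- function(bounds, n_per_axis, k = 200, steps = 1000,
                               temperature = 310) {
  stopifnot(length(bounds) == 4, n_per_axis >= 2)
  if (bounds[2] <= bounds[1] || bounds[4] <= bounds[3]) {
    stop("degenerate bounds")
  }
  xs <- seq(bounds[1], bounds[2], length.out = n_per_axis)
  ys <- seq(bounds[3], bounds[4], length.out = n_per_axis)
  out <- vector("list", n_per_axis^2)
  i <- 0L
  for (y in ys) for (x in xs) {
    i <- i + 1L
    out[[i]] <- restraint_window(c(x, y), k = k, steps = steps,
                                 temperature = temperature)
  }
  out
}

#' Sample a set of umbrella windows
#'
#' Convenience wrapper running [sample_window()] over a list of windows with
#' per-window derived seeds.
#'
#' @param surface a `model_surface`.
#' @param windows list of `restraint_window`.
#' @param n samples per window (defaults to each window's `steps`).
#' @param seed base seed; window `i` uses `seed + i`.
#' @param dt integrator step size.
#' @return a `window_set`.
#' @export
sample_windows <- function(surface, windows, n = NULL, seed, dt = 2e-3) {
  trajs <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    sample_window(surface, w, n = if (is.null(n)) w$steps else n,
                  seed = seed + i, dt = dt)
  })
  window_set(trajs)
}

## --- shared internals -----------------------------------------------------

.collect_samples <- function(ws) {
  trajs <- ws$trajectories
  X <- do.call(rbind, lapply(trajs, function(t) t$samples))
  N <- vapply(trajs, function(t) nrow(t$samples), numeric(1))
  centers <- do.call(rbind, lapply(trajs, function(t) t$window$center))
  ks <- do.call(rbind, lapply(trajs, function(t) t$window$k))
  list(X = X, N = N, centers = centers, ks = ks,
       win = rep.int(seq_along(trajs), N))
}

.make_grid <- function(X, bins, pad = 0.05) {
  rx <- range(X[, 1]); ry <- range(X[, 2])
  rx <- rx + c(-1, 1) * pad * diff(rx)
  ry <- ry + c(-1, 1) * pad * diff(ry)
  list(x_edges = seq(rx[1], rx[2], length.out = bins + 1),
       y_edges = seq(ry[1], ry[2], length.out = bins + 1))
}

.bin_index <- function(X, grid) {
  bins_x <- length(grid$x_edges) - 1L
  bins_y <- length(grid$y_edges) - 1L
  ix <- findInterval(X[, 1], grid$x_edges, rightmost.closed = TRUE)
  iy <- findInterval(X[, 2], grid$y_edges, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), bins_x)
  iy <- pmin(pmax(iy, 1L), bins_y)
  (iy - 1L) * bins_x + ix
}

## m x m sub-bin centers for every bin, grouped per bin in L-order
.subgrid_centers <- function(grid, m) {
  bx <- length(grid$x_edges) - 1L
  by <- length(grid$y_edges) - 1L
  wx <- diff(grid$x_edges[1:2]); wy <- diff(grid$y_edges[1:2])
  ix <- rep(rep(seq_len(bx), times = by), each = m * m)
  iy <- rep(rep(seq_len(by), each = bx), each = m * m)
  off <- expand.grid(a = seq_len(m), b = seq_len(m))
  oa <- rep(off$a, times = bx * by)
  ob <- rep(off$b, times = bx * by)
  cbind(grid$x_edges[ix] + (oa - 0.5) * wx / m,
        grid$y_edges[iy] + (ob - 0.5) * wy / m)
}

.bin_centers <- function(grid) {
  cx <- (grid$x_edges[-1] + grid$x_edges[-length(grid$x_edges)]) / 2
  cy <- (grid$y_edges[-1] + grid$y_edges[-length(grid$y_edges)]) / 2
  cbind(rep(cx, times = length(cy)), rep(cy, each = length(cx)))
}

## bias energy of every window at every bin center: K x L matrix
.bias_matrix <- function(centers, ks, pts) {
  K <- nrow(centers)
  t(vapply(seq_len(K), function(i) {
    0.5 * ks[i, 1] * (pts[, 1] - centers[i, 1])^2 +
      0.5 * ks[i, 2] * (pts[, 2] - centers[i, 2])^2
  }, numeric(nrow(pts))))
}

## window-overlap connectivity via shared occupied bins; errors listing the
## components when the window graph is disconnected.
.check_overlap <- function(counts_kl) {
  K <- nrow(counts_kl)
  parent <- seq_len(K)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  occ <- counts_kl > 0
  for (l in which(colSums(occ) > 1)) {
    wins <- which(occ[, l])
    for (w in wins[-1]) {
      ra <- find(wins[1]); rb <- find(w)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(K), find, integer(1))
  comp <- split(seq_len(K), roots)
  if (length(comp) > 1) {
    stop("disconnected window graph; components: ",
         paste(vapply(comp, function(cs) paste0("{", paste(cs, collapse = ","), "}"),
                      character(1)), collapse = " "))
  }
  invisible(TRUE)
}

.new_landscape <- function(grid, F, occupied, estimator, kT,
                           uncertainty = NULL) {
  F <- F - min(F[occupied])
  F[!occupied] <- NA_real_
  structure(list(x_edges = grid$x_edges, y_edges = grid$y_edges,
                 F = F, occupied = occupied, estimator = estimator,
                 kBT = kT, uncertainty = uncertainty),
            class = "free_energy_landscape")
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat(sprintf("<free_energy_landscape> %s, %d x %d bins, %d occupied, max %.2f kcal/mol\n",
              x$estimator, length(x$x_edges) - 1, length(x$y_edges) - 1,
              sum(x$occupied), max(x$F, na.rm = TRUE)))
  invisible(x)
}

## --- WHAM ------------------------------------------------------------------

#' 2D weighted-histogram free-energy estimate
#'
#' Self-consistent WHAM on a regular 2D histogram. Iteration stops when the
#' largest change in the per-window free energies falls below `tol`
#' (kcal/mol). Bins with fewer than `occupied_min` samples are flagged
#' unoccupied and reported as NA.
#'
#' @param windows a `window_set`.
#' @param bins bins per axis (grid covers the sampled range padded 5%).
#' @param tol convergence tolerance on window free energies, kcal/mol.
#' @param max_iter maximum WHAM iterations.
#' @param occupied_min minimum samples for a bin to count as occupied.
#' @param grid optional precomputed grid (list with `x_edges`, `y_edges`);
#'   used to evaluate several estimators on identical bins.
#' @return a `free_energy_landscape` (minimum over occupied bins = 0).
#' @export
wham2d <- function(windows, bins = 50, tol = 1e-7, max_iter = 100000,
                   occupied_min = 10, grid = NULL) {
  cs <- .collect_samples(windows)
  if (length(cs$N) < 1) stop("empty window set")
  kT <- kBT(windows$temperature)
  beta <- 1 / kT
  if (is.null(grid)) grid <- .make_grid(cs$X, bins)
  bl <- .bin_index(cs$X, grid)
  L <- (length(grid$x_edges) - 1L) * (length(grid$y_edges) - 1L)
  K <- length(cs$N)
  counts_kl <- matrix(0, K, L)
  tab <- table(factor(cs$win, levels = seq_len(K)),
               factor(bl, levels = seq_len(L)))
  counts_kl[] <- as.numeric(tab)
  if (K > 1) .check_overlap(counts_kl)
  n_l <- colSums(counts_kl)
  pts <- .bin_centers(grid)
  C <- exp(-beta * .bias_matrix(cs$centers, cs$ks, pts))  # K x L
  f <- rep(1, K)   # exp(beta * g_i), WHAM normalization factors
  g_old <- rep(0, K)
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(t(C) %*% (cs$N * f))     # length L
    P <- ifelse(denom > 0, n_l / denom, 0)
    f <- 1 / as.numeric(C %*% P)
    g <- -kT * log(f)
    g <- g - g[1]
    if (max(abs(g - g_old)) < tol) break
    g_old <- g
  }
  if (it == max_iter) {
    warning("WHAM did not reach tolerance within max_iter iterations")
  }
  occupied <- n_l >= occupied_min & P > 0
  F <- suppressWarnings(-kT * log(P))
  F[!occupied] <- Inf
  nb <- length(grid$x_edges) - 1L
  out <- .new_landscape(grid, matrix(F, nb), matrix(occupied, nb), "wham", kT)
  attr(out, "window_g") <- g   # per-window free energies, kcal/mol
  out
}

## --- MBAR ------------------------------------------------------------------

#' MBAR free-energy estimate on a 2D grid
#'
#' Solves the multistate Bennett acceptance ratio self-consistent equations
#' on per-sample bias energies by damped Newton iteration on the convex MBAR
#' objective (window free energies converged to a self-consistency change
#' below `tol` kcal/mol), then bins the resulting unbiased sample weights on
#' the same grid as [wham2d()].
#'
#' @inheritParams wham2d
#' @return a `free_energy_landscape`.
#' @export
mbar_fes <- function(windows, bins = 50, tol = 1e-7, max_iter = 200,
                     occupied_min = 10, grid = NULL, init = NULL) {
  cs <- .collect_samples(windows)
  kT <- kBT(windows$temperature)
  beta <- 1 / kT
  K <- length(cs$N)
  ## reduced bias energies of every sample in every window: N x K
  U <- vapply(seq_len(K), function(i) {
    beta * (0.5 * cs$ks[i, 1] * (cs$X[, 1] - cs$centers[i, 1])^2 +
            0.5 * cs$ks[i, 2] * (cs$X[, 2] - cs$centers[i, 2])^2)
  }, numeric(nrow(cs$X)))
  logN <- log(cs$N)
  weights_of <- function(f) {
    A <- sweep(-U, 2, logN + f, "+")
    m <- apply(A, 1, max)
    E <- exp(A - m)
    rs <- rowSums(E)
    list(W = E / rs, logD = m + log(rs))   # W: N x K mixture weights
  }
  scf_step <- function(logD) {
    ## self-consistent update f_k = -logsumexp_n(-u_kn - logD_n)
    M <- -U - logD
    mm <- apply(M, 2, max)
    fnew <- -(mm + log(colSums(exp(sweep(M, 2, mm)))))
    fnew - fnew[1]
  }
  if (is.null(init) && K > 1) {
    ## initialize from a coarse, loosely converged WHAM pass
    wh <- tryCatch(wham2d(windows, bins = 40, tol = 1e-4, max_iter = 5000,
                          occupied_min = 1),
                   error = function(e) NULL)
    if (!is.null(wh)) init <- attr(wh, "window_g") / kT
  }
  f <- if (!is.null(init) && length(init) == K) init - init[1] else rep(0, K)
  if (K > 1) {
    wf <- weights_of(f)
    g <- colSums(wf$W) - cs$N              # gradient of the MBAR objective
    mu <- 1e-6
    for (it in seq_len(max_iter)) {
      H <- -crossprod(wf$W)
      diag(H) <- diag(H) + colSums(wf$W)
      Hr <- H[-1, -1, drop = FALSE]
      improved <- FALSE
      if (mu < 1e6) {
        for (try in 1:6) {    # Levenberg-damped Newton with cheap retries
          sol <- tryCatch(solve(Hr + diag(mu * mean(diag(Hr)), K - 1), -g[-1]),
                          error = function(e) NULL)
          if (!is.null(sol)) {
            fnew <- f; fnew[-1] <- fnew[-1] + sol
            fnew <- fnew - fnew[1]
            wf_new <- weights_of(fnew)
            gn <- colSums(wf_new$W) - cs$N
            if (sum(gn^2) < sum(g^2)) {
              improved <- TRUE
              mu <- max(mu / 5, 1e-9)
              break
            }
          }
          mu <- mu * 20
          if (mu >= 1e6) break
        }
      }
      if (!improved) {        # fall back to one self-consistent sweep
        fnew <- scf_step(wf$logD)
        wf_new <- weights_of(fnew)
        gn <- colSums(wf_new$W) - cs$N
        mu <- 1e-2            # re-enable Newton once SCF has moved f
      }
      delta <- max(abs(fnew - f)) * kT
      f <- fnew; wf <- wf_new; g <- gn
      if (delta < tol) break
    }
    if (it == max_iter) {
      warning("MBAR did not reach tolerance within max_iter iterations")
    }
  }
  logw <- -weights_of(f)$logD                # log unbiased weights
  if (is.null(grid)) grid <- .make_grid(cs$X, bins)
  bl <- .bin_index(cs$X, grid)
  L <- (length(grid$x_edges) - 1L) * (length(grid$y_edges) - 1L)
  n_l <- tabulate(bl, nbins = L)
  logP <- vapply(seq_len(L), function(l) {
    v <- logw[bl == l]
    if (!length(v)) return(-Inf)
    mm <- max(v)
    mm + log(sum(exp(v - mm)))
  }, numeric(1))
  occupied <- n_l >= occupied_min & is.finite(logP)
  F <- -kT * logP
  nb <- length(grid$x_edges) - 1L
  out <- .new_landscape(grid, matrix(F, nb), matrix(occupied, nb), "mbar", kT)
  out$solver <- f
  out
}

## --- variational profile ---------------------------------------------------

#' Variational maximum-likelihood free-energy profile
#'
#' Parameterizes the 2D free energy on a coarse bilinear knot basis and
#' maximizes the likelihood of all biased samples given the window biases
#' (each window contributes its own normalization integral, evaluated on the
#' output grid). The optimum is found by L-BFGS-B with an analytic gradient.
#'
#' @inheritParams wham2d
#' @param knots knots per axis of the bilinear basis (basis resolution);
#'   scalar or length 2 (RC1, RC2) for anisotropic resolution.
#' @param maxit optimizer iteration cap.
#' @return a `free_energy_landscape`.
#' @export
variational_profile <- function(windows, knots = 12, bins = 50,
                                occupied_min = 10, maxit = 400, grid = NULL,
                                init = NULL) {
  cs <- .collect_samples(windows)
  kT <- kBT(windows$temperature)
  beta <- 1 / kT
  if (is.null(grid)) grid <- .make_grid(cs$X, bins)
  nb <- length(grid$x_edges) - 1L
  L <- nb * nb
  knots <- rep(as.integer(knots), length.out = 2)
  n_par <- prod(knots)
  if (n_par > L) stop("under-determined basis: more knots than bins")
  pts <- .bin_centers(grid)
  n_l <- tabulate(.bin_index(cs$X, grid), nbins = L)
  if (n_par > sum(n_l >= 1)) {
    stop("under-determined basis: more parameters than occupied bins")
  }
  kx <- seq(grid$x_edges[1], grid$x_edges[length(grid$x_edges)],
            length.out = knots[1])
  ky <- seq(grid$y_edges[1], grid$y_edges[length(grid$y_edges)],
            length.out = knots[2])
  ## bilinear basis matrix on bin centers (L x knots^2) and on samples
  basis <- function(P) {
    ix <- pmin(pmax(findInterval(P[, 1], kx), 1L), knots[1] - 1L)
    iy <- pmin(pmax(findInterval(P[, 2], ky), 1L), knots[2] - 1L)
    tx <- (P[, 1] - kx[ix]) / (kx[ix + 1L] - kx[ix])
    ty <- (P[, 2] - ky[iy]) / (ky[iy + 1L] - ky[iy])
    n <- nrow(P)
    ii <- rep(seq_len(n), 4)
    jj <- c((iy - 1L) * knots[1] + ix, (iy - 1L) * knots[1] + ix + 1L,
            iy * knots[1] + ix, iy * knots[1] + ix + 1L)
    vv <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
    M <- matrix(0, n, n_par)
    M[cbind(ii, jj)] <- vv
    M
  }
  B_grid <- basis(pts)                       # L x M
  bias_kl <- .bias_matrix(cs$centers, cs$ks, pts)   # K x L
  s_basis <- colSums(basis(cs$X))            # sum of basis over samples
  Ntot <- sum(cs$N)
  obj <- function(theta) {
    Fg <- as.numeric(B_grid %*% theta)
    E <- exp(-beta * sweep(bias_kl, 2, Fg, "+"))     # K x L
    Z <- rowSums(E)
    beta * sum(s_basis * theta) + sum(cs$N * log(Z))
  }
  grd <- function(theta) {
    Fg <- as.numeric(B_grid %*% theta)
    E <- exp(-beta * sweep(bias_kl, 2, Fg, "+"))
    Z <- rowSums(E)
    p <- as.numeric(t(E / Z) %*% cs$N)               # length L, sums to Ntot
    beta * (s_basis - as.numeric(t(B_grid) %*% p))
  }
  theta0 <- if (!is.null(init) && length(init) == n_par) init else rep(0, n_par)
  opt <- stats::optim(theta0, obj, grd, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4))
  ## report each bin as the Boltzmann average of the fitted profile over a
  ## 3x3 subgrid, the quantity a histogram estimator measures on that bin
  sub <- .subgrid_centers(grid, 3)
  Fsub <- matrix(as.numeric(basis(sub) %*% opt$par), nrow = 9)
  Fg <- -kT * (log(colMeans(exp(-beta * sweep(Fsub, 2, apply(Fsub, 2, min))))) -
                 beta * apply(Fsub, 2, min))
  occupied <- n_l >= occupied_min
  Fm <- Fg
  Fm[!occupied] <- Inf
  out <- .new_landscape(grid, matrix(Fm, nb), matrix(occupied, nb), "vfep", kT)
  out$solver <- opt$par
  out
}

#' Dispatch a free-energy estimator by name
#' @param windows a `window_set`.
#' @param estimator `"wham"`, `"mbar"` or `"vfep"`.
#' @param ... passed to the estimator.
#' @return a `free_energy_landscape`.
#' @export
reconstruct_fes <- function(windows, estimator = c("wham", "mbar", "vfep"),
                            ...) {
  estimator <- match.arg(estimator)
  switch(estimator,
         wham = wham2d(windows, ...),
         mbar = mbar_fes(windows, ...),
         vfep = variational_profile(windows, ...))
}

## --- barrier extraction ----------------------------------------------------

.landscape_lookup <- function(landscape, P) {
  xe <- landscape$x_edges; ye <- landscape$y_edges
  cx <- (xe[-1] + xe[-length(xe)]) / 2
  cy <- (ye[-1] + ye[-length(ye)]) / 2
  Fm <- landscape$F
  ix <- pmin(pmax(findInterval(P[, 1], cx), 1L), length(cx) - 1L)
  iy <- pmin(pmax(findInterval(P[, 2], cy), 1L), length(cy) - 1L)
  tx <- (P[, 1] - cx[ix]) / (cx[ix + 1L] - cx[ix])
  ty <- (P[, 2] - cy[iy]) / (cy[iy + 1L] - cy[iy])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  f00 <- Fm[cbind(ix, iy)]; f10 <- Fm[cbind(ix + 1L, iy)]
  f01 <- Fm[cbind(ix, iy + 1L)]; f11 <- Fm[cbind(ix + 1L, iy + 1L)]
  f00 * (1 - tx) * (1 - ty) + f10 * tx * (1 - ty) +
    f01 * (1 - tx) * ty + f11 * tx * ty
}

#' Barrier and reaction free energy along a string path
#'
#' Interpolates the landscape bilinearly along the densified path; the
#' barrier is the path maximum minus the reactant-basin minimum, the
#' reaction free energy is the product-basin value minus the reactant value.
#' Basins are the lowest occupied bins within `basin_radius` of the path
#' endpoints.
#'
#' @param landscape a `free_energy_landscape`.
#' @param path a `string_path` (or an n-by-2 matrix of path points).
#' @param basin_radius radius (Angstrom) about each endpoint within which the
#'   basin minimum is sought.
#' @param n_dense number of points along the densified path.
#' @return list with `barrier` and `dG` (kcal/mol), plus the basin values.
#' @export
path_barrier <- function(landscape, path, basin_radius = 0.3, n_dense = 400) {
  P <- if (inherits(path, "string_path")) densify_path(path, n_dense) else .as_points(path)
  vals <- .landscape_lookup(landscape, P)
  if (any(is.na(vals))) stop("path crosses unoccupied bins")
  ends <- P[c(1, nrow(P)), , drop = FALSE]
  ctrs <- .bin_centers(list(x_edges = landscape$x_edges,
                            y_edges = landscape$y_edges))
  occ <- as.vector(landscape$occupied)
  basin_min <- function(pt) {
    d2 <- (ctrs[, 1] - pt[1])^2 + (ctrs[, 2] - pt[2])^2
    sel <- occ & d2 <= basin_radius^2
    if (!any(sel)) stop("no occupied bins within basin_radius of a path endpoint")
    min(as.vector(landscape$F)[sel])
  }
  f_react <- basin_min(ends[1, ])
  f_prod <- basin_min(ends[2, ])
  list(barrier = max(vals) - f_react, dG = f_prod - f_react,
       reactant = f_react, product = f_prod)
}

## --- uncertainties ---------------------------------------------------------

.resample_blocks <- function(ws, block_len, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  trajs <- lapply(ws$trajectories, function(tr) {
    n <- nrow(tr$samples)
    bl <- max(1L, min(block_len, n))
    nblk <- ceiling(n / bl)
    starts <- (sample.int(nblk, nblk, replace = TRUE) - 1L) * bl + 1L
    idx <- unlist(lapply(starts, function(s) s:min(s + bl - 1L, n)))
    idx <- idx[seq_len(min(length(idx), n))]
    tr$samples <- tr$samples[idx, , drop = FALSE]
    tr
  })
  window_set(trajs)
}

#' Block-bootstrap replicates of a landscape statistic
#'
#' Resamples contiguous blocks of each window's samples (preserving
#' autocorrelation), re-runs the estimator, and evaluates `statistic` on
#' every replicate landscape.
#'
#' @param windows a `window_set`.
#' @param statistic function mapping a `free_energy_landscape` to a numeric
#'   vector (e.g. a barrier extraction).
#' @param estimator `"wham"`, `"mbar"` or `"vfep"`.
#' @param n_boot number of bootstrap replicates.
#' @param block_len block length in samples (default: a twentieth of the
#'   shortest window).
#' @param seed integer seed.
#' @param ... passed to the estimator (a shared `grid` is recommended).
#' @return matrix of replicate statistics (n_boot rows).
#' @export
fes_bootstrap <- function(windows, statistic, estimator = "wham",
                          n_boot = 50, block_len = NULL, seed = 1, ...) {
  if (is.null(block_len)) {
    nmin <- min(vapply(windows$trajectories, function(t) nrow(t$samples),
                       numeric(1)))
    block_len <- max(1L, floor(nmin / 20))
  }
  reps <- lapply(seq_len(n_boot), function(b) {
    wsb <- .resample_blocks(windows, block_len, seed + 7919L * b)
    statistic(reconstruct_fes(wsb, estimator, ...))
  })
  do.call(rbind, lapply(reps, function(r) as.numeric(r)))
}

#' Per-bin block-bootstrap uncertainty of a landscape
#'
#' @inheritParams fes_bootstrap
#' @param bins,occupied_min forwarded to the estimator; the bootstrap grid is
#'   frozen to the full-data grid so replicate bins align.
#' @return a `free_energy_landscape` whose `uncertainty` matrix holds the
#'   per-bin bootstrap standard deviation (NA where any replicate left the
#'   bin unoccupied).
#' @export
block_uncertainty <- function(windows, estimator = "wham", n_boot = 30,
                              block_len = NULL, seed = 1, bins = 50,
                              occupied_min = 10) {
  full <- reconstruct_fes(windows, estimator, bins = bins,
                          occupied_min = occupied_min)
  grid <- list(x_edges = full$x_edges, y_edges = full$y_edges)
  reps <- fes_bootstrap(windows, statistic = function(l) as.vector(l$F),
                        estimator = estimator, n_boot = n_boot,
                        block_len = block_len, seed = seed,
                        grid = grid, occupied_min = occupied_min)
  sds <- apply(reps, 2, function(v) if (any(is.na(v))) NA_real_ else stats::sd(v))
  full$uncertainty <- matrix(sds, nrow(full$F))
  full
}

#' Export a landscape as a plain-text matrix
#'
#' Writes the free-energy matrix with bin-center coordinates in the first
#' row/column; NA marks unoccupied bins.
#' @param landscape a `free_energy_landscape`.
#' @param file output path.
#' @export
write_landscape <- function(landscape, file) {
  cx <- (landscape$x_edges[-1] + landscape$x_edges[-length(landscape$x_edges)]) / 2
  cy <- (landscape$y_edges[-1] + landscape$y_edges[-length(landscape$y_edges)]) / 2
  M <- rbind(c(NA, cy), cbind(cx, landscape$F))
  utils::write.table(M, file, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
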