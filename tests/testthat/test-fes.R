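# Free-energy reconstruction: umbrella grids, the three estimators on
# closed-form cases, barrier extraction and bootstrap uncertainties.

test_that("umbrella grids form inclusive lattices with the documented counts", {
  expect_length(make_umbrella_grid(c(-1, 1, -1, 1), 13), 169)
  g4 <- make_umbrella_grid(c(0, 1, 0, 1), 2)
  expect_length(g4, 4)
  centers <- t(vapply(g4, function(w) w$center, numeric(2)))
  expect_equal(sort(centers[, 1]), c(0, 0, 1, 1))
  g9 <- make_umbrella_grid(c(0, 1, 0, 1), 3)
  expect_equal(sort(unique(vapply(g9, function(w) w$center[1], numeric(1)))),
               c(0, 0.5, 1))
  expect_equal(g9[[1]]$k, c(200, 200))   # default force constant
  expect_error(make_umbrella_grid(c(0, 0, 0, 1), 3), "degenerate")
})

test_that("a single harmonic window recovers the surface curvature", {
  s <- make_surface("harmonic-well", k = 10)
  w <- restraint_window(c(0, 0), k = 2)
  tr <- sample_window(s, w, n = 50000, seed = 2, dt = 0.03)
  ws <- window_set(list(tr))
  grid0 <- NULL
  for (est in c("wham", "mbar", "vfep")) {
    l <- reconstruct_fes(ws, est, bins = 40)
    grid <- list(x_edges = l$x_edges, y_edges = l$y_edges)
    pts <- stringpcet:::.bin_centers(grid)
    cnt <- tabulate(stringpcet:::.bin_index(tr$samples, grid),
                    nbins = length(l$F))
    sel <- as.vector(l$occupied) & cnt >= 50
    r2 <- pts[, 1]^2 + pts[, 2]^2
    fit <- lm(as.vector(l$F)[sel] ~ r2[sel], weights = cnt[sel])
    expect_equal(unname(2 * coef(fit)[2]), 10, tolerance = 0.05)
  }
})

test_that("two half-overlapping windows on a flat surface give a flat profile", {
  s <- make_surface("harmonic-well", k = 1e-9)  # effectively flat
  w1 <- restraint_window(c(-0.15, 0), k = 30)
  w2 <- restraint_window(c(0.15, 0), k = 30)
  ws <- window_set(list(sample_window(s, w1, n = 20000, seed = 1, dt = 0.02),
                        sample_window(s, w2, n = 20000, seed = 2, dt = 0.02)))
  l <- wham2d(ws, bins = 30, occupied_min = 200)
  # well-sampled bin free energies stay within a few standard errors of zero
  expect_lt(max(l$F[l$occupied]), 0.35)
})

test_that("wham and mbar agree and the window order does not matter", {
  s <- make_surface("harmonic-well", k = 5)
  wins <- make_umbrella_grid(c(-0.3, 0.3, -0.3, 0.3), 3, k = 50, steps = 3000)
  ws <- sample_windows(s, wins, seed = 30, dt = 5e-3)
  lw <- wham2d(ws, bins = 35)
  grid <- list(x_edges = lw$x_edges, y_edges = lw$y_edges)
  lm_ <- mbar_fes(ws, grid = grid)
  both <- lw$occupied & lm_$occupied
  expect_lt(max(abs(lw$F - lm_$F)[both]), 0.5)
  ws_perm <- window_set(ws$trajectories[c(5, 3, 9, 1, 2, 8, 7, 6, 4)])
  lp <- mbar_fes(ws_perm, grid = grid)
  expect_equal(lp$F, lm_$F, tolerance = 1e-6)
})

test_that("a single window degenerates mbar to the reweighted histogram", {
  s <- make_surface("harmonic-well", k = 8)
  w <- restraint_window(c(0, 0), k = 20)
  tr <- sample_window(s, w, n = 20000, seed = 5, dt = 0.01)
  ws <- window_set(list(tr))
  lm_ <- mbar_fes(ws, bins = 30)
  grid <- list(x_edges = lm_$x_edges, y_edges = lm_$y_edges)
  # direct reweighted histogram: F = -kT ln(sum exp(+beta*bias)) per bin
  beta <- 1 / kBT()
  bias <- 0.5 * 20 * rowSums(tr$samples^2)
  bl <- stringpcet:::.bin_index(tr$samples, grid)
  L <- length(lm_$F)
  F_direct <- vapply(seq_len(L), function(l) {
    v <- bias[bl == l]
    if (!length(v)) return(NA_real_)
    -kBT() * log(sum(exp(beta * (v - max(v))))) - max(v)
  }, numeric(1))
  F_direct <- F_direct - min(F_direct[as.vector(lm_$occupied)], na.rm = TRUE)
  occ <- as.vector(lm_$occupied)
  expect_equal(as.vector(lm_$F)[occ], F_direct[occ], tolerance = 1e-6)
})

test_that("disconnected window sets are rejected naming the components", {
  s <- make_surface("harmonic-well", k = 5)
  w1 <- restraint_window(c(-3, -3), k = 200)
  w2 <- restraint_window(c(3, 3), k = 200)
  ws <- window_set(list(sample_window(s, w1, n = 500, seed = 1),
                        sample_window(s, w2, n = 500, seed = 2)))
  expect_error(wham2d(ws, bins = 40), "disconnected")
})

test_that("variational profile rejects an under-determined basis", {
  s <- make_surface("harmonic-well", k = 5)
  w <- restraint_window(c(0, 0), k = 50)
  ws <- window_set(list(sample_window(s, w, n = 500, seed = 1)))
  expect_error(variational_profile(ws, knots = 40, bins = 30),
               "under-determined")
})

test_that("barrier extraction handles flat, planted and monotone landscapes", {
  mk_land <- function(Ffun, n = 41, lim = 1) {
    edges <- seq(-lim, lim, length.out = n + 1)
    ctr <- (edges[-1] + edges[-(n + 1)]) / 2
    Fm <- outer(ctr, ctr, Ffun)
    structure(list(x_edges = edges, y_edges = edges, F = Fm - min(Fm),
                   occupied = matrix(TRUE, n, n), estimator = "analytic",
                   kBT = kBT(), uncertainty = NULL),
              class = "free_energy_landscape")
  }
  path <- init_path(c(-0.8, -0.8), c(0.8, 0.8), 12)
  flat <- mk_land(function(x, y) 0 * x)
  pb <- path_barrier(flat, path)
  expect_equal(pb$barrier, 0)
  expect_equal(pb$dG, 0)
  # planted profile along the diagonal, analytic 1D oracle for the barrier
  f1d <- function(u) 12 * exp(-(u / 0.35)^2) + 7.5 * stats::plogis(u / 0.1)
  planted <- mk_land(function(x, y) {
    f1d((x + y) / 1.6) + 20 * ((x - y) / 2)^2
  })
  useq <- seq(-1, 1, length.out = 4001)
  b_exp <- max(f1d(useq)) - f1d(-1)
  pb2 <- path_barrier(planted, path, basin_radius = 0.05)
  expect_equal(pb2$barrier, b_exp, tolerance = 0.01)
  expect_equal(pb2$dG, 7.5, tolerance = 0.01)
  # monotone ramp: barrier equals the reaction free energy
  ramp <- mk_land(function(x, y) 2 * (x + y + 2))
  pb3 <- path_barrier(ramp, path, basin_radius = 0.04)
  expect_equal(pb3$barrier, pb3$dG, tolerance = 0.06)
})

test_that("block bootstrap uncertainty is zero for degenerate samples and shrinks with n", {
  s <- make_surface("harmonic-well", k = 5)
  w <- restraint_window(c(0, 0), k = 30)
  # degenerate: constant samples -> zero uncertainty
  tr0 <- sample_window(s, w, n = 200, seed = 1)
  tr0$samples <- matrix(0.05, 200, 2)
  l0 <- block_uncertainty(window_set(list(tr0)), n_boot = 8, seed = 1,
                          bins = 5, occupied_min = 1)
  expect_equal(max(l0$uncertainty, na.rm = TRUE), 0)
  # scaling: 4x samples roughly halve the bootstrap sd
  tr1 <- sample_window(s, w, n = 4000, seed = 2, dt = 0.01)
  tr2 <- sample_window(s, w, n = 16000, seed = 3, dt = 0.01)
  u1 <- block_uncertainty(window_set(list(tr1)), n_boot = 24, seed = 4,
                          bins = 12, occupied_min = 30)
  u2 <- block_uncertainty(window_set(list(tr2)), n_boot = 24, seed = 4,
                          bins = 12, occupied_min = 30)
  m1 <- median(u1$uncertainty[u1$occupied], na.rm = TRUE)
  m2 <- median(u2$uncertainty[u2$occupied], na.rm = TRUE)
  expect_lt(m2 / m1, 0.8)
  expect_gt(m2 / m1, 0.25)
  # seeded reproducibility
  u1b <- block_uncertainty(window_set(list(tr1)), n_boot = 24, seed = 4,
                           bins = 12, occupied_min = 30)
  expect_identical(u1$uncertainty, u1b$uncertainty)
})

test_that("adding a constant to the surface leaves the landscape unchanged", {
  s1 <- make_surface("harmonic-well", k = 8)
  s2 <- s1
  s2$components <- list(stringpcet:::.gauss_comp(5, c(0, 0), 1e4))  # +5 everywhere
  w <- restraint_window(c(0, 0), k = 20)
  l1 <- wham2d(window_set(list(sample_window(s1, w, n = 5000, seed = 7))), bins = 25)
  l2 <- wham2d(window_set(list(sample_window(s2, w, n = 5000, seed = 7))), bins = 25)
  expect_equal(l1$F, l2$F, tolerance = 1e-6)
})
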