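# String method: path construction, reparameterization, drift, the
# convergence rule, and full runs on analytic landscapes.

test_that("straight initialization places nodes by linear interpolation", {
  p <- init_path(c(0, 0), c(1, 1), 5)
  expect_equal(p$nodes, cbind(seq(0, 1, 0.25), seq(0, 1, 0.25)))
  expect_equal(path_length(init_path(c(-0.8, -0.8), c(0.8, 0.8), 12)),
               2 * sqrt(2) * 0.8)
  expect_error(init_path(c(0, 0), c(0, 0), 5), "coincident")
})

test_that("initialization through a via point spaces nodes along the polyline", {
  p <- init_path(c(0, 0), c(1, 1), 19, via = c(1, 0))
  seg <- sqrt(rowSums(diff(p$nodes)^2))
  expect_equal(seg, rep(2 / 18, 18), tolerance = 1e-9)
  expect_equal(p$nodes[1, ], c(0, 0))
  expect_equal(p$nodes[19, ], c(1, 1))
  # the corner lies on the polyline: node 10 at the corner
  expect_equal(p$nodes[10, ], c(1, 0), tolerance = 1e-9)
})

test_that("reparameterization matches the closed-form parabola arclength partition", {
  curve <- function(s) cbind(s, s^2)
  nodes <- reparameterize(curve, 11)
  total <- parabola_arclength(1)
  for (i in 2:10) {
    expect_equal(parabola_arclength(nodes[i, 1]), total * (i - 1) / 10,
                 tolerance = 1e-4)
  }
  expect_equal(nodes[1, ], c(0, 0))
  expect_equal(nodes[11, ], c(1, 1))
})

test_that("spline refit of a quarter circle yields equal arc angles", {
  th <- seq(0, pi / 2, length.out = 9)
  p <- stringpcet:::new_string_path(cbind(cos(th), sin(th)), fit = "spline")
  rp <- refit_path(p)
  ang <- atan2(rp$nodes[, 2], rp$nodes[, 1])
  expect_lt(max(abs(diff(ang) - pi / 2 / 8)), 1e-3)
})

test_that("zero drift on a straight path is a fixed point of refitting", {
  p <- init_path(c(0, 0), c(2, 1), 8)
  for (fit in c("spline", "poly4")) {
    rp <- refit_path(p, fit = fit)
    expect_lt(max(abs(rp$nodes - p$nodes)), 1e-6)
  }
})

test_that("polynomial and spline refits agree on smooth paths", {
  th <- seq(0, pi / 3, length.out = 12)
  nodes <- cbind(cos(th), sin(th))
  p <- stringpcet:::new_string_path(nodes, fit = "spline")
  a <- refit_path(p, fit = "spline")
  b <- refit_path(p, fit = "poly4")
  expect_lt(max(sqrt(rowSums((a$nodes - b$nodes)^2))), 0.05)
})

test_that("the sum-of-squares / max-deviation rule classifies histories exactly", {
  h <- function(ssq, mx = rep(0.001, length(ssq))) {
    data.frame(ssq = ssq, max_dev = mx)
  }
  expect_true(check_convergence(h(c(0.001, 0.001, 0.001))))
  expect_false(check_convergence(h(c(0.001, 0.009, 0.001))))
  expect_true(check_convergence(h(c(0.9, 0.5, 0, 0, 0))))
  expect_false(check_convergence(h(c(0.001, 0.001))))          # too short
  expect_false(check_convergence(h(rep(0.001, 3), c(0.01, 0.06, 0.01))))
  expect_true(check_convergence(h(rep(0.0079, 3), rep(0.049, 3))))
  expect_false(check_convergence(h(rep(0.008, 3))))             # strict <
})

test_that("drift vanishes at a minimum and follows the Gaussian mean shift on a wall", {
  s <- make_surface("harmonic-well", k = 20)
  tmpl <- restraint_window(c(0, 0), k = 200, steps = 5000)
  p <- stringpcet:::new_string_path(rbind(c(0, 0), c(0.1, 0), c(0.2, 0)))
  dr <- estimate_drift(p, s, tmpl, seed = 1, pin_ends = FALSE, dt = 2e-3)
  # node at the minimum: drift ~ 0
  expect_lt(sqrt(sum(dr[1, ]^2)), 0.02)
  # node offset on the harmonic wall: mean shift = -k_s*x0/(k_s+k_r)
  expect_equal(dr[3, 1], -20 * 0.2 / 220, tolerance = 0.25)
  # quadrature drift is noiseless and exact
  drq <- estimate_drift(p, s, tmpl, seed = 1, method = "quadrature",
                        pin_ends = FALSE)
  expect_equal(drq[3, 1], -20 * 0.2 / 220, tolerance = 1e-3)
})

test_that("degenerate strings with both endpoints at one minimum converge immediately", {
  s <- make_surface("harmonic-well", k = 10)
  tmpl <- restraint_window(c(0, 0), k = 200, steps = 100)
  p <- init_path(c(-1e-3, 0), c(1e-3, 0), 6)
  res <- run_string(s, p, tmpl, seed = 2, max_iter = 10)
  expect_true(res$converged)
  expect_lte(nrow(res$record), 4)
  expect_lt(max(abs(res$path$nodes)), 0.05)
})

test_that("a steepest-descent minimum-energy path is a fixed point of one noiseless iteration", {
  s <- make_surface("pcet-double-well")
  sp <- find_stationary_points(s, n_grid = 161)
  sad <- sp$saddles[sp$saddles[, 1] > 0 & sp$saddles[, 2] < 0, , drop = FALSE][1, ]
  # oracle MEP: steepest descent from both sides of the saddle
  descend <- function(x0, step = 2e-4, n_max = 60000) {
    path <- matrix(NA_real_, n_max, 2)
    x <- x0
    for (i in seq_len(n_max)) {
      g <- as.numeric(surface_gradient(s, x))
      if (sqrt(sum(g^2)) < 1e-4) break
      x <- x - step * g / max(sqrt(sum(g^2)), 1)
      path[i, ] <- x
    }
    path[stats::complete.cases(path), , drop = FALSE]
  }
  H <- matrix(0, 2, 2)
  for (k in 1:2) {
    dp <- c(0, 0); dp[k] <- 1e-5
    H[, k] <- (surface_gradient(s, sad + dp) - surface_gradient(s, sad - dp)) / 2e-5
  }
  v <- eigen((H + t(H)) / 2, symmetric = TRUE)$vectors[, 2]  # unstable mode
  mep <- rbind(descend(sad + 0.01 * v)[nrow(descend(sad + 0.01 * v)):1, ],
               sad, descend(sad - 0.01 * v))
  # resample the traced MEP at equal arclength into a string
  seg <- sqrt(rowSums(diff(mep)^2))
  cum <- c(0, cumsum(seg))
  targets <- seq(0, cum[length(cum)], length.out = 15)
  nodes <- t(vapply(targets, function(ss) {
    mep[which.min(abs(cum - ss)), ]
  }, numeric(2)))
  p1 <- stringpcet:::new_string_path(nodes, fit = "spline")
  tmpl <- restraint_window(c(0, 0), k = 2000, steps = 100)
  suppressWarnings(
    dr <- estimate_drift(p1, s, tmpl, seed = 1, method = "quadrature"))
  p2 <- refit_path(p1, dr)
  expect_lt(max(sqrt(rowSums((p2$nodes - p1$nodes)^2))), 1e-3 * 5)
})

test_that("node count and pinned endpoints are preserved across iterations", {
  s <- make_surface("pcet-double-well")
  tmpl <- restraint_window(c(0, 0), k = 200, steps = 150)
  p0 <- init_path(c(-0.8, -0.8), c(0.8, 0.8), 12, via = c(0.8, -0.8))
  res <- run_string(s, p0, tmpl, seed = 3, max_iter = 5)
  expect_equal(nrow(res$path$nodes), 12)
  expect_equal(res$path$nodes[1, ], c(-0.8, -0.8))
  expect_equal(res$path$nodes[12, ], c(0.8, 0.8))
})

test_that("distinct initializations converge to distinct channel strings", {
  s <- make_surface("pcet-double-well")
  tmpl <- restraint_window(c(0, 0), k = 200, steps = 200)
  rA <- run_string(s, init_path(c(-0.8, -0.8), c(0.8, 0.8), 19,
                                via = c(0.8, -0.8)), tmpl, seed = 11)
  rB <- run_string(s, init_path(c(-0.8, -0.8), c(0.8, 0.8), 19,
                                via = c(-0.8, 0.8)), tmpl, seed = 12)
  expect_true(rA$converged && rB$converged)
  mid_A <- rA$path$nodes[10, ]
  mid_B <- rB$path$nodes[10, ]
  expect_gt(sqrt(sum((mid_A - mid_B)^2)), 1)   # opposite channels
  eR <- surface_energy(s, matrix(c(-0.802, -0.802), 1))
  bA <- max(surface_energy(s, densify_path(rA$path, 400))) - eR
  bB <- max(surface_energy(s, densify_path(rB$path, 400))) - eR
  expect_gt(bB - bA, 2)   # alternative channel resolved as higher
})

test_that("noiseless drift settles into monotonically shrinking path updates on every preset", {
  cases <- list(
    list(s = make_surface("pcet-double-well"), k = 200,
         from = c(-0.8, -0.8), to = c(0.8, 0.8), via = c(0.8, -0.8)),
    list(s = make_surface("mueller-brown"), k = 500,
         from = c(-0.558, 1.442), to = c(0.623, 0.028), via = c(-0.05, 0.467)),
    list(s = make_surface("harmonic-well", k = 10), k = 200,
         from = c(-0.5, 0), to = c(0.5, 0), via = NULL))
  for (cs in cases) {
    tmpl <- restraint_window(c(0, 0), k = cs$k, steps = 100)
    suppressWarnings(
      res <- run_string(cs$s, init_path(cs$from, cs$to, 15, via = cs$via),
                        tmpl, seed = 1, method = "quadrature", max_iter = 25))
    ssq <- res$record$ssq
    n <- length(ssq)
    if (n >= 4) {
      tail3 <- ssq[(n - 2):n]
      expect_true(all(diff(tail3) <= 1e-8 + 0.05 * tail3[-3]))
      expect_lt(ssq[n], ssq[3] + 1e-8)
    } else {
      expect_true(res$converged)
    }
  }
})
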