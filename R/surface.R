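## Surrogate 2D energy surfaces for proton-coupled electron transfer (PCET)
## model studies. A surface is an analytic function of two reaction
## coordinates (RC1, RC2, Angstrom) built from generalized Gaussian
## components, an optional separable quartic double-well base term and an
## optional harmonic confinement. Energies are kcal/mol.

#' Build a generalized Gaussian component
#'
#' Internal helper returning exponent coefficients (a, b, c) such that the
#' component contributes `A * exp(a*dx^2 + b*dx*dy + c*dy^2)`.
#'
#' @param A amplitude (kcal/mol); negative values are wells.
#' @param center length-2 center (RC1, RC2).
#' @param sx,sy standard deviations along the (possibly rotated) principal
#'   axes.
#' @param theta rotation angle of the principal axes (radians).
#' @noRd
.gauss_comp <- function(A, center, sx, sy = sx, theta = 0) {
  if (sx <= 0 || sy <= 0) stop("non-positive width in Gaussian component")
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Q <- -0.5 * R %*% diag(c(1 / sx^2, 1 / sy^2)) %*% t(R)
  list(A = A, center = as.numeric(center), a = Q[1, 1], b = 2 * Q[1, 2], c = Q[2, 2])
}

.mb_components <- function() {
  # Mueller-Brown benchmark potential parameters
  A <- c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  lapply(seq_len(4), function(i) {
    list(A = A[i], center = c(x0[i], y0[i]), a = a[i], b = b[i], c = cc[i])
  })
}

.new_surface <- function(label, components = list(), base = NULL,
                         confine = NULL, domain, stationary = NULL) {
  structure(list(label = label, components = components, base = base,
                 confine = confine, domain = domain, stationary = stationary),
            class = "model_surface")
}

#' Evaluate the energy of a model surface
#'
#' @param surface a `model_surface` from [make_surface()].
#' @param x numeric length-2 point or an n-by-2 matrix of (RC1, RC2) points.
#' @return numeric vector of energies (kcal/mol).
#' @export
surface_energy <- function(surface, x) {
  x <- .as_points(x)
  e <- numeric(nrow(x))
  for (cp in surface$components) {
    dx <- x[, 1] - cp$center[1]
    dy <- x[, 2] - cp$center[2]
    e <- e + cp$A * exp(cp$a * dx^2 + cp$b * dx * dy + cp$c * dy^2)
  }
  if (!is.null(surface$base)) {
    q <- surface$base$q
    h <- surface$base$h
    e <- e + h * ((x[, 1] / q)^2 - 1)^2 + h * ((x[, 2] / q)^2 - 1)^2
  }
  if (!is.null(surface$confine)) {
    k <- surface$confine$k
    ctr <- surface$confine$center
    e <- e + 0.5 * k[1] * (x[, 1] - ctr[1])^2 + 0.5 * k[2] * (x[, 2] - ctr[2])^2
  }
  e
}

#' Analytic gradient of a model surface
#'
#' @inheritParams surface_energy
#' @return n-by-2 matrix of gradients (kcal/mol/Angstrom).
#' @export
surface_gradient <- function(surface, x) {
  x <- .as_points(x)
  gx <- numeric(nrow(x))
  gy <- numeric(nrow(x))
  for (cp in surface$components) {
    dx <- x[, 1] - cp$center[1]
    dy <- x[, 2] - cp$center[2]
    g <- cp$A * exp(cp$a * dx^2 + cp$b * dx * dy + cp$c * dy^2)
    gx <- gx + g * (2 * cp$a * dx + cp$b * dy)
    gy <- gy + g * (cp$b * dx + 2 * cp$c * dy)
  }
  if (!is.null(surface$base)) {
    q <- surface$base$q
    h <- surface$base$h
    gx <- gx + h * 4 * ((x[, 1] / q)^2 - 1) * x[, 1] / q^2
    gy <- gy + h * 4 * ((x[, 2] / q)^2 - 1) * x[, 2] / q^2
  }
  if (!is.null(surface$confine)) {
    k <- surface$confine$k
    ctr <- surface$confine$center
    gx <- gx + k[1] * (x[, 1] - ctr[1])
    gy <- gy + k[2] * (x[, 2] - ctr[2])
  }
  cbind(gx, gy, deparse.level = 0)
}

.as_points <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 2)
    x <- matrix(x, 1, 2)
  }
  stopifnot(ncol(x) == 2)
  storage.mode(x) <- "double"
  x
}

#' @export
print.model_surface <- function(x, ...) {
  cat("<model_surface>", x$label, "\n")
  cat("  components:", length(x$components),
      if (!is.null(x$base)) "+ quartic double-well base" else "",
      if (!is.null(x$confine)) "+ harmonic confinement" else "", "\n")
  cat(sprintf("  domain: RC1 [%.2f, %.2f]  RC2 [%.2f, %.2f] Angstrom\n",
              x$domain[1], x$domain[2], x$domain[3], x$domain[4]))
  if (!is.null(x$stationary)) {
    cat("  documented minima:\n")
    print(round(x$stationary$minima, 3))
  }
  invisible(x)
}

#' Construct a surrogate energy surface
#'
#' Available presets:
#'
#' * `"harmonic-well"`: isotropic harmonic well, `E = k/2 * |r - center|^2`.
#'   Used for closed-form validation of the restrained sampler and of the
#'   free-energy estimators.
#' * `"mueller-brown"`: the classic Mueller-Brown benchmark with three minima
#'   and two saddles; exercises the string method on a rugged landscape.
#' * `"pcet-double-well"`: a PCET-like double well with reactant and product
#'   minima near (-0.8, -0.8) and (+0.8, +0.8) Angstrom, two metastable
#'   stepwise channels through the off-diagonal corners, and a calibrated
#'   topography: the lower channel carries a minimum-energy-path barrier of
#'   `barrier` kcal/mol (default 12), the other channel `alt_barrier`
#'   (default 15), and the reaction is endergonic by `dG` (default 7.5).
#'   Amplitudes of the shaping Gaussians are calibrated at construction by a
#'   deterministic secant loop against grid barrier searches, so the planted
#'   values are exact ground truths for downstream estimators.
#'
#' @param preset one of `"pcet-double-well"`, `"mueller-brown"`,
#'   `"harmonic-well"`.
#' @param ... preset overrides: `k` and `center` for the harmonic well;
#'   `barrier`, `dG`, `alt_barrier` (kcal/mol) for the PCET double well.
#' @return a `model_surface` object with documented stationary points in
#'   `$stationary` where applicable.
#' @examples
#' s <- make_surface("harmonic-well", k = 2)
#' surface_energy(s, c(0, 0))
#' @export
make_surface <- function(preset = c("pcet-double-well", "mueller-brown",
                                    "harmonic-well"), ...) {
  preset <- match.arg(preset)
  opts <- list(...)
  switch(preset,
    "harmonic-well" = {
      k <- opts$k %||% 1
      center <- opts$center %||% c(0, 0)
      if (any(k <= 0)) stop("non-positive force constant for harmonic-well")
      .new_surface("harmonic-well",
                   confine = list(k = rep(as.numeric(k), length.out = 2),
                                  center = center),
                   domain = c(-4, 4, -4, 4),
                   stationary = list(minima = matrix(center, 1, 2),
                                     saddles = NULL))
    },
    "mueller-brown" = {
      .new_surface("mueller-brown",
                   components = .mb_components(),
                   domain = c(-1.8, 1.3, -0.5, 2.3),
                   stationary = list(
                     minima = rbind(c(-0.558, 1.442), c(0.623, 0.028),
                                    c(-0.050, 0.467)),
                     saddles = rbind(c(-0.822, 0.624), c(0.212, 0.293))))
    },
    "pcet-double-well" = .make_pcet_surface(
      barrier = opts$barrier %||% 12,
      dG = opts$dG %||% 7.5,
      alt_barrier = opts$alt_barrier %||% 15)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## pcet-double-well construction.  Shape: separable quartic double well
## (four-fold corner topology) whose two off-diagonal corner basins are
## converted to transversely stable passes by anisotropic corner bumps; the
## reactant well is deepened to plant the reaction free energy.  Three
## amplitudes are calibrated: reactant-deepening (-> dG), corner bump A
## (-> main stepwise barrier), corner bump B (-> alternative barrier).
.make_pcet_surface <- function(barrier = 12, dG = 7.5, alt_barrier = 15,
                               q = 0.8, h = 3.0, max_iter = 40, tol = 0.02) {
  if (barrier <= 0 || alt_barrier <= 0) stop("barriers must be positive")
  if (dG >= barrier) stop("planted dG must lie below the planted barrier")
  build <- function(d_t, cA, cB) {
    comps <- list(
      .gauss_comp(-d_t, c(-q, -q), 0.5),                      # reactant deepening
      .gauss_comp(cA, c(q, -q), sx = 0.55, sy = 0.32, theta = -pi / 4),
      .gauss_comp(cB, c(-q, q), sx = 0.55, sy = 0.32, theta = -pi / 4),
      .gauss_comp(4.0, c(0, 0), 0.35)                          # concerted ridge
    )
    .new_surface("pcet-double-well", components = comps,
                 base = list(h = h, q = q),
                 domain = c(-1.6, 1.6, -1.6, 1.6))
  }
  refine_min <- function(s, x0) {
    fit <- stats::optim(x0, function(p) surface_energy(s, p),
                        function(p) as.numeric(surface_gradient(s, p)),
                        method = "BFGS", control = list(reltol = 1e-14))
    list(x = fit$par, E = fit$value)
  }
  d_t <- dG; cA <- barrier - dG + 0.5; cB <- alt_barrier - dG + 0.5
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    s <- build(d_t, cA, cB)
    mR <- refine_min(s, c(-q, -q))
    mP <- refine_min(s, c(q, q))
    bA <- .grid_minimax(s, mR$x, mP$x, n_grid = 161,
                        mask = function(x, y) x - y >= -0.15) - mR$E
    bB <- .grid_minimax(s, mR$x, mP$x, n_grid = 161,
                        mask = function(x, y) x - y <= 0.15) - mR$E
    errs <- c(dG = (mP$E - mR$E) - dG, bA = bA - barrier, bB = bB - alt_barrier)
    if (max(abs(errs)) < tol) { ok <- TRUE; break }
    d_t <- d_t + errs["dG"]
    cA <- cA - errs["bA"]
    cB <- cB - errs["bB"]
  }
  if (!ok) stop("pcet-double-well calibration failed to converge")
  s$stationary <- list(minima = rbind(reactant = mR$x, product = mP$x),
                       saddles = NULL,
                       barrier = bA, alt_barrier = bB, dG = mP$E - mR$E)
  s$pcet <- list(barrier = barrier, dG = dG, alt_barrier = alt_barrier, q = q)
  s
}

#' Locate stationary points of a surface by dense grid search
#'
#' Scans the surface on a dense regular grid, refines every candidate
#' stationary point by minimizing the squared gradient norm, and classifies
#' the result by the eigenvalues of a finite-difference Hessian.
#'
#' @param surface a `model_surface`.
#' @param n_grid grid points per axis.
#' @param grad_tol gradient-norm tolerance for accepting a stationary point.
#' @param merge_tol distance below which two stationary points are merged.
#' @return list with matrices `minima`, `saddles`, `maxima` (possibly NULL).
#' @export
find_stationary_points <- function(surface, n_grid = 201, grad_tol = 1e-4,
                                   merge_tol = 0.05) {
  d <- surface$domain
  xs <- seq(d[1], d[2], length.out = n_grid)
  ys <- seq(d[3], d[4], length.out = n_grid)
  pts <- cbind(rep(xs, times = n_grid), rep(ys, each = n_grid))
  g <- surface_gradient(surface, pts)
  gn <- matrix(g[, 1]^2 + g[, 2]^2, n_grid, n_grid)
  # candidates: grid-local minima of |grad|^2
  cand <- list()
  for (i in 2:(n_grid - 1)) {
    for (j in 2:(n_grid - 1)) {
      v <- gn[i, j]
      if (v <= min(gn[(i - 1):(i + 1), (j - 1):(j + 1)]) &&
          v < (mean(gn) * 1e-2)) {
        cand[[length(cand) + 1]] <- c(xs[i], ys[j])
      }
    }
  }
  fd_hess <- function(p, eps = 1e-5) {
    H <- matrix(0, 2, 2)
    for (k in 1:2) {
      dp <- c(0, 0); dp[k] <- eps
      H[, k] <- (surface_gradient(surface, p + dp) -
                 surface_gradient(surface, p - dp)) / (2 * eps)
    }
    (H + t(H)) / 2
  }
  tol_abs <- max(grad_tol, 1e-8 * sqrt(mean(gn)))
  res <- list()
  for (p0 in cand) {
    p <- p0
    ok <- FALSE
    for (it in 1:60) {   # Newton refinement on the gradient root
      gg <- as.numeric(surface_gradient(surface, p))
      if (sqrt(sum(gg^2)) < tol_abs) { ok <- TRUE; break }
      H <- fd_hess(p)
      step <- tryCatch(solve(H, -gg), error = function(e) NULL)
      if (is.null(step)) break
      if (sqrt(sum(step^2)) > 0.2) step <- step * 0.2 / sqrt(sum(step^2))
      p <- p + step
    }
    if (!ok) next
    if (p[1] < d[1] || p[1] > d[2] || p[2] < d[3] || p[2] > d[4]) next
    res[[length(res) + 1]] <- p
  }
  if (!length(res)) return(list(minima = NULL, saddles = NULL, maxima = NULL))
  pts <- do.call(rbind, res)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(pts))) {
      if (j <= i || !keep[j]) next
      if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < merge_tol) keep[j] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  hess_eig <- function(p, eps = 1e-4) {
    H <- matrix(0, 2, 2)
    for (k in 1:2) {
      dp <- c(0, 0); dp[k] <- eps
      H[, k] <- (surface_gradient(surface, p + dp) -
                 surface_gradient(surface, p - dp)) / (2 * eps)
    }
    eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  }
  cls <- apply(pts, 1, function(p) {
    ev <- hess_eig(p)
    if (all(ev > 0)) "min" else if (all(ev < 0)) "max" else "saddle"
  })
  pick <- function(what) {
    m <- pts[cls == what, , drop = FALSE]
    if (nrow(m)) m else NULL
  }
  list(minima = pick("min"), saddles = pick("saddle"), maxima = pick("max"))
}

## Minimax (lowest highest-energy crossing) barrier between two basins on a
## dense grid, by union-find over cells activated in order of energy.
## Returns the absolute threshold energy at which `from` and `to` connect.
.grid_minimax <- function(surface, from, to, n_grid = 201, mask = NULL) {
  d <- surface$domain
  xs <- seq(d[1], d[2], length.out = n_grid)
  ys <- seq(d[3], d[4], length.out = n_grid)
  pts <- cbind(rep(xs, times = n_grid), rep(ys, each = n_grid))
  E <- surface_energy(surface, pts)
  allowed <- rep(TRUE, length(E))
  if (!is.null(mask)) allowed <- mask(pts[, 1], pts[, 2])
  idx_of <- function(p) {
    i <- which.min(abs(xs - p[1]))
    j <- which.min(abs(ys - p[2]))
    (j - 1L) * n_grid + i
  }
  a <- idx_of(from); b <- idx_of(to)
  if (!allowed[a] || !allowed[b]) stop("endpoint excluded by mask")
  parent <- seq_along(E)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(E)
  active <- rep(FALSE, length(E))
  for (cell in ord) {
    if (!allowed[cell]) next
    active[cell] <- TRUE
    i <- ((cell - 1L) %% n_grid) + 1L
    j <- ((cell - 1L) %/% n_grid) + 1L
    for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
      if (nb[1] < 1L || nb[1] > n_grid || nb[2] < 1L || nb[2] > n_grid) next
      k <- (nb[2] - 1L) * n_grid + nb[1]
      if (active[k]) {
        ra <- find(cell); rb <- find(k)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (active[a] && active[b] && find(a) == find(b)) return(E[cell])
  }
  stop("basins never connect on the grid (check mask)")
}

#' Grid-search minimum-energy-path barrier between two basins
#'
#' Computes the lowest maximum energy that any grid path connecting the two
#' basins must cross (a minimax flood-fill over a dense energy grid), minus
#' the refined energy of the starting basin. This is the independent
#' geometric ground truth against which sampled free-energy reconstructions
#' are compared.
#'
#' @param surface a `model_surface`.
#' @param from,to length-2 starting points for the two basins (refined to
#'   the nearest local minimum internally).
#' @param n_grid grid points per axis.
#' @param mask optional `function(x, y)` returning TRUE for admissible grid
#'   cells; used to isolate one reaction channel.
#' @return list with `barrier` (kcal/mol above the `from` minimum), `dG`
#'   (product minus reactant minimum), and the refined `minima`.
#' @export
grid_barrier <- function(surface, from, to, n_grid = 201, mask = NULL) {
  refine <- function(x0) {
    fit <- stats::optim(x0, function(p) surface_energy(surface, p),
                        function(p) as.numeric(surface_gradient(surface, p)),
                        method = "BFGS", control = list(reltol = 1e-14))
    list(x = fit$par, E = fit$value)
  }
  mA <- refine(from); mB <- refine(to)
  thr <- .grid_minimax(surface, mA$x, mB$x, n_grid = n_grid, mask = mask)
  list(barrier = thr - mA$E, dG = mB$E - mA$E,
       minima = rbind(from = mA$x, to = mB$x))
}
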