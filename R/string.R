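## Finite-temperature string method in 2D reaction-coordinate space.
## A string is an ordered set of nodes; each iteration estimates the drift
## of restrained sampling about every node, refits a smooth curve
## (fourth-order polynomial or cubic spline) through the displaced nodes,
## and redistributes the nodes to equal arclength. Convergence follows the
## sum-of-squares / maximum-deviation rule.

#' Initialize a string path
#'
#' Places `n_nodes` nodes equally spaced (by arclength) along the straight
#' segment between the endpoints, or along the two-segment polyline through
#' `via`.
#'
#' @param from,to length-2 endpoints in (RC1, RC2), Angstrom.
#' @param n_nodes number of nodes (>= 4); typical choices are 12 for
#'   concerted-style and 19 for stepwise-style paths.
#' @param via optional length-2 intermediate point.
#' @param fit fit mode used later by [refit_path()]: `"spline"` (default) or
#'   `"poly4"`.
#' @return a `string_path` object.
#' @examples
#' init_path(c(0, 0), c(1, 1), 5)
#' @export
init_path <- function(from, to, n_nodes, via = NULL, fit = c("spline", "poly4")) {
  fit <- match.arg(fit)
  stopifnot(n_nodes >= 4)
  from <- as.numeric(from); to <- as.numeric(to)
  if (sqrt(sum((from - to)^2)) < 1e-12) stop("coincident endpoints")
  wp <- rbind(from, if (!is.null(via)) as.numeric(via), to)
  seg <- sqrt(rowSums((wp[-1, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  targets <- seq(0, cum[length(cum)], length.out = n_nodes)
  nodes <- t(vapply(targets, function(s) {
    j <- max(which(cum <= s + 1e-15))
    if (j == nrow(wp)) return(wp[j, ])
    f <- (s - cum[j]) / seg[j]
    wp[j, ] + f * (wp[j + 1, ] - wp[j, ])
  }, numeric(2)))
  new_string_path(nodes, iteration = 0L, fit = fit)
}

new_string_path <- function(nodes, iteration = 0L, fit = "spline") {
  structure(list(nodes = nodes, iteration = as.integer(iteration), fit = fit),
            class = "string_path")
}

#' @export
print.string_path <- function(x, ...) {
  cat(sprintf("<string_path> %d nodes, iteration %d, fit = %s, length %.3f A\n",
              nrow(x$nodes), x$iteration, x$fit, path_length(x)))
  invisible(x)
}

#' Polyline length of a string path
#' @param path a `string_path`.
#' @return total node-to-node Euclidean length (Angstrom).
#' @export
path_length <- function(path) {
  nd <- path$nodes
  sum(sqrt(rowSums((nd[-1, , drop = FALSE] - nd[-nrow(nd), , drop = FALSE])^2)))
}

#' Estimate per-node sampling drift
#'
#' For every node, the biased sample mean under a harmonic restraint centered
#' at the node is computed and the drift is `mean - node`. With
#' `method = "quadrature"` the exact biased-density mean replaces sampling
#' (noiseless drift). Endpoint drifts are zeroed when `pin_ends` is TRUE.
#'
#' @param path a `string_path`.
#' @param surface a `model_surface`.
#' @param template a `restraint_window` supplying force constants, step count
#'   and temperature (its center is ignored). A warning is issued if the
#'   force constants fall outside the customary 50-200 kcal/mol/A^2 range.
#' @param seed integer seed; node `i` uses `seed + i`.
#' @param method `"sample"` or `"quadrature"`.
#' @param dt integrator step size for sampling.
#' @param burnin fraction of initial samples discarded from each window mean.
#' @param pin_ends logical; keep endpoints fixed.
#' @return n-by-2 matrix of drifts (Angstrom).
#' @export
estimate_drift <- function(path, surface, template, seed,
                           method = c("sample", "quadrature"), dt = 2e-3,
                           burnin = 0.25, pin_ends = TRUE) {
  method <- match.arg(method)
  if (any(template$k < 50 | template$k > 200)) {
    warning("restraint force constant outside the customary 50-200 kcal/mol/A^2 range")
  }
  n <- nrow(path$nodes)
  drifts <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    if (pin_ends && (i == 1L || i == n)) next
    w <- restraint_window(path$nodes[i, ], k = template$k,
                          steps = template$steps,
                          temperature = template$temperature)
    mu <- if (method == "quadrature") {
      window_quadrature(surface, w)$mean
    } else {
      tr <- tryCatch(sample_window(surface, w, seed = seed + i, dt = dt),
                     error = function(e) {
                       stop(sprintf("sampler failure at node %d: %s", i,
                                    conditionMessage(e)))
                     })
      keep <- seq.int(floor(burnin * nrow(tr$samples)) + 1L, nrow(tr$samples))
      colMeans(tr$samples[keep, , drop = FALSE])
    }
    drifts[i, ] <- mu - path$nodes[i, ]
  }
  drifts
}

#' Refit and reparameterize a string
#'
#' Displaces the nodes by their drifts, fits a smooth curve through the
#' displaced nodes (each coordinate against normalized arclength, either a
#' fourth-order polynomial or a cubic interpolating spline), and places the
#' nodes back at equal arclength along the fitted curve.
#'
#' @param path a `string_path`.
#' @param drifts n-by-2 drift matrix (default zero).
#' @param fit `"spline"` or `"poly4"`; defaults to the path's fit mode.
#' @return a `string_path` with updated nodes and `fit_residual` attribute
#'   (maximum distance between the fitted curve and the displaced nodes;
#'   zero for the interpolating spline).
#' @export
refit_path <- function(path, drifts = NULL, fit = NULL) {
  fit <- fit %||% path$fit
  nodes <- path$nodes
  if (!is.null(drifts)) nodes <- nodes + drifts
  n <- nrow(nodes)
  if (fit == "poly4" && n < 5) stop("fourth-order polynomial fit needs >= 5 nodes")
  seg <- sqrt(rowSums((nodes[-1, , drop = FALSE] - nodes[-n, , drop = FALSE])^2))
  if (any(seg == 0)) {
    # degenerate (coincident consecutive nodes): treat as converged point set
    out <- new_string_path(nodes, path$iteration + 1L, fit)
    attr(out, "fit_residual") <- 0
    return(out)
  }
  sarc <- c(0, cumsum(seg)) / sum(seg)
  curve <- .fit_curve(sarc, nodes, fit)
  resid <- max(sqrt(rowSums((curve(sarc) - nodes)^2)))
  newnodes <- reparameterize(curve, n)
  out <- new_string_path(newnodes, path$iteration + 1L, fit)
  attr(out, "fit_residual") <- resid
  out
}

.fit_curve <- function(sarc, nodes, fit) {
  if (fit == "poly4") {
    V <- cbind(1, sarc, sarc^2, sarc^3, sarc^4)
    fx <- stats::lm.fit(V, nodes[, 1])
    fy <- stats::lm.fit(V, nodes[, 2])
    if (any(is.na(fx$coefficients)) || any(is.na(fy$coefficients))) {
      stop("rank-deficient polynomial fit")
    }
    cf <- cbind(fx$coefficients, fy$coefficients)
    function(s) {
      V <- cbind(1, s, s^2, s^3, s^4)
      V %*% cf
    }
  } else {
    sfx <- stats::splinefun(sarc, nodes[, 1], method = "natural")
    sfy <- stats::splinefun(sarc, nodes[, 2], method = "natural")
    function(s) cbind(sfx(s), sfy(s))
  }
}

#' Equal-arclength node placement along a curve
#'
#' Given a parametric curve on `[0, 1]`, returns `n_nodes` points whose
#' cumulative arclengths are `i/(n-1)` of the total. Each location is found
#' by bisection on the cumulative-arclength function to a relative arclength
#' tolerance of 1e-6; the curve endpoints are returned exactly.
#'
#' @param curve function mapping a parameter vector in `[0, 1]` to an
#'   n-by-2 matrix of points.
#' @param n_nodes number of output nodes.
#' @param n_dense number of dense evaluations used for the arclength table.
#' @return n_nodes-by-2 matrix of points on the curve.
#' @export
reparameterize <- function(curve, n_nodes, n_dense = 4001) {
  sd <- seq(0, 1, length.out = n_dense)
  P <- curve(sd)
  if (any(!is.finite(P))) stop("non-finite curve values")
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-n_dense, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[n_dense]
  alen <- stats::approxfun(sd, cum)
  out <- matrix(NA_real_, n_nodes, 2)
  out[1, ] <- P[1, ]
  out[n_nodes, ] <- P[n_dense, ]
  for (i in seq(2, n_nodes - 1)) {
    target <- total * (i - 1) / (n_nodes - 1)
    lo <- 0; hi <- 1
    while ((hi - lo) * total > 1e-6 * total) {
      mid <- (lo + hi) / 2
      if (alen(mid) < target) lo <- mid else hi <- mid
    }
    out[i, ] <- curve((lo + hi) / 2)
  }
  out
}

#' Convergence test for a string iteration history
#'
#' A run is converged when both the sum-of-squares change and the maximum
#' per-node squared deviation between consecutive paths have stayed below
#' their thresholds (defaults 0.008 and 0.05 Angstrom^2) for at least
#' `n_consecutive` latest iterations.
#'
#' @param record a `convergence_record` (or data.frame with columns `ssq`
#'   and `max_dev`).
#' @param tol_ssq threshold on the sum-of-squares change, Angstrom^2.
#' @param tol_max threshold on the maximum node deviation, Angstrom^2.
#' @param n_consecutive required number of consecutive sub-threshold
#'   iterations.
#' @return logical.
#' @examples
#' h <- data.frame(ssq = c(0.1, 0.001, 0.001, 0.001),
#'                 max_dev = c(0.2, 0.01, 0.01, 0.01))
#' check_convergence(h)
#' @export
check_convergence <- function(record, tol_ssq = 0.008, tol_max = 0.05,
                              n_consecutive = 3) {
  if (NROW(record) < n_consecutive) return(FALSE)
  tail_ok <- utils::tail(record$ssq < tol_ssq & record$max_dev < tol_max,
                         n_consecutive)
  all(tail_ok)
}

#' Run the finite-temperature string method
#'
#' Iterates drift estimation, curve refitting and equal-arclength
#' reparameterization until the convergence rule is met or `max_iter` is
#' reached. Non-convergence is reported in the returned record, not raised.
#'
#' @inheritParams estimate_drift
#' @param max_iter maximum number of iterations.
#' @param verbose print one log line per iteration.
#' @return list with `path` (final `string_path`), `record` (data.frame with
#'   columns iteration, ssq, max_dev, converged) and `converged` flag.
#' @export
run_string <- function(surface, path, template, seed, max_iter = 30,
                       method = c("sample", "quadrature"), dt = 2e-3,
                       burnin = 0.25, pin_ends = TRUE,
                       tol_ssq = 0.008, tol_max = 0.05, n_consecutive = 3,
                       verbose = FALSE) {
  method <- match.arg(method)
  rec <- data.frame(iteration = integer(), ssq = numeric(),
                    max_dev = numeric(), converged = logical())
  for (it in seq_len(max_iter)) {
    drifts <- estimate_drift(path, surface, template,
                             seed = seed + 1000L * it, method = method,
                             dt = dt, burnin = burnin, pin_ends = pin_ends)
    newpath <- refit_path(path, drifts)
    d2 <- rowSums((newpath$nodes - path$nodes)^2)
    rec <- rbind(rec, data.frame(iteration = it, ssq = sum(d2),
                                 max_dev = max(d2), converged = FALSE))
    conv <- check_convergence(rec, tol_ssq, tol_max, n_consecutive)
    rec$converged[nrow(rec)] <- conv
    if (verbose) {
      message(sprintf("iter %2d  ssq %.5f  max_dev %.5f%s", it, sum(d2),
                      max(d2), if (conv) "  [converged]" else ""))
    }
    path <- newpath
    if (conv) break
  }
  structure(list(path = path, record = rec,
                 converged = isTRUE(rec$converged[nrow(rec)])),
            class = "string_result")
}

#' @export
print.string_result <- function(x, ...) {
  cat(sprintf("<string_result> %s after %d iterations (ssq %.2g, max_dev %.2g A^2)\n",
              if (x$converged) "converged" else "NOT converged",
              nrow(x$record), utils::tail(x$record$ssq, 1),
              utils::tail(x$record$max_dev, 1)))
  invisible(x)
}

#' Densify a string path
#'
#' Evaluates the path's fitted curve at `n` equally spaced parameter values;
#' used for distance-to-feature diagnostics and barrier extraction.
#'
#' @param path a `string_path`.
#' @param n number of output points.
#' @return n-by-2 matrix.
#' @export
densify_path <- function(path, n = 400) {
  nodes <- path$nodes
  m <- nrow(nodes)
  seg <- sqrt(rowSums((nodes[-1, , drop = FALSE] - nodes[-m, , drop = FALSE])^2))
  if (all(seg == 0)) return(matrix(nodes[1, ], n, 2, byrow = TRUE))
  sarc <- c(0, cumsum(seg)) / sum(seg)
  curve <- .fit_curve(sarc, nodes, path$fit)
  curve(seq(0, 1, length.out = n))
}
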