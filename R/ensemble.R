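## Ensemble statistics over particle trajectories: axial density profiles
## across a membrane, radial distributions about a reference atom, binding
## site occupancies, center-of-mass distance series, and concentration-
## driven redox-potential profiles.

#' Axial density profile across the membrane normal
#'
#' Histograms the selected species along the membrane-normal axis,
#' normalized per frame and per bin volume, and reports the core/bulk
#' partition ratio (mean density inside `|axis| < core_halfwidth` over mean
#' density outside).
#'
#' @param traj a `particle_trajectory`.
#' @param species species label(s) to select.
#' @param bin_width histogram bin width, Angstrom.
#' @param core_halfwidth half-width of the membrane core region, Angstrom.
#' @return list with `profile` (data.frame: z, density in A^-3) and
#'   `partition_ratio`.
#' @export
axial_density <- function(traj, species, bin_width = 1, core_halfwidth = 10) {
  ax <- .axis_index(traj$axis)
  sel <- .select_species(traj, species)
  L <- traj$box[ax]
  zs <- as.vector(traj$coords[sel, ax, ])
  zs <- zs - L * round(zs / L)                    # wrap into [-L/2, L/2)
  edges <- seq(-L / 2, L / 2, by = bin_width)
  if (edges[length(edges)] < L / 2) edges <- c(edges, L / 2)
  counts <- graphics::hist(zs, breaks = edges, plot = FALSE)$counts
  n_frames <- dim(traj$coords)[3]
  area <- prod(traj$box[-ax])
  dens <- counts / (n_frames * area * diff(edges))
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  core <- abs(mids) < core_halfwidth
  ratio <- mean(dens[core]) / mean(dens[!core])
  list(profile = data.frame(z = mids, density = dens),
       partition_ratio = ratio)
}

#' Radial distribution function about a reference point or atom
#'
#' Shell-volume-normalized g(r) of the selected species about a fixed
#' reference (a coordinate, or an atom index whose per-frame position is
#' used), under the minimum-image convention. An ideal gas gives g(r) ~ 1.
#'
#' @param traj a `particle_trajectory`.
#' @param species species label(s).
#' @param ref length-3 reference point, or a single atom index.
#' @param bin_width shell width, Angstrom.
#' @param r_max maximum radius (default 0.45 of the smallest box edge).
#' @return data.frame with columns r (shell centers) and g.
#' @export
radial_distribution <- function(traj, species, ref, bin_width = 0.5,
                                r_max = NULL) {
  sel <- .select_species(traj, species)
  if (is.null(r_max)) r_max <- 0.45 * min(traj$box)
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  n_frames <- dim(traj$coords)[3]
  counts <- numeric(length(edges) - 1)
  for (f in seq_len(n_frames)) {
    P <- traj$coords[sel, , f, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(P))) P <- matrix(P, ncol = 3)
    rp <- if (length(ref) == 1) traj$coords[ref, , f] else as.numeric(ref)
    d <- .min_image(sweep(P, 2, rp), traj$box)
    r <- sqrt(rowSums(d^2))
    counts <- counts + graphics::hist(r[r < r_max], breaks = edges,
                                      plot = FALSE)$counts
  }
  vol_shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  rho_bulk <- sum(sel) / prod(traj$box)
  g <- counts / (n_frames * vol_shell * rho_bulk)
  data.frame(r = (edges[-1] + edges[-length(edges)]) / 2, g = g)
}

#' Binding-site occupancy report
#'
#' For every site, the fraction of frames with at least one selected
#' particle within the cutoff (`frame_fraction`) and the fraction of all
#' particle-frames within the cutoff (`species_fraction`); both conventions
#' are reported. Sites may include a decoy/control site to gauge random
#' diffusion.
#'
#' @param traj a `particle_trajectory`.
#' @param species species label(s).
#' @param sites named list of length-3 site coordinates (or single atom
#'   indices, resolved per frame).
#' @param cutoffs cutoff radius per site, Angstrom (recycled).
#' @return an `occupancy_report` data.frame: site, cutoff, frame_fraction,
#'   species_fraction.
#' @export
site_occupancy <- function(traj, species, sites, cutoffs) {
  sel <- .select_species(traj, species)
  cutoffs <- rep(as.numeric(cutoffs), length.out = length(sites))
  n_frames <- dim(traj$coords)[3]
  out <- data.frame(site = names(sites), cutoff = cutoffs,
                    frame_fraction = NA_real_, species_fraction = NA_real_)
  for (s in seq_along(sites)) {
    hit_frames <- 0L; hit_pairs <- 0L
    for (f in seq_len(n_frames)) {
      P <- traj$coords[sel, , f, drop = FALSE][, , 1, drop = TRUE]
      if (is.null(dim(P))) P <- matrix(P, ncol = 3)
      sp <- sites[[s]]
      rp <- if (length(sp) == 1) traj$coords[sp, , f] else as.numeric(sp)
      d <- .min_image(sweep(P, 2, rp), traj$box)
      within <- sqrt(rowSums(d^2)) <= cutoffs[s]
      hit_frames <- hit_frames + any(within)
      hit_pairs <- hit_pairs + sum(within)
    }
    out$frame_fraction[s] <- hit_frames / n_frames
    out$species_fraction[s] <- hit_pairs / (n_frames * sum(sel))
  }
  class(out) <- c("occupancy_report", class(out))
  out
}

#' Center-of-mass distance series between two atom groups
#'
#' Mass-weighted centers of mass per frame; the inter-COM distance uses the
#' minimum-image convention. When `threshold` is given, frames are
#' segmented into bound/unbound runs.
#'
#' @param traj a `particle_trajectory`.
#' @param group_a,group_b atom index vectors or species labels.
#' @param masses per-atom masses (default: unit masses).
#' @param threshold optional bound/unbound distance threshold, Angstrom.
#' @return data.frame with frame, distance, and (with threshold) `bound`
#'   plus a `segments` attribute (rle of the bound flag).
#' @export
com_distance_series <- function(traj, group_a, group_b, masses = NULL,
                                threshold = NULL) {
  resolve <- function(g) {
    if (is.character(g)) which(.select_species(traj, g)) else as.integer(g)
  }
  ia <- resolve(group_a); ib <- resolve(group_b)
  if (is.null(masses)) masses <- rep(1, dim(traj$coords)[1])
  n_frames <- dim(traj$coords)[3]
  d <- vapply(seq_len(n_frames), function(f) {
    com <- function(idx) {
      w <- masses[idx] / sum(masses[idx])
      M <- matrix(traj$coords[idx, , f], ncol = 3)
      colSums(M * w)
    }
    dd <- .min_image(matrix(com(ia) - com(ib), 1, 3), traj$box)
    sqrt(sum(dd^2))
  }, numeric(1))
  out <- data.frame(frame = seq_len(n_frames), distance = d)
  if (!is.null(threshold)) {
    out$bound <- d < threshold
    attr(out, "segments") <- rle(out$bound)
  }
  out
}

#' Concentration-driven redox-potential profile along the membrane normal
#'
#' Applies the Nernst concentration correction bin-wise to the ratio of the
#' reduced- and oxidized-species axial densities:
#' `E(z) = Em - slope * log10(rho_red(z)/rho_ox(z))`. Bins lacking either
#' species are flagged NA.
#'
#' @param dens_red,dens_ox axial density profiles (the `profile` data.frame
#'   from [axial_density()], on identical bins).
#' @param Em midpoint potential at equal concentrations, mV.
#' @param slope mV per decade.
#' @return data.frame with z, E (mV) and `flagged` (TRUE where undefined).
#' @export
potential_shift_profile <- function(dens_red, dens_ox, Em, slope = 59) {
  if (!isTRUE(all.equal(dens_red$z, dens_ox$z))) {
    stop("density profiles must share bins")
  }
  ok <- dens_red$density > 0 & dens_ox$density > 0
  E <- rep(NA_real_, nrow(dens_red))
  cp <- function(z) redox_couple("bin", Em, conc_red = z[1], conc_ox = z[2])
  E[ok] <- vapply(which(ok), function(i) {
    nernst_shift(cp(c(dens_red$density[i], dens_ox$density[i])), slope = slope)
  }, numeric(1))
  data.frame(z = dens_red$z, E = E, flagged = !ok)
}
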