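# Trajectory ensemble statistics on seeded fixtures with planted ground
# truths, plus the rigid-motion/permutation invariances.

test_that("axial density recovers flat and planted partition profiles", {
  gas <- make_uniform_gas(n = 8000, box = c(40, 40, 80), seed = 2)
  ad <- axial_density(gas, "GAS")
  expect_equal(ad$partition_ratio, 1, tolerance = 0.1)
  tr <- make_partition_trajectory(n = 10000, ratio = 12, seed = 3)
  ad12 <- axial_density(tr, "O2")
  expect_equal(ad12$partition_ratio, 12, tolerance = 0.1)
  # all particles in one plane occupy a single bin
  one <- particle_trajectory(cbind(runif(50, -5, 5), runif(50, -5, 5), 0.1),
                             rep("X", 50), box = c(20, 20, 20))
  ad1 <- axial_density(one, "X")
  expect_equal(sum(ad1$profile$density > 0), 1)
  expect_error(axial_density(gas, "NOPE"), "empty species")
})

test_that("the radial distribution is unity for an ideal gas and peaks at a planted shell", {
  gas <- make_uniform_gas(n = 6000, box = c(50, 50, 50), seed = 4)
  g <- radial_distribution(gas, "GAS", ref = c(0, 0, 0))
  expect_lt(abs(mean(g$g[g$r > 3]) - 1), 0.05)
  # g(r) integrates to the particle count within 2%
  edges <- c(0, g$r + diff(g$r[1:2]) / 2)
  rho <- 6000 / prod(gas$box)
  n_int <- sum(g$g * rho * 4 / 3 * pi * diff(edges^3))
  n_exp <- 4 / 3 * pi * max(edges)^3 * rho
  expect_equal(n_int, n_exp, tolerance = 0.02)
  sh <- make_shell_trajectory(r0 = 9, seed = 5)
  gs <- radial_distribution(sh, "SOX", ref = c(0, 0, 0), bin_width = 0.5)
  expect_equal(gs$r[which.max(gs$g)], 9, tolerance = 0.5 / 9 + 1e-9)
  # empty shell region has zero g
  lone <- particle_trajectory(matrix(c(20, 0, 0), 1, 3), "X", c(60, 60, 60))
  gl <- radial_distribution(lone, "X", ref = c(0, 0, 0), r_max = 10)
  expect_true(all(gl$g == 0))
})

test_that("site occupancy reports planted dwell fractions for real and decoy sites", {
  dw <- make_dwell_trajectory(n_frames = 1000, dwell = 0.4, seed = 6)
  oc <- site_occupancy(dw, "SOX", list(site = c(0, 0, 0), decoy = c(15, 15, 0)),
                       cutoffs = 5)
  expect_equal(oc$frame_fraction[oc$site == "site"], 0.40, tolerance = 0.02 / 0.4)
  expect_lt(oc$frame_fraction[oc$site == "decoy"], 0.05)
  expect_equal(oc$frame_fraction, oc$species_fraction)  # one particle
  # a particle fixed at a site has occupancy one
  fixed <- particle_trajectory(array(0, c(1, 3, 20)), "X", c(30, 30, 30))
  of <- site_occupancy(fixed, "X", list(s = c(0, 0, 0)), cutoffs = 3)
  expect_equal(of$frame_fraction, 1)
  # a uniform gas fills a cutoff sphere in proportion to its volume
  gas <- make_uniform_gas(n = 20000, box = c(40, 40, 40), n_frames = 3, seed = 7)
  og <- site_occupancy(gas, "GAS", list(s = c(0, 0, 0)), cutoffs = 6)
  expect_equal(og$species_fraction, 4 / 3 * pi * 6^3 / 40^3, tolerance = 0.1)
})

test_that("center-of-mass distances handle coincident, fixed and telegraph groups", {
  two <- particle_trajectory(rbind(c(1, 2, 3), c(1, 2, 3)), c("A", "B"),
                             c(30, 30, 30))
  expect_equal(com_distance_series(two, "A", "B")$distance, 0)
  fx <- particle_trajectory(array(rbind(c(0, 0, 0), c(3, 4, 0)),
                                  c(2, 3, 7)), c("A", "B"), c(40, 40, 40))
  expect_equal(com_distance_series(fx, "A", "B")$distance, rep(5, 7))
  tg <- make_telegraph_trajectory(n_frames = 200, period = 25)
  cs <- com_distance_series(tg, "A", "B", threshold = 12)
  seg <- attr(cs, "segments")
  expect_equal(seg$lengths, rep(25, 8))
  expect_equal(seg$values, rep(c(TRUE, FALSE), 4))
})

test_that("potential-shift profiles apply the Nernst correction bin-wise", {
  prof <- function(d) data.frame(z = seq(-19.5, 19.5, 1), density = d)
  flat <- prof(rep(0.01, 40))
  ps <- potential_shift_profile(flat, flat, Em = -160)
  expect_true(all(abs(ps$E + 160) < 1e-9))
  # 1e4-fold oxidized excess: +236 mV
  ps2 <- potential_shift_profile(prof(rep(1e-6, 40)), prof(rep(1e-2, 40)),
                                 Em = 0)
  expect_true(all(abs(ps2$E - 236) < 1e-9))
  # composition with nernst_shift bin by bin
  red <- prof(10^runif(40, -8, -2)); ox <- prof(10^runif(40, -8, -2))
  ps3 <- potential_shift_profile(red, ox, Em = -160)
  i <- 17
  expect_equal(ps3$E[i],
               nernst_shift(redox_couple("b", -160, red$density[i],
                                         ox$density[i])))
  # missing species flagged
  red$density[5] <- 0
  ps4 <- potential_shift_profile(red, ox, Em = -160)
  expect_true(ps4$flagged[5] && is.na(ps4$E[5]))
})

test_that("statistics are invariant under rigid translation and frame permutation", {
  tr <- make_partition_trajectory(n = 3000, n_frames = 4, seed = 8)
  ref <- axial_density(tr, "O2")
  # translate in the membrane plane (z untouched) and permute frames
  tr2 <- tr
  tr2$coords[, 1, ] <- tr2$coords[, 1, ] + 7
  tr2$coords <- tr2$coords[, , c(3, 1, 4, 2)]
  ad2 <- axial_density(tr2, "O2")
  expect_equal(ad2$profile$density, ref$profile$density)
  gas <- make_uniform_gas(n = 3000, n_frames = 4, seed = 9)
  g1 <- radial_distribution(gas, "GAS", ref = c(1, 2, 3))
  gas2 <- gas
  gas2$coords <- gas2$coords + 5   # rigid shift of everything incl. reference
  g2 <- radial_distribution(gas2, "GAS", ref = c(6, 7, 8))
  expect_equal(g1$g, g2$g)
})

test_that("XYZ round-trips and PDB frames load through the standard reader", {
  gas <- make_uniform_gas(n = 40, n_frames = 3, seed = 10)
  f <- tempfile(fileext = ".xyz")
  write_xyz(gas, f)
  back <- read_xyz(f, gas$box)
  expect_equal(back$coords, gas$coords, tolerance = 1e-5)
  expect_identical(back$species, gas$species)
  # minimal 2-model PDB
  pf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   40.000   40.000   40.000  90.00  90.00  90.00 P 1           1",
    "MODEL        1",
    "ATOM      1  C2D HEM A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  O1  SOX A   2       4.000   5.000   6.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  C2D HEM A   1       1.500   2.000   3.000  1.00  0.00           C",
    "ATOM      2  O1  SOX A   2       4.000   5.500   6.000  1.00  0.00           O",
    "ENDMDL",
    "END"), pf)
  tr <- read_pdb_frames(pf)
  expect_equal(dim(tr$coords), c(2, 3, 2))
  expect_equal(tr$box, c(40, 40, 40))
  expect_equal(tr$coords[1, 1, 2], 1.5)
  expect_identical(tr$species, c("C2D", "O1"))
})
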