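## Electron-transfer rate ruler, transition-state-theory conversions and
## Nernst/thermodynamic arithmetic for redox chains.

#' Define an electron-transfer step
#'
#' @param donor,acceptor cofactor labels.
#' @param R edge-to-edge donor-acceptor distance, Angstrom (>= 3.6, the van
#'   der Waals contact distance).
#' @param lambda reorganization energy, eV (> 0); 0.7 eV is the standard
#'   protein value.
#' @param rho packing density of the intervening medium, dimensionless in
#'   [0, 1]; 0.76 is the standard protein value.
#' @param dG driving force in eV (negative = exergonic).
#' @return an `et_step` object.
#' @export
et_step <- function(donor, acceptor, R, lambda = 0.7, rho = 0.76, dG = 0) {
  if (R < 3.6) stop("edge-to-edge distance below 3.6 Angstrom contact")
  if (lambda <= 0) stop("reorganization energy must be positive")
  if (rho < 0 || rho > 1) stop("packing density must lie in [0, 1]")
  structure(list(donor = donor, acceptor = acceptor, R = R,
                 lambda = lambda, rho = rho, dG = dG), class = "et_step")
}

#' Electron tunneling rate from the empirical distance ruler
#'
#' Computes `log10 k = 13 - (1.2 - 0.8 rho) (R - 3.6) - 3.1 (dG + lambda)^2 / lambda`
#' (R in Angstrom; dG and lambda in eV), the empirical ruler for
#' intraprotein electron tunneling: 10^13 /s at van der Waals contact,
#' a packing-dependent exponential distance decay, and a Marcus activation
#' term that is maximal (activationless) at `dG = -lambda`. The same
#' quadratic form is applied to endergonic steps.
#'
#' @param step an `et_step`, or a distance `R` when the remaining parameters
#'   are given explicitly.
#' @param lambda,rho,dG used when `step` is a bare distance.
#' @return rate constant, s^-1.
#' @examples
#' moser_dutton_rate(et_step("SOX", "heme2", R = 17))   # ~8e2 /s
#' moser_dutton_rate(et_step("heme2", "heme1", R = 11, dG = -0.108))
#' @export
moser_dutton_rate <- function(step, lambda = 0.7, rho = 0.76, dG = 0) {
  if (!inherits(step, "et_step")) {
    step <- et_step("donor", "acceptor", R = step, lambda = lambda,
                    rho = rho, dG = dG)
  }
  log10k <- 13 - (1.2 - 0.8 * step$rho) * (step$R - 3.6) -
    3.1 * (step$dG + step$lambda)^2 / step$lambda
  10^log10k
}

#' Transition-state-theory rate from a free-energy barrier
#'
#' `k = k0 exp(-barrier/kBT)` with the standard prefactor
#' `kB T / h = 6e12 /s` (6 per picosecond); `tst_barrier()` is the exact
#' inverse.
#'
#' @param barrier activation free energy, kcal/mol (>= 0).
#' @param temperature Kelvin.
#' @param prefactor attempt frequency, s^-1.
#' @return rate constant, s^-1.
#' @examples
#' tst_rate(12)            # ~2e4 /s, i.e. a ~48 microsecond timescale
#' tst_barrier(350)        # ~14.5 kcal/mol
#' @export
tst_rate <- function(barrier, temperature = 310, prefactor = .TST_PREFACTOR) {
  if (any(barrier < 0)) stop("barrier must be non-negative")
  prefactor * exp(-barrier / kBT(temperature))
}

#' @param rate rate constant, s^-1 (0 < rate <= prefactor).
#' @rdname tst_rate
#' @return `tst_barrier()`: activation free energy, kcal/mol.
#' @export
tst_barrier <- function(rate, temperature = 310, prefactor = .TST_PREFACTOR) {
  if (any(rate <= 0)) stop("rate must be positive")
  if (any(rate > prefactor)) stop("rate exceeds the attempt frequency")
  kBT(temperature) * log(prefactor / rate)
}

#' Define a redox couple
#'
#' @param name label.
#' @param Em midpoint potential, mV vs NHE.
#' @param conc_red,conc_ox concentrations of the reduced and oxidized
#'   species, mol/L (optional; both needed for [nernst_shift()]).
#' @return a `redox_couple`.
#' @export
redox_couple <- function(name, Em, conc_red = NA_real_, conc_ox = NA_real_) {
  if (!is.na(conc_red) && conc_red <= 0) stop("concentrations must be positive")
  if (!is.na(conc_ox) && conc_ox <= 0) stop("concentrations must be positive")
  structure(list(name = name, Em = Em, conc_red = conc_red,
                 conc_ox = conc_ox), class = "redox_couple")
}

#' Concentration-corrected redox potential
#'
#' `E = Em - slope * log10([red]/[ox])` in mV: depleting the reduced species
#' shifts the effective potential up (a scarce-superoxide couple with
#' `[red]/[ox] = 1e-4` and `Em = -160 mV` comes out near +80 mV). The
#' 59 mV/decade slope is used verbatim; pass
#' `slope = 1000 * kBT_eV(T) * log(10)` for the exact value at another
#' temperature.
#'
#' @param couple a `redox_couple` with both concentrations set.
#' @param slope mV per decade of concentration ratio.
#' @return effective potential, mV vs NHE.
#' @examples
#' sox <- redox_couple("O2/O2.-", -160, conc_red = 1e-10, conc_ox = 1e-6)
#' nernst_shift(sox)   # ~ +76 mV
#' @export
nernst_shift <- function(couple, slope = 59) {
  if (is.na(couple$conc_red) || is.na(couple$conc_ox)) {
    stop("both concentrations must be set")
  }
  couple$Em - slope * log10(couple$conc_red / couple$conc_ox)
}

#' Driving force between two redox couples
#'
#' `dG = -n F (E_acceptor - E_donor)` with the Faraday constant
#' 23.061 kcal/mol/V.
#'
#' @param donor,acceptor `redox_couple` objects (midpoint potentials used as
#'   given; apply [nernst_shift()] first for concentration corrections).
#' @param n_electrons number of electrons transferred.
#' @return list with `dG_kcal` (kcal/mol) and `dG_eV` (eV per electron).
#' @examples
#' driving_force(redox_couple("O2/O2.-", -160), redox_couple("Q/QH2", 90))
#' @export
driving_force <- function(donor, acceptor, n_electrons = 1) {
  dE_V <- (acceptor$Em - donor$Em) / 1000
  list(dG_kcal = -n_electrons * .F_kcal_per_V * dE_V,
       dG_eV = -dE_V)
}

#' Electron-transfer rate table for the superoxide:quinone oxidoreductase
#' chain
#'
#' Builds the three tunneling steps of the two-heme chain with the standard
#' parameters: edge-to-edge distances of 9 (superoxide site to heme 2), 11
#' (heme 2 to heme 1) and 6 Angstrom (heme 1 to quinone), reorganization
#' energy 0.7 eV, packing density 0.76, and driving forces from the
#' midpoint potentials of the effective superoxide couple (0 mV after
#' concentration corrections), the hemes (-8 and +100 mV) and the quinone
#' (+90 mV).
#'
#' @param Em_sox,Em_h2,Em_h1,Em_Q midpoint potentials, mV vs NHE.
#' @param R_sox_h2,R_h2_h1,R_h1_Q edge-to-edge distances, Angstrom.
#' @param lambda,rho ruler parameters.
#' @return data.frame with one row per step: donor, acceptor, R, lambda,
#'   rho, dG_eV, rate (s^-1).
#' @export
soo_rate_table <- function(Em_sox = 0, Em_h2 = -8, Em_h1 = 100, Em_Q = 90,
                           R_sox_h2 = 9, R_h2_h1 = 11, R_h1_Q = 6,
                           lambda = 0.7, rho = 0.76) {
  steps <- list(
    et_step("SOX", "heme2", R_sox_h2, lambda, rho, -(Em_h2 - Em_sox) / 1000),
    et_step("heme2", "heme1", R_h2_h1, lambda, rho, -(Em_h1 - Em_h2) / 1000),
    et_step("heme1", "Q", R_h1_Q, lambda, rho, -(Em_Q - Em_h1) / 1000))
  data.frame(donor = vapply(steps, `[[`, "", "donor"),
             acceptor = vapply(steps, `[[`, "", "acceptor"),
             R = vapply(steps, `[[`, 0, "R"),
             lambda = lambda, rho = rho,
             dG_eV = vapply(steps, `[[`, 0, "dG"),
             rate = vapply(steps, moser_dutton_rate, 0))
}
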