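# Seeded generators with the statistical structure the analysis assumes:
# noisy multi-speed SE radial scans, two-state thermal melts, and
# helix/coil CD spectra. Every generator is a pure function of
# (parameters, seed); Gaussian homoscedastic noise only.

#' Simulate multi-speed sedimentation-equilibrium scans
#'
#' Evaluates the forward model ([radialProfile()]) on a radial grid at each
#' rotor speed and adds i.i.d. Gaussian noise. The same reference
#' concentrations are applied at every speed, so the total loading at the
#' reference radius is identical across channels. Deterministic given
#' `seed`.
#'
#' @param scheme an [associationScheme()].
#' @param refConcs free base-species concentrations at the reference radius,
#'   mol/l (use [totalToFree()] to derive them from a loading
#'   concentration).
#' @param rpms rotor speeds, one scan per speed.
#' @param buffer a [bufferSpec()].
#' @param radiiGrid radial grid, cm (default 6.85-7.15 cm, step 0.001 cm, a
#'   typical 3-mm column).
#' @param referenceRadius cm; default mid-grid.
#' @param pathlength cm.
#' @param baseline constant offset, AU.
#' @param noiseSd Gaussian noise SD, AU (default 0.005).
#' @param seed integer seed.
#' @return Named list of [radialScan()]s (one per rpm).
#' @examples
#' a <- species("A", 17000, 0.726, extinction230(150))
#' sch <- associationScheme("MONOMER_DIMER", list(a), kd = 40e-9)
#' b <- bufferSpec(1.005, 277)
#' scans <- simulateScans(sch, totalToFree(sch, 10e-6),
#'                        rpms = c(20000, 25000), buffer = b, seed = 1)
#' @export
simulateScans <- function(scheme, refConcs, rpms, buffer,
                          radiiGrid = seq(6.85, 7.15, by = 0.001),
                          referenceRadius = NULL, pathlength = 1.2,
                          baseline = 0, noiseSd = 0.005, seed = 1L) {
  stopifnot(is(scheme, "AssociationScheme"), is(buffer, "Buffer"),
            noiseSd >= 0, length(rpms) >= 1)
  if (is.null(referenceRadius))
    referenceRadius <- (min(radiiGrid) + max(radiiGrid)) / 2
  set.seed(as.integer(seed))
  scans <- lapply(seq_along(rpms), function(i) {
    sc <- radialScan(rpm = rpms[i], temperature = buffer@temperature,
                     radii = radiiGrid, absorbance = rep(0, length(radiiGrid)),
                     referenceRadius = referenceRadius,
                     channelId = paste0("rpm", rpms[i]))
    a <- radialProfile(scheme, refConcs, sc, buffer, pathlength, baseline)
    if (noiseSd > 0) a <- a + stats::rnorm(length(a), 0, noiseSd)
    sc@absorbance <- a
    sc
  })
  names(scans) <- paste0("rpm", rpms)
  scans
}

#' Simulate a two-state thermal melt
#'
#' Van't Hoff two-state unfolding: the equilibrium constant is
#' \eqn{K(T) = \exp[\Delta H / R\, (1/T_m - 1/T)]} (temperatures in K,
#' \eqn{\Delta C_p = 0}), the folded fraction \eqn{f = 1/(1+K)} equals 1/2
#' at Tm, and the observed signal mixes linear folded and unfolded
#' baselines: \eqn{y(T) = f\,(b_{f0} + b_{f1} T) + (1-f)(b_{u0} + b_{u1} T)}
#' plus Gaussian noise.
#'
#' @param tm melting temperature, degrees C.
#' @param deltaH van't Hoff enthalpy, kcal/mol (> 0; larger = sharper).
#' @param temperatures grid, degrees C, ascending.
#' @param foldedBaseline,unfoldedBaseline `c(intercept, slope)` of each
#'   baseline (signal units, units/degC).
#' @param noiseSd Gaussian noise SD (same units as the signal).
#' @param seed integer seed.
#' @param units signal units flag for the returned [meltCurve()].
#' @return A `MeltCurve`.
#' @export
simulateMelt <- function(tm, deltaH, temperatures = seq(0, 80, by = 1),
                         foldedBaseline = c(-30, 0),
                         unfoldedBaseline = c(-2, 0),
                         noiseSd = 0, seed = 1L, units = "mre") {
  stopifnot(deltaH > 0, noiseSd >= 0)
  f <- foldedFraction(temperatures, tm, deltaH)
  y <- f * (foldedBaseline[1] + foldedBaseline[2] * temperatures) +
    (1 - f) * (unfoldedBaseline[1] + unfoldedBaseline[2] * temperatures)
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(y), 0, noiseSd)
  }
  meltCurve(temperatures, y, units = units)
}

#' Two-state folded fraction
#'
#' @param temperatures degrees C.
#' @param tm degrees C.
#' @param deltaH kcal/mol.
#' @return Folded fraction in (0, 1); exactly 0.5 at `tm`.
#' @export
foldedFraction <- function(temperatures, tm, deltaH) {
  tK <- temperatures + 273.15
  tmK <- tm + 273.15
  dH <- deltaH * 1000          # cal/mol
  K <- exp(dH / 1.98720 * (1 / tmK - 1 / tK))
  1 / (1 + K)
}

# Basis shapes for the spectrum generator. The helix basis has the double
# minimum at 208/222 nm and a positive band near 193 nm, normalized so its
# value at 222 nm is exactly 1; the coil basis is a small positive shoulder
# near 218 nm that is close to zero at 222 nm. These are documented
# fixtures with the right qualitative geometry, not measured basis spectra.
.helixBasis <- function(lambda) {
  g <- function(mu, s) exp(-(lambda - mu)^2 / (2 * s^2))
  g0 <- function(mu, s, at) exp(-(at - mu)^2 / (2 * s^2))
  raw <- g(222, 6) + g(208, 6) - 1.8 * g(193, 5)
  norm <- g0(222, 6, 222) + g0(208, 6, 222) - 1.8 * g0(193, 5, 222)
  raw / norm
}

.coilBasis <- function(lambda) {
  350 * exp(-(lambda - 218)^2 / (2 * 2^2))
}

#' Simulate a CD spectrum as a helix/coil mixture
#'
#' Builds a mean-residue-ellipticity spectrum as a linear mixture of a
#' parameterized helix basis (double minimum at 208/222 nm whose 222-nm
#' depth equals [theoreticalHelixMRE()] for the chain length) and a coil
#' basis, then converts back to observed ellipticity through the MRE
#' formula and adds Gaussian noise in degrees.
#'
#' @param fracHelix helical fraction in \[0, 1\].
#' @param n chain length, residues (> 4).
#' @param wavelengths nm grid (default 190-260).
#' @param pathlength cm (default 0.1, molar-ellipticity cuvette).
#' @param concentration mg/ml (default 0.1).
#' @param mrw Da/residue (default 110).
#' @param noiseSd Gaussian noise SD on the observed ellipticity, degrees.
#' @param seed integer seed.
#' @return A [cdSpectrum()]; at zero noise its 222-nm MRE equals
#'   `fracHelix * theoreticalHelixMRE(n) + (1 - fracHelix) * coil(222)`.
#' @export
simulateCDSpectrum <- function(fracHelix, n, wavelengths = 190:260,
                               pathlength = 0.1, concentration = 0.1,
                               mrw = 110, noiseSd = 0, seed = 1L) {
  if (fracHelix < 0 || fracHelix > 1) stop("'fracHelix' must be in [0, 1]")
  mre <- fracHelix * theoreticalHelixMRE(n) * .helixBasis(wavelengths) +
    (1 - fracHelix) * .coilBasis(wavelengths)
  thetaObs <- mre * 10 * pathlength * concentration / mrw
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    thetaObs <- thetaObs + stats::rnorm(length(thetaObs), 0, noiseSd)
  }
  cdSpectrum(wavelengths, thetaObs, pathlength, concentration, mrw, n)
}

#' Helicity analysis of a measured or simulated spectrum
#'
#' Interpolates the mean residue ellipticity at 222 nm and converts it to a
#' helical fraction with [percentHelicity()] using the chain length stored
#' in the spectrum.
#'
#' @param spectrum a [cdSpectrum()].
#' @return List with `mre222` (deg cm^2 dmol^-1) and `fracHelix`.
#' @export
helicityFromSpectrum <- function(spectrum) {
  stopifnot(is(spectrum, "CDSpectrum"))
  mre <- spectrumMRE(spectrum)
  m222 <- stats::approx(spectrum@wavelengths, mre, xout = 222)$y
  if (is.na(m222)) stop("spectrum does not cover 222 nm")
  list(mre222 = m222, fracHelix = percentHelicity(m222, spectrum@nResidues))
}
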