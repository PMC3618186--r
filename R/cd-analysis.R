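# Circular dichroism reductions: mean residue ellipticity, the
# length-corrected theoretical helix signal, percent helicity, helical
# residue counts, and Tm extraction from thermal melts.

#' Mean residue ellipticity
#'
#' \eqn{[\theta] = \theta_{obs} \times MRW / (10\, l\, c)} where
#' \eqn{\theta_{obs}} is the observed ellipticity in degrees, MRW the mean
#' residue weight (Da/residue), l the pathlength in cm and c the
#' concentration in mg/ml.
#'
#' @param thetaObs observed ellipticity, degrees (vectorized).
#' @param mrw mean residue weight, Da per residue.
#' @param pathlength cm, > 0.
#' @param concentration mg/ml, > 0.
#' @return MRE in deg cm^2 dmol^-1. Stored at full scale; print in units of
#'   10^3 to match the conventional "-20.5" style.
#' @examples
#' meanResidueEllipticity(-0.050, 110, 0.1, 0.1)  # -55
#' @export
meanResidueEllipticity <- function(thetaObs, mrw, pathlength, concentration) {
  if (!is.finite(pathlength) || pathlength <= 0)
    stop("'pathlength' must be > 0")
  if (!is.finite(concentration) || concentration <= 0)
    stop("'concentration' must be > 0")
  if (!is.finite(mrw) || mrw <= 0) stop("'mrw' must be > 0")
  thetaObs * mrw / (10 * pathlength * concentration)
}

#' Theoretical 222-nm MRE of a fully helical chain
#'
#' Length-corrected helix signal \eqn{[\theta]_{222} = -40\times10^3 (1 -
#' 4.6/n)} for a chain of n residues; full helix is negative at 222 nm and
#' the magnitude approaches 40x10^3 for long chains.
#'
#' @param n number of residues, > 4 (the formula is non-positive below).
#' @return MRE at 222 nm, deg cm^2 dmol^-1 (negative).
#' @examples
#' theoreticalHelixMRE(327) / 1e3   # -39.4
#' theoreticalHelixMRE(145) / 1e3   # -38.7
#' @export
theoreticalHelixMRE <- function(n) {
  if (any(!is.finite(n)) || any(n <= 4))
    stop("'n' must be > 4")
  -40e3 * (1 - 4.6 / n)
}

#' Fractional helicity from a measured 222-nm MRE
#'
#' Ratio of the experimental 222-nm mean residue ellipticity to the
#' theoretical fully helical value for the same chain length. Values are
#' clipped to \[0, 1.05\]; a ratio above 1 (possible with noise or
#' concentration error) triggers a warning.
#'
#' @param mre222Exp experimental MRE at 222 nm, deg cm^2 dmol^-1 (sign
#'   ignored; helix is negative).
#' @param n number of residues, > 4.
#' @return Helical fraction in \[0, 1.05\]. Multiply by 100 and round for
#'   the conventional integer-percent report.
#' @examples
#' round(100 * percentHelicity(-20.5e3, 327))  # 52
#' @export
percentHelicity <- function(mre222Exp, n) {
  frac <- abs(mre222Exp) / abs(theoreticalHelixMRE(n))
  if (any(frac > 1))
    warning("helicity ratio exceeds 1 (", paste(round(frac[frac > 1], 3),
            collapse = ", "), "); clipped to 1.05")
  pmin(pmax(frac, 0), 1.05)
}

#' Helical residue count
#'
#' Number of residues in helical conformation implied by a helical fraction,
#' rounded half-to-even.
#'
#' @param frac helical fraction in \[0, 1\].
#' @param n chain length, residues.
#' @return Integer residue count.
#' @examples
#' helicalResidueCount(0.21, 45)  # 9
#' @export
helicalResidueCount <- function(frac, n) {
  if (any(frac < 0 | frac > 1)) stop("'frac' must lie in [0, 1]")
  as.integer(round(frac * n))
}

#' Melting temperature from the first derivative of a melt curve
#'
#' Smooths the 222-nm melt with a Savitzky-Golay local polynomial (order 2,
#' window `smoothWindow` points), takes the central-difference first
#' derivative with respect to temperature, and reports Tm at the extremum of
#' the absolute derivative. A transition is only called when that extremum
#' exceeds 3x the median absolute derivative (`detectFactor`); a strictly
#' linear trace therefore reports no transition, the behaviour expected of
#' an unfolded chain.
#'
#' @param curve a [meltCurve()].
#' @param smoothWindow smoothing window, points (odd; default 5).
#' @param detectFactor transition-detection threshold as a multiple of the
#'   median absolute derivative (default 3).
#' @return A `MeltResult`; see [meltingTemperature()] and
#'   [transitionDetected()].
#' @examples
#' tc <- seq(0, 80, by = 1)
#' mc <- simulateMelt(tm = 38, deltaH = 40, temperatures = tc, noiseSd = 0)
#' meltingTemperature(meltTm(mc))
#' @export
meltTm <- function(curve, smoothWindow = 5L, detectFactor = 3) {
  stopifnot(is(curve, "MeltCurve"))
  smoothWindow <- as.integer(smoothWindow)
  if (smoothWindow %% 2L == 0L) smoothWindow <- smoothWindow + 1L
  tt <- curve@temperatures
  y <- curve@theta222
  n <- length(y)
  if (n < smoothWindow + 2L)
    stop("melt curve has too few points (", n, ") for smoothing window ",
         smoothWindow)
  ys <- signal::sgolayfilt(y, p = 2, n = smoothWindow)
  # central differences on the actual temperature grid; drop the endpoints,
  # which carry one-sided filter artifacts
  idx <- 2:(n - 1L)
  d <- (ys[idx + 1L] - ys[idx - 1L]) / (tt[idx + 1L] - tt[idx - 1L])
  tmid <- tt[idx]
  imax <- which.max(abs(d))
  extremum <- abs(d[imax])
  detected <- extremum >= detectFactor * stats::median(abs(d))
  new("MeltResult",
      tm = if (detected) tmid[imax] else NA_real_,
      transitionDetected = detected,
      derivativeExtremum = extremum)
}
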