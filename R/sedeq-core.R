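# Forward physics of sedimentation equilibrium. Shared by the simulator and
# the fitter. Unit system is cgs: cm, g, s, erg; concentrations in mol/l,
# masses in g/mol, rotor speed in rpm (converted internally).

.R_GAS <- 8.314e7  # erg mol^-1 K^-1

#' Reduced sedimentation-equilibrium exponent
#'
#' \eqn{\sigma = M (1 - \bar v \rho)\, \omega^2 / (R T)} in cm^-2, with
#' \eqn{\omega = rpm \cdot 2\pi/60}, R = 8.314e7 erg/(mol K), M in g/mol and
#' radii in cm. At equilibrium an ideal species distributes as
#' \eqn{c(r) = c(r_0) \exp[\sigma (r^2 - r_0^2)/2]}.
#'
#' @param mass molar mass, Da (g/mol).
#' @param vbar partial specific volume, ml/g.
#' @param buffer a [bufferSpec()] supplying density (g/ml) and T (K).
#' @param rpm rotor speed, revolutions per minute.
#' @return sigma in cm^-2 (0 at neutral buoyancy or zero speed).
#' @examples
#' b <- bufferSpec(1.000, 277)
#' reducedExponent(13880, 0.731, b, 25000)  # ~1.1 cm^-2
#' @export
reducedExponent <- function(mass, vbar, buffer, rpm) {
  stopifnot(is(buffer, "Buffer"))
  omega <- rpm * 2 * pi / 60
  mass * (1 - vbar * buffer@density) * omega^2 /
    (.R_GAS * buffer@temperature)
}

# Expand a scheme into the full species table (base species + complex):
# mass, vbar (mass-weighted for the complex), epsilon (sum), and the
# stoichiometry of base species in each row. Buoyant-mass additivity
# sigma_complex = sum(stoich * sigma_base) follows from the mass-weighted
# vbar and makes mass action hold at every radius, not just r0.
.speciesTable <- function(scheme) {
  sp <- scheme@speciesList
  base <- data.frame(
    name = vapply(sp, function(s) s@name, character(1)),
    mass = vapply(sp, function(s) s@monomerMass, numeric(1)),
    vbar = vapply(sp, function(s) s@vbar, numeric(1)),
    epsilon = vapply(sp, function(s) s@epsilon, numeric(1)),
    stringsAsFactors = FALSE)
  kind <- scheme@kind
  if (kind == "SINGLE") {
    base$stoich1 <- 1; base$stoich2 <- 0
    return(base)
  }
  if (kind == "MONOMER_DIMER") {
    cx <- data.frame(name = paste0(base$name[1], ".dimer"),
                     mass = 2 * base$mass[1], vbar = base$vbar[1],
                     epsilon = 2 * base$epsilon[1])
    out <- rbind(cbind(base, stoich1 = 1, stoich2 = 0),
                 cbind(cx, stoich1 = 2, stoich2 = 0))
    return(out)
  }
  # HETERO_2_2: participants are A (monomer, row 1) and B2 (preformed
  # homodimer, row 2); the complex is B2A2.
  mC <- base$mass[2] + 2 * base$mass[1]
  vC <- (base$mass[2] * base$vbar[2] + 2 * base$mass[1] * base$vbar[1]) / mC
  cx <- data.frame(name = paste0(base$name[2], ".", base$name[1], "2"),
                   mass = mC, vbar = vC,
                   epsilon = base$epsilon[2] + 2 * base$epsilon[1])
  rbind(cbind(base, stoich1 = c(1, 0), stoich2 = c(0, 1)),
        cbind(cx, stoich1 = 2, stoich2 = 1))
}

# Complex concentration at the reference radius from mass action on the
# free base-species concentrations there.
.complexConc <- function(scheme, free) {
  switch(scheme@kind,
    SINGLE = numeric(0),
    MONOMER_DIMER = free[1]^2 / scheme@kd,
    HETERO_2_2 = free[1]^2 * free[2] / scheme@kd)
}

#' Free concentrations from total loading concentrations
#'
#' Inverts mass action at the reference radius: given the total
#' concentration of each base species (in monomer-equivalent mol/l for the
#' self-associating monomer, particle mol/l for a preformed dimer), returns
#' the free concentrations consistent with the scheme's Kd. For
#' `MONOMER_DIMER` this solves \eqn{c_A + 2 c_A^2/K_d = T_A}; for
#' `HETERO_2_2` it solves the coupled pair
#' \eqn{c_A + 2 c_A^2 c_{B_2}/K_d = T_A},
#' \eqn{c_{B_2}(1 + c_A^2/K_d) = T_{B_2}}.
#'
#' @param scheme an [associationScheme()] with a finite Kd.
#' @param totals numeric vector of totals at the reference radius, one per
#'   base species, mol/l.
#' @return Free base-species concentrations, mol/l.
#' @examples
#' a <- species("A", 17000, 0.726)
#' sch <- associationScheme("MONOMER_DIMER", list(a), kd = 40e-9)
#' totalToFree(sch, 10e-6)
#' @export
totalToFree <- function(scheme, totals) {
  stopifnot(is(scheme, "AssociationScheme"))
  if (any(totals < 0)) stop("totals must be >= 0")
  switch(scheme@kind,
    SINGLE = totals,
    MONOMER_DIMER = {
      kd <- scheme@kd
      tA <- totals[1]
      if (tA == 0) 0 else kd * (sqrt(1 + 8 * tA / kd) - 1) / 4
    },
    HETERO_2_2 = {
      kd <- scheme@kd
      tA <- totals[1]; tB <- totals[2]
      if (tA == 0) return(c(0, tB))
      consumed <- function(a) {
        b <- tB / (1 + a^2 / kd)
        a + 2 * a^2 * b / kd - tA
      }
      a <- stats::uniroot(consumed, c(0, tA), tol = 1e-18 * max(tA, 1e-12),
                          maxiter = 2000L)$root
      b <- tB / (1 + a^2 / kd)
      c(a, b)
    })
}

#' Model radial absorbance profile
#'
#' Evaluates the ideal sedimentation-equilibrium forward model for an
#' association scheme. Each species i follows
#' \eqn{c_i(r) = c_i(r_0)\exp[\sigma_i (r^2 - r_0^2)/2]}; the complex
#' concentration at r0 comes from mass action on the free concentrations
#' (\eqn{c_{A_2} = c_A^2/K_d}, \eqn{c_{B_2A_2} = c_A^2 c_{B_2}/K_d}); the
#' complex partial specific volume is the mass-weighted mean of its
#' components, so \eqn{\sigma} is additive and chemical equilibrium holds at
#' every radius. The signal is
#' \eqn{A(r) = \sum_i \epsilon_i\, l\, c_i(r) + baseline}.
#'
#' @param scheme an [associationScheme()].
#' @param refConcs free concentration of each base species at the reference
#'   radius, mol/l (length 1, or 2 for `HETERO_2_2`).
#' @param scan a [radialScan()] providing rpm, radii and reference radius
#'   (its absorbance slot is ignored).
#' @param buffer a [bufferSpec()].
#' @param pathlength optical pathlength, cm (default 1.2, the standard
#'   centerpiece).
#' @param baseline radially constant offset, AU (default 0).
#' @return Absorbance (AU) at each radius of `scan`.
#' @export
radialProfile <- function(scheme, refConcs, scan, buffer, pathlength = 1.2,
                          baseline = 0) {
  stopifnot(is(scheme, "AssociationScheme"), is(scan, "RadialScan"),
            is(buffer, "Buffer"))
  nbase <- length(scheme@speciesList)
  if (length(refConcs) != nbase)
    stop("'refConcs' must supply one free concentration per base species")
  if (any(refConcs < 0)) stop("'refConcs' must be >= 0")
  tab <- .speciesTable(scheme)
  conc0 <- c(refConcs, .complexConc(scheme, refConcs))
  sigma <- reducedExponent(tab$mass, tab$vbar, buffer, scan@rpm)
  dr2 <- (scan@radii^2 - scan@referenceRadius^2) / 2
  sig <- rep(baseline, length(scan@radii))
  for (i in seq_len(nrow(tab)))
    sig <- sig + tab$epsilon[i] * pathlength * conc0[i] * exp(sigma[i] * dr2)
  sig
}
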