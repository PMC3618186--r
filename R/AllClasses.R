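# S4 containers for the sedimentation-equilibrium / CD analysis chain.
# Validity methods enforce the physical invariants each object must satisfy;
# user code goes through the constructors and accessors, never @ slots.

.msg <- function(...) paste0(...)

setClass("Species",
  representation(
    name = "character",
    monomerMass = "numeric",
    vbar = "numeric",
    epsilon = "numeric"
  )
)

setValidity("Species", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "'name' must be a single non-empty string")
  if (length(object@monomerMass) != 1L || !is.finite(object@monomerMass) ||
      object@monomerMass <= 0)
    msgs <- c(msgs, "'monomerMass' must be a single positive number (Da)")
  if (length(object@vbar) != 1L || !is.finite(object@vbar) ||
      object@vbar <= 0.5 || object@vbar >= 0.9)
    msgs <- c(msgs, "'vbar' must lie in (0.5, 0.9) ml/g")
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon < 0)
    msgs <- c(msgs, "'epsilon' must be >= 0 (AU per mol/l per cm)")
  if (length(msgs)) msgs else TRUE
})

#' Protein species for sedimentation-equilibrium modeling
#'
#' A sedimenting species is described by its molar mass, partial specific
#' volume and molar extinction coefficient at the detection wavelength.
#' Complexes (dimers, 2:2 heterotetramers) are derived internally from their
#' components: the complex mass is the stoichiometric sum, its partial
#' specific volume the mass-weighted mean, and its extinction the sum --
#' which makes buoyant masses exactly additive.
#'
#' @param name single string identifying the species.
#' @param monomerMass molar mass of one chain, Da.
#' @param vbar partial specific volume, ml/g; must lie in (0.5, 0.9).
#' @param epsilon molar extinction coefficient, AU per (mol/l) per cm, at the
#'   detection wavelength. See [extinction230()] for the 230-nm per-residue
#'   rule.
#' @return A `Species` object.
#' @examples
#' cc1b <- species("CC1B", monomerMass = 17000, vbar = 0.726,
#'                 epsilon = extinction230(150))
#' @export
species <- function(name, monomerMass, vbar, epsilon = 0) {
  new("Species", name = as.character(name),
      monomerMass = as.numeric(monomerMass),
      vbar = as.numeric(vbar), epsilon = as.numeric(epsilon))
}

setClass("Buffer",
  representation(
    density = "numeric",
    temperature = "numeric",
    nacl = "numeric",
    pH = "numeric"
  )
)

setValidity("Buffer", function(object) {
  msgs <- character()
  if (!is.finite(object@density) || object@density <= 0.9 ||
      object@density >= 1.2)
    msgs <- c(msgs, "'density' must lie in (0.9, 1.2) g/ml")
  if (!is.finite(object@temperature) || object@temperature <= 273 ||
      object@temperature >= 320)
    msgs <- c(msgs, "'temperature' must lie in (273, 320) K")
  if (length(msgs)) msgs else TRUE
})

#' Buffer / solvent description
#'
#' @param density solvent density, g/ml.
#' @param temperature absolute temperature, K.
#' @param nacl sodium chloride concentration, mol/l (descriptive metadata).
#' @param pH buffer pH (descriptive metadata).
#' @return A `Buffer` object.
#' @examples
#' pbs <- bufferSpec(density = 1.005, temperature = 277)
#' @export
bufferSpec <- function(density, temperature, nacl = NA_real_, pH = NA_real_) {
  new("Buffer", density = as.numeric(density),
      temperature = as.numeric(temperature),
      nacl = as.numeric(nacl), pH = as.numeric(pH))
}

setClass("RadialScan",
  representation(
    rpm = "numeric",
    temperature = "numeric",
    radii = "numeric",
    absorbance = "numeric",
    referenceRadius = "numeric",
    channelId = "character"
  )
)

setValidity("RadialScan", function(object) {
  msgs <- character()
  r <- object@radii
  if (length(r) < 2L || any(!is.finite(r)))
    msgs <- c(msgs, "'radii' must hold at least two finite values")
  else if (any(diff(r) <= 0))
    msgs <- c(msgs, .msg("'radii' must be strictly increasing (first ",
                         "violation at row ", which(diff(r) <= 0)[1L] + 1L, ")"))
  if (length(object@absorbance) != length(r))
    msgs <- c(msgs, "'absorbance' and 'radii' lengths differ")
  if (any(!is.finite(object@absorbance)))
    msgs <- c(msgs, "'absorbance' must be finite")
  if (!is.finite(object@referenceRadius) ||
      object@referenceRadius < min(r) || object@referenceRadius > max(r))
    msgs <- c(msgs, "'referenceRadius' must lie within the radial range")
  if (!is.finite(object@rpm) || object@rpm < 0)
    msgs <- c(msgs, "'rpm' must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' One equilibrium radial absorbance scan
#'
#' A single channel of a sedimentation-equilibrium experiment: absorbance
#' versus radius at one rotor speed and temperature, together with the
#' reference radius at which species concentrations are parameterized.
#'
#' @param rpm rotor speed, revolutions per minute.
#' @param temperature temperature of the run, K.
#' @param radii radial positions, cm, strictly increasing.
#' @param absorbance absorbance at each radius, AU.
#' @param referenceRadius reference radius r0, cm; defaults to mid-range.
#' @param channelId label for the cell/channel.
#' @return A `RadialScan` object.
#' @export
radialScan <- function(rpm, temperature, radii, absorbance,
                       referenceRadius = NULL, channelId = "channel1") {
  radii <- as.numeric(radii)
  if (is.null(referenceRadius))
    referenceRadius <- (min(radii) + max(radii)) / 2
  new("RadialScan", rpm = as.numeric(rpm), temperature = as.numeric(temperature),
      radii = radii, absorbance = as.numeric(absorbance),
      referenceRadius = as.numeric(referenceRadius),
      channelId = as.character(channelId))
}

.SCHEME_KINDS <- c("SINGLE", "MONOMER_DIMER", "HETERO_2_2")

setClass("AssociationScheme",
  representation(
    kind = "character",
    speciesList = "list",
    kd = "numeric"
  )
)

setValidity("AssociationScheme", function(object) {
  msgs <- character()
  if (!(object@kind %in% .SCHEME_KINDS))
    msgs <- c(msgs, paste0("'kind' must be one of ",
                           paste(.SCHEME_KINDS, collapse = ", ")))
  nsp <- length(object@speciesList)
  if (!all(vapply(object@speciesList, is, logical(1), "Species")))
    msgs <- c(msgs, "all participants must be Species objects")
  need <- switch(object@kind, SINGLE = 1L, MONOMER_DIMER = 1L,
                 HETERO_2_2 = 2L, NA_integer_)
  if (!is.na(need) && nsp != need)
    msgs <- c(msgs, .msg("scheme kind ", object@kind, " needs exactly ",
                         need, " base species, got ", nsp))
  if (object@kind != "SINGLE" &&
      (!is.finite(object@kd) || object@kd <= 0))
    msgs <- c(msgs, "'kd' must be a positive finite number")
  if (length(msgs)) msgs else TRUE
})

#' Declarative association scheme
#'
#' Describes which species sediment and how they are chemically coupled:
#' a single ideal species, a monomer-dimer self-association
#' \eqn{2A \rightleftharpoons A_2} with \eqn{K_d = [A]^2/[A_2]} (mol/l), or a
#' 2:2 "dimer of dimers" hetero-association
#' \eqn{B_2 + 2A \rightleftharpoons B_2A_2} with
#' \eqn{K_d = [A]^2[B_2]/[B_2A_2]} (mol^2/l^2, because the two A chains are
#' treated as independent monomers).
#'
#' @param kind one of `"SINGLE"`, `"MONOMER_DIMER"`, `"HETERO_2_2"`.
#' @param speciesList list of [species()] objects: the single species, the
#'   monomer A, or `list(A, B2)` where B2 is the preformed homodimer.
#' @param kd dissociation constant in the units above; ignored for `SINGLE`.
#' @return An `AssociationScheme` object.
#' @examples
#' a <- species("IC", 13880, 0.731, extinction230(124))
#' b2 <- species("CC1dimer", 2 * 36000, 0.721, 2 * extinction230(327))
#' sch <- associationScheme("HETERO_2_2", list(a, b2), kd = 1e-12)
#' @export
associationScheme <- function(kind = c("SINGLE", "MONOMER_DIMER", "HETERO_2_2"),
                              speciesList, kd = NA_real_) {
  kind <- match.arg(kind)
  if (is(speciesList, "Species")) speciesList <- list(speciesList)
  new("AssociationScheme", kind = kind, speciesList = speciesList,
      kd = as.numeric(kd))
}

setClass("CDSpectrum",
  representation(
    wavelengths = "numeric",
    thetaObs = "numeric",
    pathlength = "numeric",
    concentration = "numeric",
    mrw = "numeric",
    nResidues = "numeric"
  )
)

setValidity("CDSpectrum", function(object) {
  msgs <- character()
  w <- object@wavelengths
  if (length(w) < 2L || any(diff(w) <= 0))
    msgs <- c(msgs, "'wavelengths' must be strictly increasing")
  if (length(object@thetaObs) != length(w))
    msgs <- c(msgs, "'thetaObs' and 'wavelengths' lengths differ")
  for (s in c("pathlength", "concentration", "mrw", "nResidues"))
    if (!is.finite(slot(object, s)) || slot(object, s) <= 0)
      msgs <- c(msgs, .msg("'", s, "' must be > 0"))
  if (length(msgs)) msgs else TRUE
})

#' Circular dichroism spectrum with optical metadata
#'
#' @param wavelengths nm, strictly increasing.
#' @param thetaObs observed ellipticity at each wavelength, degrees.
#' @param pathlength cuvette pathlength, cm.
#' @param concentration protein concentration, mg/ml.
#' @param mrw mean residue weight, Da per residue (molar mass / residues).
#' @param nResidues number of residues in the chain.
#' @return A `CDSpectrum` object.
#' @export
cdSpectrum <- function(wavelengths, thetaObs, pathlength, concentration,
                       mrw, nResidues) {
  new("CDSpectrum", wavelengths = as.numeric(wavelengths),
      thetaObs = as.numeric(thetaObs), pathlength = as.numeric(pathlength),
      concentration = as.numeric(concentration), mrw = as.numeric(mrw),
      nResidues = as.numeric(nResidues))
}

setClass("MeltCurve",
  representation(
    temperatures = "numeric",
    theta222 = "numeric",
    units = "character"
  )
)

setValidity("MeltCurve", function(object) {
  msgs <- character()
  tt <- object@temperatures
  if (length(tt) < 5L)
    msgs <- c(msgs, "a melt curve needs at least 5 points")
  else if (any(diff(tt) <= 0))
    msgs <- c(msgs, "'temperatures' must be strictly increasing")
  if (length(object@theta222) != length(tt))
    msgs <- c(msgs, "'theta222' and 'temperatures' lengths differ")
  if (!(object@units %in% c("deg", "mre")))
    msgs <- c(msgs, "'units' must be \"deg\" or \"mre\"")
  if (length(msgs)) msgs else TRUE
})

#' Thermal denaturation curve monitored at 222 nm
#'
#' @param temperatures degrees C, strictly increasing, at least 5 points.
#' @param theta222 ellipticity at 222 nm at each temperature.
#' @param units `"deg"` for raw observed ellipticity or `"mre"` for mean
#'   residue ellipticity.
#' @return A `MeltCurve` object.
#' @export
meltCurve <- function(temperatures, theta222, units = c("deg", "mre")) {
  units <- match.arg(units)
  new("MeltCurve", temperatures = as.numeric(temperatures),
      theta222 = as.numeric(theta222), units = units)
}

setClass("MeltResult",
  representation(
    tm = "numeric",
    transitionDetected = "logical",
    derivativeExtremum = "numeric"
  )
)

setValidity("MeltResult", function(object) {
  if (isTRUE(object@transitionDetected) && !is.finite(object@tm))
    "a detected transition must carry a finite tm" else TRUE
})

setClass("SEFit",
  representation(
    params = "data.frame",       # name, value, status ("fixed"/"floated")
    chiSquare = "numeric",
    reducedChiSquare = "numeric",
    residuals = "list",          # per-channel residual vectors, AU
    converged = "logical",
    nStarts = "integer",
    seed = "integer",
    scheme = "AssociationScheme",
    nPoints = "integer"
  )
)

setValidity("SEFit", function(object) {
  msgs <- character()
  if (!all(c("name", "value", "status") %in% names(object@params)))
    msgs <- c(msgs, "'params' needs columns name, value, status")
  if (!is.finite(object@chiSquare) || object@chiSquare < 0)
    msgs <- c(msgs, "'chiSquare' must be >= 0")
  if (length(msgs)) msgs else TRUE
})

setClass("KdProfile",
  representation(
    kdGrid = "numeric",
    chiSquare = "numeric",
    bestKd = "numeric",
    bestChiSquare = "numeric",
    lower = "numeric",
    upper = "numeric",
    threshold = "numeric"
  )
)

setValidity("KdProfile", function(object) {
  msgs <- character()
  if (length(object@kdGrid) != length(object@chiSquare))
    msgs <- c(msgs, "'kdGrid' and 'chiSquare' lengths differ")
  if (any(diff(object@kdGrid) <= 0))
    msgs <- c(msgs, "'kdGrid' must be strictly increasing")
  if (is.finite(object@lower) && is.finite(object@upper) &&
      !(object@lower <= object@bestKd && object@bestKd <= object@upper))
    msgs <- c(msgs, "bounds must bracket the best-fit kd")
  if (length(msgs)) msgs else TRUE
})

setClass("ConditionSeries",
  representation(
    conditionName = "character",
    summary = "data.frame",      # condition, metric, converged
    fits = "list",
    mode = "character"
  )
)

setValidity("ConditionSeries", function(object) {
  msgs <- character()
  if (!all(c("condition", "metric", "converged") %in% names(object@summary)))
    msgs <- c(msgs, "'summary' needs columns condition, metric, converged")
  if (any(diff(object@summary$condition) <= 0))
    msgs <- c(msgs, "conditions must be strictly ordered")
  if (length(msgs)) msgs else TRUE
})
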