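#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for sedeq objects
#'
#' Small, read-only accessors for the S4 containers: radial data, scheme
#' metadata, fit statistics and melt results. Slot access (`@`) is not part
#' of the package interface.
#'
#' @param x a sedeq S4 object.
#' @return The slot value (numeric, character, logical or data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("radii", "RadialScan", function(x) x@radii)

#' @rdname accessors
#' @export
setMethod("absorbance", "RadialScan", function(x) x@absorbance)

#' @rdname accessors
#' @export
setMethod("rotorSpeed", "RadialScan", function(x) x@rpm)

#' @rdname accessors
#' @export
setMethod("referenceRadius", "RadialScan", function(x) x@referenceRadius)

#' @rdname accessors
#' @export
setMethod("channelId", "RadialScan", function(x) x@channelId)

#' @rdname accessors
#' @export
setMethod("schemeKind", "AssociationScheme", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("kdValue", "AssociationScheme", function(x) x@kd)

#' @rdname accessors
#' @export
setMethod("kdValue", "SEFit", function(x) {
  p <- x@params
  if (!"log10kd" %in% p$name) return(NA_real_)
  10^p$value[p$name == "log10kd"]
})

#' @rdname accessors
#' @export
setMethod("chiSquare", "SEFit", function(x) x@chiSquare)

#' @rdname accessors
#' @export
setMethod("reducedChiSquare", "SEFit", function(x) x@reducedChiSquare)

#' @rdname accessors
#' @export
setMethod("fittedParams", "SEFit", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("residualsList", "SEFit", function(x) x@residuals)

#' @rdname accessors
#' @export
setMethod("isConverged", "SEFit", function(x) x@converged)

#' @rdname accessors
#' @export
setMethod("chiSquare", "KdProfile", function(x) x@chiSquare)

#' @rdname accessors
#' @export
setMethod("kdValue", "KdProfile", function(x) x@bestKd)

#' @rdname accessors
#' @export
setMethod("meltingTemperature", "MeltResult", function(x) x@tm)

#' @rdname accessors
#' @export
setMethod("transitionDetected", "MeltResult", function(x) x@transitionDetected)

#' @rdname accessors
#' @export
setMethod("wavelengths", "CDSpectrum", function(x) x@wavelengths)

#' Mean residue ellipticity of a measured spectrum
#'
#' Applies the standard normalization
#' \eqn{[\theta] = \theta_{obs} \times MRW / (10\, l\, c)} to every point of
#' a [cdSpectrum()], using the optical metadata stored with it.
#'
#' @param x a `CDSpectrum`.
#' @return Numeric vector of MRE values, deg cm^2 dmol^-1, parallel to
#'   `wavelengths(x)`.
#' @export
setMethod("spectrumMRE", "CDSpectrum", function(x) {
  meanResidueEllipticity(x@thetaObs, x@mrw, x@pathlength, x@concentration)
})

setMethod("show", "Species", function(object) {
  cat("Species \"", object@name, "\": ", format(object@monomerMass),
      " Da, vbar ", format(object@vbar), " ml/g, epsilon ",
      format(object@epsilon), " AU/(M cm)\n", sep = "")
})

setMethod("show", "RadialScan", function(object) {
  cat("RadialScan [", object@channelId, "]: ", length(object@radii),
      " points, ", format(object@rpm), " rpm, ",
      format(object@temperature), " K, r = ",
      format(min(object@radii)), "-", format(max(object@radii)),
      " cm (r0 = ", format(object@referenceRadius), ")\n", sep = "")
})

setMethod("show", "AssociationScheme", function(object) {
  cat("AssociationScheme ", object@kind, "\n", sep = "")
  for (sp in object@speciesList)
    cat("  ", sp@name, ": ", format(sp@monomerMass), " Da\n", sep = "")
  if (object@kind == "MONOMER_DIMER")
    cat("  Kd = ", format(object@kd), " M\n", sep = "")
  if (object@kind == "HETERO_2_2")
    cat("  Kd = ", format(object@kd), " M^2\n", sep = "")
})

setMethod("show", "CDSpectrum", function(object) {
  cat("CDSpectrum: ", length(object@wavelengths), " points, ",
      format(min(object@wavelengths)), "-", format(max(object@wavelengths)),
      " nm; l = ", format(object@pathlength), " cm, c = ",
      format(object@concentration), " mg/ml, n = ",
      format(object@nResidues), "\n", sep = "")
})

setMethod("show", "MeltCurve", function(object) {
  cat("MeltCurve: ", length(object@temperatures), " points, ",
      format(min(object@temperatures)), "-",
      format(max(object@temperatures)), " C [", object@units, "]\n",
      sep = "")
})

setMethod("show", "MeltResult", function(object) {
  if (object@transitionDetected)
    cat("MeltResult: Tm = ", format(object@tm), " C (transition detected)\n",
        sep = "")
  else
    cat("MeltResult: no transition detected\n")
})

setMethod("show", "SEFit", function(object) {
  cat("SEFit (", object@scheme@kind, "): chi^2 = ",
      format(object@chiSquare), ", reduced chi^2 = ",
      format(object@reducedChiSquare), ", converged = ",
      object@converged, "\n", sep = "")
  p <- object@params
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-24s %14.6g  [%s]\n", p$name[i], p$value[i], p$status[i]))
})

setMethod("show", "KdProfile", function(object) {
  cat("KdProfile: ", length(object@kdGrid), " grid points, best Kd = ",
      format(object@bestKd), ", chi^2_min = ",
      format(object@bestChiSquare), "\n", sep = "")
  cat("  bounds at chi^2_min + ", format(object@threshold), ": [",
      ifelse(is.finite(object@lower), format(object@lower), "-"), ", ",
      ifelse(is.finite(object@upper), format(object@upper), "-"), "]\n",
      sep = "")
})

setMethod("show", "ConditionSeries", function(object) {
  cat("ConditionSeries over ", object@conditionName, " (mode ",
      object@mode, "):\n", sep = "")
  print(object@summary, row.names = FALSE)
})

#' Summary table of a condition series
#'
#' @param object a `ConditionSeries`.
#' @param ... ignored.
#' @return data.frame with columns `condition`, `metric` (apparent mass in Da
#'   or -log10 Kd) and `converged`.
#' @export
setMethod("summary", "ConditionSeries", function(object, ...) object@summary)
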