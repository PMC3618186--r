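#' @include AllClasses.R
NULL

#' @export
setGeneric("radii", function(x) standardGeneric("radii"))

#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @export
setGeneric("rotorSpeed", function(x) standardGeneric("rotorSpeed"))

#' @export
setGeneric("referenceRadius", function(x) standardGeneric("referenceRadius"))

#' @export
setGeneric("channelId", function(x) standardGeneric("channelId"))

#' @export
setGeneric("schemeKind", function(x) standardGeneric("schemeKind"))

#' @export
setGeneric("kdValue", function(x) standardGeneric("kdValue"))

#' @export
setGeneric("chiSquare", function(x) standardGeneric("chiSquare"))

#' @export
setGeneric("reducedChiSquare", function(x) standardGeneric("reducedChiSquare"))

#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))

#' @export
setGeneric("residualsList", function(x) standardGeneric("residualsList"))

#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @export
setGeneric("meltingTemperature", function(x) standardGeneric("meltingTemperature"))

#' @export
setGeneric("transitionDetected", function(x) standardGeneric("transitionDetected"))

#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @export
setGeneric("spectrumMRE", function(x) standardGeneric("spectrumMRE"))
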