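# Readers/writers and run configuration. Open text dialects only: FASTA for
# sequences, CSV with unit-bearing column names for scans, YAML for run
# configuration, JSON for fit reports.

#' Read protein sequences from FASTA
#'
#' Standard single- or multi-record FASTA via \pkg{Biostrings}. Sequences
#' are uppercase-normalized (with a message when lowercase input was
#' found); empty records are rejected.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences, in file order.
#' @export
readFasta <- function(path) {
  raw <- readLines(path)
  sq <- raw[!startsWith(raw, ">")]
  if (any(grepl("[a-z]", sq)))
    message("lowercase residues uppercased in ", path)
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  if (!length(seqs)) stop("no records in ", path)
  if (any(!nzchar(seqs)))
    stop("empty record(s) in ", path, ": ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  seqs
}

#' Read a radial scan from CSV
#'
#' Expects a header row with columns `radius_cm` and `absorbance`
#' (additional columns are ignored); radii must be strictly increasing and
#' violations are reported with the offending row number.
#'
#' @param path CSV file.
#' @param rpm,temperature,referenceRadius,channelId scan metadata (see
#'   [radialScan()]).
#' @return A `RadialScan`.
#' @export
readScanCSV <- function(path, rpm, temperature, referenceRadius = NULL,
                        channelId = "channel1") {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("radius_cm", "absorbance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  bad <- which(diff(df$radius_cm) <= 0)
  if (length(bad))
    stop("radii not strictly increasing in ", path, " at row ",
         bad[1L] + 1L, " (radius_cm = ", df$radius_cm[bad[1L] + 1L], ")")
  radialScan(rpm = rpm, temperature = temperature, radii = df$radius_cm,
             absorbance = df$absorbance, referenceRadius = referenceRadius,
             channelId = channelId)
}

#' Write a radial scan to CSV
#'
#' @param scan a [radialScan()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScanCSV <- function(scan, path) {
  stopifnot(is(scan, "RadialScan"))
  utils::write.csv(data.frame(radius_cm = scan@radii,
                              absorbance = scan@absorbance),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON fit report
#'
#' Serializes an `SEFit` (and optionally a `KdProfile`) to a stable JSON
#' schema: every parameter with its fix/float status and at-bound flag,
#' chi-square statistics, multi-start seed and software version. Profile
#' bounds are written in both linear and -log10 form. Reports of a seeded
#' fit are byte-identical across reruns.
#'
#' @param fit an `SEFit`.
#' @param path output JSON file.
#' @param profile optional `KdProfile` to embed.
#' @return `path`, invisibly.
#' @export
writeReport <- function(fit, path, profile = NULL) {
  stopifnot(is(fit, "SEFit"))
  rep <- list(
    software = list(package = "sedeq",
                    version = as.character(utils::packageVersion("sedeq"))),
    scheme = fit@scheme@kind,
    n_points = fit@nPoints,
    chi_square = fit@chiSquare,
    reduced_chi_square = fit@reducedChiSquare,
    converged = fit@converged,
    n_starts = fit@nStarts,
    seed = fit@seed,
    parameters = fit@params)
  if (!is.null(profile)) {
    stopifnot(is(profile, "KdProfile"))
    rep$kd_profile <- list(
      kd_grid = profile@kdGrid,
      chi_square = profile@chiSquare,
      best_kd = profile@bestKd,
      threshold = profile@threshold,
      bounds = list(
        lower = profile@lower, upper = profile@upper,
        neg_log10_lower = -log10(profile@lower),
        neg_log10_upper = -log10(profile@upper)))
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

.CONFIG_KEYS <- c("pka_set", "buffer", "species", "fit", "output_dir")
.BUFFER_KEYS <- c("density_g_ml", "temperature_K", "nacl_M", "pH")
.SPECIES_KEYS <- c("name", "mass_da", "vbar", "epsilon", "n_residues")

#' Read and validate a run configuration
#'
#' YAML configuration with a fixed schema: `pka_set`, a `buffer` block
#' (`density_g_ml`, `temperature_K`, optional `nacl_M`, `pH`), a `species`
#' table (`name`, `mass_da`, `vbar`, optional `epsilon` or `n_residues`
#' from which the 230-nm extinction is derived), an optional free-form
#' `fit` block and `output_dir`. Unknown keys anywhere are rejected before
#' any computation.
#'
#' @param path YAML file.
#' @return List with elements `pka_set`, `buffer` (a [bufferSpec()]),
#'   `species` (named list of [species()]), `fit`, `output_dir`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$buffer)) stop("configuration needs a 'buffer' block")
  bu <- setdiff(names(cfg$buffer), .BUFFER_KEYS)
  if (length(bu))
    stop("unknown buffer key(s): ", paste(bu, collapse = ", "))
  buf <- bufferSpec(density = cfg$buffer$density_g_ml,
                    temperature = cfg$buffer$temperature_K,
                    nacl = cfg$buffer$nacl_M %||% NA_real_,
                    pH = cfg$buffer$pH %||% NA_real_)
  spl <- list()
  for (s in cfg$species) {
    su <- setdiff(names(s), .SPECIES_KEYS)
    if (length(su))
      stop("unknown species key(s): ", paste(su, collapse = ", "))
    eps <- s$epsilon %||%
      (if (!is.null(s$n_residues)) extinction230(s$n_residues) else 0)
    spl[[s$name]] <- species(s$name, s$mass_da, s$vbar, eps)
  }
  pka <- cfg$pka_set %||% "emboss"
  pkaSet(pka)  # validates the name
  list(pka_set = pka, buffer = buf, species = spl,
       fit = cfg$fit %||% list(), output_dir = cfg$output_dir %||% ".")
}

#' Reference table of coiled-coil construct properties
#'
#' Partial specific volumes (SEDNTERP-derived, ml/g), theoretical monomer
#' masses where established (Da) and residue counts for the dynein
#' intermediate-chain and dynactin p150 coiled-coil fragments analyzed by
#' this package's workflow. Extinction coefficients follow the 230-nm
#' per-residue rule ([extinction230()]).
#'
#' @return data.frame with columns `name`, `vbar`, `mass_da` (NA where not
#'   established), `n_residues`, `epsilon230`.
#' @examples
#' referenceSpeciesTable()
#' @export
referenceSpeciesTable <- function() {
  df <- data.frame(
    name = c("CC1", "CC1A", "CC1B", "IC1-44", "IC1-124"),
    vbar = c(0.721, 0.727, 0.726, 0.736, 0.731),
    mass_da = c(NA, NA, NA, 5470, 13880),
    n_residues = c(327, 145, 149, 44, 124))
  df$epsilon230 <- extinction230(df$n_residues)
  df
}
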