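# Sequence-derived physical properties: Henderson-Hasselbalch charge, pI
# (whole-chain and windowed), average mass, 230-nm extinction, helix
# geometry and heptad counting.

.AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V")

# IUPAC average residue masses (Da); free chain mass adds one water.
.RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

.WATER_MASS <- 18.0153

.PKA_SETS <- list(
  # EMBOSS iep defaults
  emboss = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  # Lehninger textbook values
  lehninger = c(Nterm = 9.69, Cterm = 2.34, C = 8.33, D = 3.86, E = 4.25,
                H = 6.0, K = 10.53, R = 12.48, Y = 10.07)
)

#' Ionizable-group pKa sets
#'
#' Returns the pKa values used by [netCharge()] and [isoelectricPoint()]:
#' the free alpha-amino and alpha-carboxyl termini and the side chains of
#' D, E, C, Y, H, K and R. The EMBOSS set is the default scale; computed pI
#' values shift by a few tenths of a pH unit between scales, which is why
#' literature pI figures are only comparable given the same scale.
#'
#' @param name `"emboss"` (default) or `"lehninger"`.
#' @return Named numeric vector with elements `Nterm`, `Cterm`, `C`, `D`,
#'   `E`, `H`, `K`, `R`, `Y` (pH units, all in (0, 14)).
#' @examples
#' pkaSet()["K"]
#' @export
pkaSet <- function(name = c("emboss", "lehninger")) {
  name <- match.arg(name)
  set <- .PKA_SETS[[name]]
  stopifnot(all(set > 0 & set < 14))
  set
}

# Validate and explode a sequence into residue letters.
.residues <- function(seq) {
  if (is(seq, "AAString") || is(seq, "AAStringSet")) seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence must be a single non-empty character string")
  res <- strsplit(toupper(seq), "")[[1L]]
  bad <- setdiff(unique(res), .AA_CODES)
  if (length(bad))
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "),
         " (only the 20 standard one-letter codes are accepted)")
  res
}

#' Net charge of a polypeptide at a given pH
#'
#' Henderson-Hasselbalch sum over the two termini and all ionizable side
#' chains. Basic groups (N-terminus, K, R, H) contribute
#' \eqn{+1/(1+10^{pH-pKa})}; acidic groups (C-terminus, D, E, C, Y)
#' contribute \eqn{-1/(1+10^{pKa-pH})}. The result is strictly decreasing
#' in pH.
#'
#' @param seq one-letter amino-acid string (or `AAString`).
#' @param pH numeric vector of pH values.
#' @param pkas a pKa set, see [pkaSet()].
#' @return Net charge in elementary-charge units, one value per `pH`.
#' @examples
#' netCharge("DDKKH", 7.0)
#' @export
netCharge <- function(seq, pH, pkas = pkaSet()) {
  res <- .residues(seq)
  counts <- table(factor(res, levels = .AA_CODES))
  basic <- c(Nterm = 1, K = unname(counts[["K"]]), R = unname(counts[["R"]]),
             H = unname(counts[["H"]]))
  acidic <- c(Cterm = 1, D = unname(counts[["D"]]), E = unname(counts[["E"]]),
              C = unname(counts[["C"]]), Y = unname(counts[["Y"]]))
  vapply(pH, function(p) {
    pos <- sum(basic / (1 + 10^(p - pkas[names(basic)])))
    neg <- sum(acidic / (1 + 10^(pkas[names(acidic)] - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' pH at which [netCharge()] crosses zero, located by bisection on
#' \[0, 14\] to a tolerance of 1e-4 pH units. Because both termini are
#' always ionizable the charge is positive at pH 0 and negative at pH 14,
#' so a crossing always exists.
#'
#' @inheritParams netCharge
#' @param tol bisection tolerance, pH units.
#' @return pI in pH units.
#' @examples
#' isoelectricPoint("GGGGG")  # (pKa_Nterm + pKa_Cterm)/2
#' @export
isoelectricPoint <- function(seq, pkas = pkaSet(), tol = 1e-4) {
  lo <- 0; hi <- 14
  clo <- netCharge(seq, lo, pkas)
  chi <- netCharge(seq, hi, pkas)
  if (clo <= 0 || chi >= 0)
    stop("net charge does not change sign on [0, 14]")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (netCharge(seq, mid, pkas) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Windowed isoelectric-point profile
#'
#' Scans the sequence with a sliding window (default 28 residues advanced in
#' steps of 7) and reports the pI of every complete window; a trailing
#' partial window is dropped so all values are comparable. Window start
#' positions are 1-based inclusive.
#'
#' @inheritParams netCharge
#' @param window window length, residues.
#' @param step step between window starts, residues.
#' @return data.frame with columns `window_start`, `window_end`, `pI`.
#' @examples
#' windowedPI(strrep("K", 40), window = 28, step = 7)
#' @export
windowedPI <- function(seq, window = 28L, step = 7L, pkas = pkaSet()) {
  res <- .residues(seq)
  n <- length(res)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L) stop("'window' and 'step' must be >= 1")
  if (window > n)
    stop("window (", window, ") exceeds sequence length (", n, ")")
  starts <- seq.int(1L, n - window + 1L, by = step)
  pi <- vapply(starts, function(s)
    isoelectricPoint(paste(res[s:(s + window - 1L)], collapse = ""), pkas),
    numeric(1))
  data.frame(window_start = starts, window_end = starts + window - 1L,
             pI = pi)
}

#' Average molecular mass of a polypeptide
#'
#' Sum of IUPAC average residue masses plus one water (18.02 Da).
#'
#' @inheritParams netCharge
#' @return Mass in Da.
#' @examples
#' averageMass("G")  # free glycine, 75.07 Da
#' @export
averageMass <- function(seq) {
  res <- .residues(seq)
  sum(.RESIDUE_MASS[res]) + .WATER_MASS
}

#' 230-nm extinction coefficient from residue count
#'
#' Applies the per-residue rule of 900 absorbance units per residue used for
#' quantifying coiled-coil fragments at 230 nm (per mol/l, per cm path).
#'
#' @param nResidues number of residues, >= 1.
#' @return Extinction coefficient, AU per (mol/l) per cm.
#' @examples
#' extinction230(45)   # 40,500
#' @export
extinction230 <- function(nResidues) {
  if (any(!is.finite(nResidues)) || any(nResidues < 1))
    stop("'nResidues' must be >= 1")
  900 * nResidues
}

#' End-to-end length of a partially helical chain
#'
#' An alpha helix rises 1.5 Angstrom per residue, so a chain of `n` residues
#' with helical fraction `fracHelix` spans `n * fracHelix * rise` Angstrom
#' end to end when its helical content is contiguous.
#'
#' @param nResidues chain length, residues.
#' @param fracHelix helical fraction in \[0, 1\].
#' @param rise helix rise per residue, Angstrom (default 1.5).
#' @return Length in Angstrom.
#' @examples
#' helixEndToEnd(149, 0.30)  # ~67 Angstrom
#' @export
helixEndToEnd <- function(nResidues, fracHelix, rise = 1.5) {
  if (any(fracHelix < 0 | fracHelix > 1))
    stop("'fracHelix' must lie in [0, 1]")
  nResidues * fracHelix * rise
}

#' Count complete heptad repeats in a residue range
#'
#' Coiled-coil sequences repeat with a seven-residue (abcdefg) period; the
#' number of potential heptads in an inclusive 1-based residue range is
#' `floor(length / 7)`.
#'
#' @param start,end 1-based inclusive residue indices, `start <= end`.
#' @return Integer heptad count.
#' @examples
#' heptadCount(415, 530)  # 16
#' @export
heptadCount <- function(start, end) {
  if (any(start > end)) stop("'start' must be <= 'end'")
  as.integer((end - start + 1) %/% 7)
}
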