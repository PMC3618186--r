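# Global nonlinear fitting of radial scans: fix/float parameter scheme,
# bounded Levenberg-Marquardt least squares with multi-start, chi-square
# Kd profiling and condition-series summaries.
#
# Parameterization: masses in linear space (bounds [0.2, 5] x initial),
# reference concentrations and Kd in log10 space, one baseline per channel.
# The objective is unweighted sum of squared residuals in AU.

#' Fit specification: which parameters float
#'
#' Declares the fix/float status of every model parameter for
#' [fitGlobal()]: monomer masses, per-channel reference concentrations, the
#' dissociation constant and per-channel baselines. The conventional
#' molecular-weight determination fixes vbar, density and extinction, floats
#' the concentration and the mass; the association fit fixes mass and
#' concentration and floats the association constant.
#'
#' @param scheme an [associationScheme()]; its species masses and `kd` are
#'   the fixed values / initial values of those parameters.
#' @param floatMass float the base-species masses?
#' @param floatConc float per-channel free reference concentrations (log10
#'   space)?
#' @param floatKd float log10(Kd)? Only allowed for associating schemes.
#' @param floatBaseline float one radially constant offset per channel?
#' @param concValues fixed concentrations when `floatConc = FALSE`: a vector
#'   (one per base species, recycled over channels) or a channels x species
#'   matrix, in mol/l.
#' @param concAs how fixed concentrations are interpreted: `"free"` (free
#'   base-species concentration at the reference radius) or `"total"` (total
#'   loading concentration at the reference radius; free concentrations are
#'   then recomputed from mass action at the current Kd on every evaluation,
#'   which is what makes "concentration held constant while Kd floats"
#'   self-consistent).
#' @param init optional named list of initial values overriding the scheme:
#'   `mass` (vector), `kd`, `conc` (channels x species matrix of free
#'   concentrations), `baseline` (vector).
#' @param kdBounds length-2 numeric, bounds for Kd (linear scale); default
#'   spans 6 decades either side of the initial value.
#' @param nStarts number of multi-start initializations (default 5); start 1
#'   is the supplied initial value, the rest perturb it (Kd log-uniform over
#'   its bounds).
#' @return An object of class `"seFitSpec"` consumed by [fitGlobal()],
#'   [profileKd()] and [conditionSeries()].
#' @export
seFitSpec <- function(scheme, floatMass = FALSE, floatConc = TRUE,
                      floatKd = FALSE, floatBaseline = FALSE,
                      concValues = NULL, concAs = c("free", "total"),
                      init = list(), kdBounds = NULL, nStarts = 5L) {
  stopifnot(is(scheme, "AssociationScheme"))
  concAs <- match.arg(concAs)
  if (floatKd && scheme@kind == "SINGLE")
    stop("Kd can only float for an associating scheme")
  if (!floatMass && !floatConc && !floatKd && !floatBaseline)
    stop("at least one parameter must float")
  if (!floatConc && is.null(concValues))
    stop("fixed concentrations require 'concValues'")
  if (scheme@kind != "SINGLE" && !is.finite(scheme@kd))
    stop("associating scheme needs a finite kd as fixed/initial value")
  structure(list(scheme = scheme, floatMass = floatMass,
                 floatConc = floatConc, floatKd = floatKd,
                 floatBaseline = floatBaseline, concValues = concValues,
                 concAs = concAs, init = init, kdBounds = kdBounds,
                 nStarts = as.integer(nStarts)),
            class = "seFitSpec")
}

.schemeWith <- function(scheme, masses, kd) {
  sl <- scheme@speciesList
  for (i in seq_along(sl)) sl[[i]]@monomerMass <- masses[i]
  new("AssociationScheme", kind = scheme@kind, speciesList = sl, kd = kd)
}

.concMatrix <- function(values, nch, nbase) {
  if (is.null(values)) return(NULL)
  m <- if (is.matrix(values)) values else
    matrix(values, nrow = nch, ncol = nbase, byrow = TRUE)
  if (nrow(m) != nch || ncol(m) != nbase)
    stop("concentration values must be one per base species, ",
         "or a channels x species matrix")
  m
}

# Interpolated absorbance at the reference radius, for data-driven
# concentration initialization.
.refAbs <- function(scan) {
  stats::approx(scan@radii, scan@absorbance, xout = scan@referenceRadius,
                rule = 2)$y
}

#' Global least-squares fit of sedimentation-equilibrium scans
#'
#' Minimizes the unweighted sum of squared absorbance residuals jointly over
#' all scans: masses and Kd are shared across channels, concentrations and
#' baselines are per-channel. Optimization is bounded Levenberg-Marquardt
#' (via \pkg{minpack.lm}) with `nStarts` seeded multi-start initializations;
#' the best run is kept and the whole procedure is deterministic given
#' `seed`.
#'
#' @param scans a list of [radialScan()] objects (>= 1).
#' @param spec an [seFitSpec()].
#' @param buffer a [bufferSpec()].
#' @param seed integer seed controlling the multi-start perturbations.
#' @param pathlength optical pathlength, cm.
#' @return An `SEFit` object: parameter table with fix/float status and
#'   at-bound flags, chi-square (sum of squared residuals, AU^2), reduced
#'   chi-square (chi-square / (N - n_floated)), per-channel residuals and a
#'   convergence flag. See [fittedParams()], [chiSquare()], [kdValue()].
#' @export
fitGlobal <- function(scans, spec, buffer, seed = 1L, pathlength = 1.2) {
  stopifnot(inherits(spec, "seFitSpec"), is(buffer, "Buffer"))
  if (is(scans, "RadialScan")) scans <- list(scans)
  if (!length(scans) || !all(vapply(scans, is, logical(1), "RadialScan")))
    stop("'scans' must be a non-empty list of RadialScan objects")
  scheme <- spec$scheme
  nbase <- length(scheme@speciesList)
  nch <- length(scans)
  chIds <- vapply(seq_along(scans), function(i) {
    id <- scans[[i]]@channelId
    if (nzchar(id)) paste0(id, ".", i) else paste0("ch", i)
  }, character(1))

  masses0 <- spec$init$mass %||%
    vapply(scheme@speciesList, function(s) s@monomerMass, numeric(1))
  kd0 <- spec$init$kd %||% scheme@kd
  baselines0 <- rep_len(spec$init$baseline %||% 0, nch)

  # identifiability: with no field (or neutral buoyancy) every profile is
  # flat and mass/Kd carry no signal gradient
  sigma0 <- unlist(lapply(scans, function(sc)
    reducedExponent(masses0,
                    vapply(scheme@speciesList, function(s) s@vbar, numeric(1)),
                    buffer, sc@rpm)))
  if (all(abs(sigma0) < 1e-12))
    stop("non-identifiable fit: all reduced exponents are zero ",
         "(zero rotor speed or neutral buoyancy)")

  concFixed <- .concMatrix(spec$concValues, nch, nbase)
  epsb <- vapply(scheme@speciesList, function(s) s@epsilon, numeric(1))

  conc0 <- spec$init$conc
  if (is.null(conc0)) {
    if (!spec$floatConc && spec$concAs == "free") {
      conc0 <- concFixed
    } else {
      cc <- vapply(scans, function(sc) {
        a0 <- max(.refAbs(sc) - baselines0[1], 1e-6)
        tot <- a0 / (pathlength * pmax(epsb, 1)) / nbase
        sch <- .schemeWith(scheme, masses0, kd0)
        pmax(totalToFree(sch, tot), 1e-15)
      }, numeric(nbase))
      conc0 <- if (nbase == 1L) matrix(cc, ncol = 1L) else t(cc)
    }
  }
  conc0 <- .concMatrix(conc0, nch, nbase)

  kdBounds <- spec$kdBounds %||%
    (if (scheme@kind == "SINGLE") NULL else c(kd0 * 1e-6, kd0 * 1e6))

  # --- parameter packing -------------------------------------------------
  parNames <- character(0); par0 <- numeric(0)
  lower <- numeric(0); upper <- numeric(0)
  spNames <- vapply(scheme@speciesList, function(s) s@name, character(1))
  if (spec$floatMass) {
    parNames <- c(parNames, paste0("mass.", spNames))
    par0 <- c(par0, masses0)
    lower <- c(lower, 0.2 * masses0); upper <- c(upper, 5 * masses0)
  }
  if (spec$floatConc) {
    for (j in seq_len(nbase)) {
      parNames <- c(parNames, paste0("logconc.", chIds, ".", spNames[j]))
      lc <- log10(pmax(conc0[, j], 1e-15))
      par0 <- c(par0, lc)
      lower <- c(lower, lc - 4); upper <- c(upper, lc + 4)
    }
  }
  if (spec$floatKd) {
    parNames <- c(parNames, "log10kd")
    par0 <- c(par0, log10(kd0))
    lower <- c(lower, log10(kdBounds[1])); upper <- c(upper, log10(kdBounds[2]))
  }
  if (spec$floatBaseline) {
    parNames <- c(parNames, paste0("baseline.", chIds))
    amax <- max(abs(unlist(lapply(scans, absorbance))), 1)
    par0 <- c(par0, baselines0)
    lower <- c(lower, rep(-amax, nch)); upper <- c(upper, rep(amax, nch))
  }
  nfloat <- length(par0)

  unpack <- function(p) {
    i <- 0L
    masses <- masses0; conc <- conc0; kd <- kd0; basel <- baselines0
    if (spec$floatMass) { masses <- p[i + seq_len(nbase)]; i <- i + nbase }
    if (spec$floatConc) {
      conc <- matrix(10^p[i + seq_len(nch * nbase)], nrow = nch)
      i <- i + nch * nbase
    }
    if (spec$floatKd) { kd <- 10^p[i + 1L]; i <- i + 1L }
    if (spec$floatBaseline) basel <- p[i + seq_len(nch)]
    list(masses = masses, conc = conc, kd = kd, baselines = basel)
  }

  residFun <- function(p) {
    st <- unpack(p)
    sch <- .schemeWith(scheme, st$masses, st$kd)
    unlist(lapply(seq_len(nch), function(ch) {
      free <- if (spec$floatConc || spec$concAs == "free") st$conc[ch, ]
              else totalToFree(sch, concFixed[ch, ])
      radialProfile(sch, free, scans[[ch]], buffer, pathlength,
                    st$baselines[ch]) - scans[[ch]]@absorbance
    }))
  }

  npts <- sum(vapply(scans, function(s) length(s@radii), integer(1)))

  if (nfloat == 0L) {
    r <- residFun(numeric(0))
    ss <- sum(r^2)
    best <- list(par = numeric(0), ssr = ss, converged = TRUE)
  } else {
    ctrl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                       ptol = 1e-15, gtol = 0)
    best <- NULL
    for (s in seq_len(spec$nStarts)) {
      ps <- par0
      if (s > 1L) {
        set.seed(as.integer(seed) + s - 1L)
        jit <- stats::runif(nfloat, -1, 1)
        ps <- par0 + jit * pmin(upper - par0, par0 - lower) * 0.5
        # Kd restarts are log-uniform over the full bounded range
        ik <- which(parNames == "log10kd")
        if (length(ik))
          ps[ik] <- stats::runif(1, lower[ik], upper[ik])
        ps <- pmin(pmax(ps, lower), upper)
      }
      fit <- tryCatch(
        minpack.lm::nls.lm(par = ps, lower = lower, upper = upper,
                           fn = residFun, control = ctrl),
        error = function(e) NULL)
      if (is.null(fit)) next
      ssr <- fit$deviance
      if (is.null(best) || ssr < best$ssr)
        best <- list(par = fit$par, ssr = ssr,
                     converged = fit$info %in% 1:4)
    }
    if (is.null(best))
      stop("all multi-start optimizations failed")
  }

  st <- unpack(best$par)
  schBest <- .schemeWith(scheme, st$masses, st$kd)
  residVecs <- vector("list", nch); names(residVecs) <- chIds
  off <- 0L
  rAll <- residFun(best$par)
  for (ch in seq_len(nch)) {
    nn <- length(scans[[ch]]@radii)
    residVecs[[ch]] <- rAll[off + seq_len(nn)]
    off <- off + nn
  }

  # --- full parameter report (fixed + floated) ---------------------------
  fb <- vapply(seq_len(nch), function(ch) {
    if (spec$floatConc || spec$concAs == "free") st$conc[ch, ]
    else totalToFree(schBest, concFixed[ch, ])
  }, numeric(nbase))
  freeBest <- if (nbase == 1L) matrix(fb, ncol = 1L) else t(fb)
  rows <- list()
  add <- function(name, value, status, atB = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, value = value,
                                             status = status,
                                             atBound = atB)
  stat <- function(f) if (f) "floated" else "fixed"
  for (j in seq_len(nbase))
    add(paste0("mass.", spNames[j]), st$masses[j], stat(spec$floatMass))
  for (ch in seq_len(nch)) for (j in seq_len(nbase)) {
    if (!spec$floatConc && spec$concAs == "total")
      add(paste0("totalconc.", chIds[ch], ".", spNames[j]),
          concFixed[ch, j], "fixed")
    add(paste0("conc.", chIds[ch], ".", spNames[j]), freeBest[ch, j],
        if (spec$floatConc) "floated" else "fixed")
  }
  if (scheme@kind != "SINGLE") {
    atB <- FALSE
    if (spec$floatKd) {
      lk <- log10(st$kd)
      atB <- min(abs(lk - log10(kdBounds))) < 1e-3
    }
    add("log10kd", log10(st$kd), stat(spec$floatKd), atB)
  }
  for (ch in seq_len(nch))
    add(paste0("baseline.", chIds[ch]), st$baselines[ch],
        stat(spec$floatBaseline))
  params <- do.call(rbind, rows)

  redchi <- if (npts > nfloat) best$ssr / (npts - nfloat) else NA_real_
  new("SEFit", params = params, chiSquare = best$ssr,
      reducedChiSquare = redchi, residuals = residVecs,
      converged = isTRUE(best$converged), nStarts = spec$nStarts,
      seed = as.integer(seed), scheme = schBest, nPoints = npts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fitted mass of the (first) base species
#'
#' @param fit an `SEFit`.
#' @param species name of the species; default the first mass parameter.
#' @return Mass in Da.
#' @export
fittedMass <- function(fit, species = NULL) {
  p <- fit@params
  rows <- grep("^mass\\.", p$name)
  if (!length(rows)) return(NA_real_)
  if (!is.null(species)) {
    rows <- which(p$name == paste0("mass.", species))
    if (!length(rows)) stop("no mass parameter for species '", species, "'")
  }
  p$value[rows[1L]]
}

#' Single-species molecular-weight determination
#'
#' Convenience wrapper implementing the conventional scheme: single ideal
#' species, vbar / density / extinction fixed, per-channel concentration
#' floated, molecular weight floated.
#'
#' @param scans list of [radialScan()]s.
#' @param speciesTemplate a [species()] supplying vbar, extinction and the
#'   initial mass guess.
#' @param buffer a [bufferSpec()].
#' @param floatBaseline float per-channel baselines? Default `FALSE`.
#' @param ... passed to [fitGlobal()] (`seed`, `pathlength`).
#' @return An `SEFit`; `fittedMass()` extracts the apparent molecular
#'   weight.
#' @export
fitMolecularWeight <- function(scans, speciesTemplate, buffer,
                               floatBaseline = FALSE, ...) {
  sch <- associationScheme("SINGLE", list(speciesTemplate))
  spec <- seFitSpec(sch, floatMass = TRUE, floatConc = TRUE,
                    floatBaseline = floatBaseline)
  fitGlobal(scans, spec, buffer, ...)
}

#' Association-constant fit with mass and concentration held fixed
#'
#' Implements the conventional association analysis: vbar, density,
#' extinction, number of associating units, molecular weight and loading
#' concentration are kept constant while the association constant floats
#' (in log space, multi-start). Kd is reported in mol/l for
#' `MONOMER_DIMER` (\eqn{[A]^2/[A_2]}) and mol^2/l^2 for `HETERO_2_2`
#' (\eqn{[A]^2[B_2]/[B_2A_2]}).
#'
#' @param scans list of [radialScan()]s.
#' @param scheme an associating [associationScheme()]; its `kd` is the
#'   initial value.
#' @param buffer a [bufferSpec()].
#' @param totalConcs total loading concentration at the reference radius,
#'   one per base species (vector, or channels x species matrix), mol/l.
#'   Held fixed; free concentrations follow from mass action at the current
#'   Kd.
#' @param floatConc float free concentrations instead of fixing totals.
#' @param floatBaseline float per-channel baselines.
#' @param kdBounds,nStarts see [seFitSpec()].
#' @param ... passed to [fitGlobal()].
#' @return An `SEFit`; `kdValue()` extracts the fitted Kd (linear scale).
#' @export
fitAssociation <- function(scans, scheme, buffer, totalConcs = NULL,
                           floatConc = FALSE, floatBaseline = FALSE,
                           kdBounds = NULL, nStarts = 5L, ...) {
  if (scheme@kind == "SINGLE")
    stop("association fit needs an associating scheme")
  spec <- seFitSpec(scheme, floatMass = FALSE, floatConc = floatConc,
                    floatKd = TRUE, floatBaseline = floatBaseline,
                    concValues = if (floatConc) NULL else totalConcs,
                    concAs = "total", kdBounds = kdBounds,
                    nStarts = nStarts)
  fitGlobal(scans, spec, buffer, ...)
}

#' Chi-square profile of the dissociation constant
#'
#' Fixes Kd at each point of a log-spaced grid centered on the best-fit
#' value, re-fits every remaining floated (nuisance) parameter, and records
#' the resulting chi-square. Confidence bounds are read off where the
#' profile first exceeds chi^2_min + `threshold` on either side (log-linear
#' interpolation); a sharp rise marks a well-constrained Kd, a flat side
#' yields a one-sided bound.
#'
#' @param scans list of [radialScan()]s.
#' @param spec an [seFitSpec()] with `floatKd = TRUE` describing the fit
#'   being profiled.
#' @param buffer a [bufferSpec()].
#' @param grid Kd values (linear scale, strictly increasing). Default: 25
#'   points spanning 3 decades either side of the best fit.
#' @param threshold delta chi-square defining the bounds (default 4).
#' @param seed,pathlength as in [fitGlobal()].
#' @return A `KdProfile` with the grid, chi-square curve, best Kd and the
#'   lower/upper bounds (NA when one-sided, with a warning).
#' @export
profileKd <- function(scans, spec, buffer, grid = NULL, threshold = 4,
                      seed = 1L, pathlength = 1.2) {
  stopifnot(inherits(spec, "seFitSpec"))
  if (!spec$floatKd)
    stop("profiling requires a spec with floatKd = TRUE")
  best <- fitGlobal(scans, spec, buffer, seed = seed,
                    pathlength = pathlength)
  bestKd <- kdValue(best)
  if (is.null(grid))
    grid <- 10^seq(log10(bestKd) - 3, log10(bestKd) + 3, length.out = 25L)
  grid <- sort(grid)

  # warm-start nuisance parameters at the best fit
  p <- best@params
  concBest <- NULL
  if (spec$floatConc) {
    nbase <- length(spec$scheme@speciesList)
    cv <- p$value[grepl("^conc\\.", p$name)]
    concBest <- matrix(cv, ncol = nbase, byrow = TRUE)
  }
  chi <- vapply(grid, function(g) {
    sp2 <- spec                       # fixed-Kd copy; nuisances keep floating
    sp2$scheme@kd <- g
    sp2$floatKd <- FALSE
    sp2$nStarts <- 1L
    sp2$init <- utils::modifyList(spec$init,
                  if (is.null(concBest)) list() else list(conc = concBest))
    chiSquare(fitGlobal(scans, sp2, buffer, seed = seed,
                        pathlength = pathlength))
  }, numeric(1))

  bestChi <- min(chiSquare(best), min(chi))
  target <- bestChi + threshold
  lg <- log10(grid)
  ib <- which.min(chi)
  crossing <- function(idx) {
    # first crossing of `target` walking outward from the minimum
    for (k in seq_along(idx)[-1L]) {
      i0 <- idx[k - 1L]; i1 <- idx[k]
      if (chi[i1] >= target && chi[i0] < target) {
        f <- (target - chi[i0]) / (chi[i1] - chi[i0])
        return(10^(lg[i0] + f * (lg[i1] - lg[i0])))
      }
    }
    NA_real_
  }
  lowerB <- crossing(rev(seq_len(ib)))
  upperB <- crossing(ib:length(grid))
  if (is.na(lowerB) || is.na(upperB))
    warning("chi-square profile does not cross chi^2_min + ", threshold,
            " on ", if (is.na(lowerB) && is.na(upperB)) "either side"
                    else if (is.na(lowerB)) "the lower side"
                    else "the upper side",
            "; reporting a one-sided bound")
  new("KdProfile", kdGrid = grid, chiSquare = chi, bestKd = bestKd,
      bestChiSquare = bestChi, lower = lowerB, upper = upperB,
      threshold = threshold)
}

#' Independent fits across an experimental condition series
#'
#' Runs one fit per condition (temperature, salt concentration, pH, ...)
#' and tabulates a summary metric against the condition: the apparent
#' single-species molecular weight (`mode = "apparent_mass"`) or -log10 of
#' the fitted dissociation constant (`mode = "kd"`). Failed or
#' non-converged conditions are flagged in the summary and the series
#' continues.
#'
#' @param scanSets named list; each element is the list of [radialScan()]s
#'   for one condition, names are the numeric condition values.
#' @param mode `"apparent_mass"` or `"kd"`.
#' @param scheme a [species()] template (apparent-mass mode) or an
#'   associating [associationScheme()] (kd mode).
#' @param buffer a [bufferSpec()], or a list of one per condition (e.g. a
#'   temperature series).
#' @param totalConcs for kd mode: totals passed to [fitAssociation()].
#' @param seed,pathlength as in [fitGlobal()].
#' @return A `ConditionSeries`; `summary()` returns the condition/metric
#'   table.
#' @export
conditionSeries <- function(scanSets, mode = c("apparent_mass", "kd"),
                            scheme, buffer, totalConcs = NULL, seed = 1L,
                            pathlength = 1.2) {
  mode <- match.arg(mode)
  if (length(scanSets) < 2L) stop("a series needs at least 2 conditions")
  conds <- suppressWarnings(as.numeric(names(scanSets)))
  if (any(is.na(conds)))
    stop("names(scanSets) must be numeric condition values")
  ord <- order(conds)
  if (any(duplicated(conds))) stop("conditions must be distinct")
  scanSets <- scanSets[ord]; conds <- conds[ord]
  buffers <- if (is(buffer, "Buffer")) rep(list(buffer), length(conds))
             else buffer[ord]

  fits <- vector("list", length(conds))
  metric <- rep(NA_real_, length(conds))
  conv <- rep(FALSE, length(conds))
  for (i in seq_along(conds)) {
    fit <- tryCatch({
      if (mode == "apparent_mass")
        fitMolecularWeight(scanSets[[i]], scheme, buffers[[i]], seed = seed,
                           pathlength = pathlength)
      else
        fitAssociation(scanSets[[i]], scheme, buffers[[i]],
                       totalConcs = totalConcs, seed = seed,
                       pathlength = pathlength)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      warning("condition ", conds[i], " failed: ", conditionMessage(fit))
      next
    }
    fits[[i]] <- fit
    conv[i] <- isConverged(fit)
    metric[i] <- if (mode == "apparent_mass") fittedMass(fit)
                 else -log10(kdValue(fit))
  }
  new("ConditionSeries",
      conditionName = "condition",
      summary = data.frame(condition = conds, metric = metric,
                           converged = conv),
      fits = fits, mode = mode)
}
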