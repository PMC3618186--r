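# Global-fit behaviour. Scans use a coarse 61-point grid; "1% noise" means
# a noise SD of 1% of the loading signal at the reference radius.

fitScans <- function(scheme, free, rpms, b, noiseSd, seed,
                     baseline = 0)
  simulateScans(scheme, free, rpms, b, radiiGrid = coarseGrid,
                noiseSd = noiseSd, seed = seed, baseline = baseline)

test_that("single-species global fits recover the generating mass", {
  b <- pbsBuffer()
  truth <- species("mono", 5470, 0.736, extinction230(44))
  sch <- associationScheme("SINGLE", list(truth))
  conc <- 8e-6   # ~0.3 AU at r0
  start <- species("mono", 7000, 0.736, extinction230(44))

  # noiseless: relative error < 1e-6
  scans0 <- fitScans(sch, conc, c(20000, 30000, 40000), b, 0, 1)
  fit0 <- fitMolecularWeight(scans0, start, b, seed = 1)
  expect_true(isConverged(fit0))
  expect_lt(abs(fittedMass(fit0) - 5470) / 5470, 1e-6)
  expect_lt(reducedChiSquare(fit0), 1e-12)

  # 1% noise: within the +-5% instrumental error
  a0 <- 0.3
  scans1 <- fitScans(sch, conc, c(20000, 30000, 40000), b, 0.01 * a0, 2)
  fit1 <- fitMolecularWeight(scans1, start, b, seed = 1)
  expect_lt(abs(fittedMass(fit1) - 5470) / 5470, 0.05)

  # reduced chi^2 estimates the noise variance
  expect_equal(reducedChiSquare(fit1), (0.01 * a0)^2, tolerance = 0.2)
})

test_that("mass recovery at 1% noise is tight over 20 seeded replicates", {
  b <- pbsBuffer()
  truth <- ccSpecies()
  sch <- associationScheme("SINGLE", list(truth))
  start <- species("cc", 20000, 0.726, extinction230(150))
  errs <- vapply(1:20, function(s) {
    scans <- fitScans(sch, 3e-6, c(20000, 30000), b, 0.005, s)
    abs(fittedMass(fitMolecularWeight(scans, start, b, seed = 1)) -
          17000) / 17000
  }, numeric(1))
  expect_lt(median(errs), 0.02)
  expect_lt(max(errs), 0.05)
})

test_that("a strongly dimerized pool fit as a single species shows an intermediate mass", {
  b <- pbsBuffer()
  sp <- ccSpecies()
  sch <- associationScheme("MONOMER_DIMER", list(sp), kd = 1e-9)
  scans <- fitScans(sch, totalToFree(sch, 6e-6), c(20000, 30000), b, 0, 1)
  app <- fittedMass(fitMolecularWeight(scans, sp, b, seed = 1))
  expect_gt(app, 17000)
  expect_lt(app, 34000)
})

test_that("duplicate scans leave the fitted parameters unchanged", {
  b <- pbsBuffer()
  sp <- ccSpecies()
  sch <- associationScheme("SINGLE", list(sp))
  scans <- fitScans(sch, 4e-6, c(20000, 30000), b, 0.003, 3)
  f1 <- fitMolecularWeight(scans, sp, b, seed = 1)
  f2 <- fitMolecularWeight(c(scans, scans), sp, b, seed = 1)
  expect_equal(fittedMass(f2), fittedMass(f1), tolerance = 1e-6)
  expect_equal(chiSquare(f2), 2 * chiSquare(f1), tolerance = 1e-6)
})

test_that("scan order does not change the reported fit", {
  b <- pbsBuffer()
  sp <- ccSpecies()
  sch <- associationScheme("SINGLE", list(sp))
  scans <- fitScans(sch, 4e-6, c(20000, 25000, 30000), b, 0.003, 4)
  spec <- seFitSpec(sch, floatMass = TRUE, floatConc = TRUE, nStarts = 1L)
  f1 <- fitGlobal(scans, spec, b, seed = 1)
  f2 <- fitGlobal(rev(scans), spec, b, seed = 1)
  expect_equal(fittedMass(f2), fittedMass(f1), tolerance = 1e-8)
  expect_equal(chiSquare(f2), chiSquare(f1), tolerance = 1e-8)
})

test_that("zero rotor speed is reported as non-identifiable, not silently fit", {
  b <- pbsBuffer()
  sp <- ccSpecies()
  sch <- associationScheme("SINGLE", list(sp))
  scans <- fitScans(sch, 4e-6, c(0, 0), b, 0.001, 1)
  expect_error(fitMolecularWeight(scans, sp, b), "non-identifiable")
})

test_that("monomer-dimer Kd is recovered within a factor of 2 at 1% noise", {
  b <- pbsBuffer()
  sp <- ccSpecies()
  truth <- associationScheme("MONOMER_DIMER", list(sp), kd = 40e-9)
  free <- totalToFree(truth, 10e-6)
  init <- associationScheme("MONOMER_DIMER", list(sp), kd = 1e-6)
  for (s in 1:3) {
    scans <- fitScans(truth, free, c(20000, 25000, 30000, 35000), b,
                      0.005, s)
    fit <- fitAssociation(scans, init, b, totalConcs = 10e-6, seed = s)
    kd <- kdValue(fit)
    expect_gt(kd, 20e-9)
    expect_lt(kd, 80e-9)
  }
})

test_that("data without association drive the fitted Kd to its upper bound, flagged", {
  b <- pbsBuffer()
  sp <- ccSpecies()
  none <- associationScheme("MONOMER_DIMER", list(sp), kd = 1e5)  # no dimer
  scans <- fitScans(none, 4e-6, c(20000, 30000), b, 0.003, 6)
  init <- associationScheme("MONOMER_DIMER", list(sp), kd = 1e-7)
  fit <- fitAssociation(scans, init, b, totalConcs = 4e-6, seed = 1,
                        kdBounds = c(1e-10, 1e-4))
  p <- fittedParams(fit)
  krow <- p[p$name == "log10kd", ]
  expect_equal(krow$value, -4, tolerance = 0.01)
  expect_true(krow$atBound)
})

test_that("chi-square profile is anchored at the best fit and monotone on noiseless data", {
  b <- pbsBuffer()
  sp <- ccSpecies()
  truth <- associationScheme("MONOMER_DIMER", list(sp), kd = 40e-9)
  scans <- fitScans(truth, totalToFree(truth, 10e-6),
                    c(20000, 25000, 30000), b, 0, 1)
  spec <- seFitSpec(associationScheme("MONOMER_DIMER", list(sp), kd = 1e-7),
                    floatKd = TRUE, floatConc = TRUE)
  grid <- 40e-9 * 10^seq(-2, 2, length.out = 13)
  pr <- suppressWarnings(profileKd(scans, spec, b, grid = grid, seed = 1))
  chi <- chiSquare(pr)
  best <- kdValue(pr)
  expect_equal(best, 40e-9, tolerance = 1e-3)
  # nuisance re-fits can never beat the global optimum
  expect_gte(min(chi), pr@bestChiSquare - 1e-9)
  # strictly increasing away from the minimum on both sides
  ib <- which.min(chi)
  expect_true(all(diff(chi[ib:length(chi)]) > 0))
  expect_true(all(diff(rev(chi[1:ib])) > 0))
})

test_that("a weakly constrained dataset yields a one-sided profile bound", {
  b <- pbsBuffer()
  sp <- ccSpecies()
  # binding too weak to populate the dimer at this loading: the lower side
  # of the profile stays flat
  truth <- associationScheme("MONOMER_DIMER", list(sp), kd = 1e-4)
  scans <- fitScans(truth, totalToFree(truth, 2e-6), c(20000, 25000), b,
                    0.005, 2)
  spec <- seFitSpec(associationScheme("MONOMER_DIMER", list(sp), kd = 1e-5),
                    floatKd = TRUE, floatConc = TRUE,
                    kdBounds = c(1e-9, 1e-2))
  expect_warning(
    pr <- profileKd(scans, spec, b,
                    grid = 10^seq(-8, -2, length.out = 9), seed = 1),
    "one-sided")
  expect_true(is.na(pr@lower) || is.na(pr@upper))
})

test_that("condition series tabulate the right summary and survive failures", {
  b <- pbsBuffer()
  sp <- ccSpecies()
  # apparent mass decreases as the generating Kd weakens with temperature
  kds <- c(1e-8, 1e-7, 1e-6, 1e-5)
  temps <- c(278, 283, 288, 293)
  sets <- list(); bufs <- list()
  for (i in seq_along(temps)) {
    bi <- bufferSpec(1.005, temps[i])
    si <- associationScheme("MONOMER_DIMER", list(sp), kd = kds[i])
    sets[[as.character(temps[i])]] <-
      simulateScans(si, totalToFree(si, 8e-6), 25000, bi,
                    radiiGrid = coarseGrid, noiseSd = 0.003, seed = i)
    bufs[[i]] <- bi
  }
  cs <- conditionSeries(sets, "apparent_mass", sp, bufs, seed = 1)
  s <- summary(cs)
  expect_true(all(diff(s$metric) < 0))
  expect_true(all(s$converged))

  # identical data at all conditions give identical summaries
  same <- list("1" = sets[[1]], "2" = sets[[1]])
  cs2 <- conditionSeries(same, "apparent_mass", sp, bufs[[1]], seed = 1)
  expect_equal(summary(cs2)$metric[1], summary(cs2)$metric[2])

  # -log10 Kd peaks at the condition where binding is tightest
  saltKds <- c(1e-6, 1e-8, 1e-5)
  salts <- c(0, 0.1, 0.25)
  ssets <- list()
  for (i in seq_along(salts)) {
    si <- associationScheme("MONOMER_DIMER", list(sp), kd = saltKds[i])
    ssets[[as.character(salts[i])]] <-
      simulateScans(si, totalToFree(si, 8e-6), c(20000, 30000), b,
                    radiiGrid = coarseGrid, noiseSd = 0.003, seed = 10 + i)
  }
  init <- associationScheme("MONOMER_DIMER", list(sp), kd = 1e-7)
  cs3 <- conditionSeries(ssets, "kd", init, b, totalConcs = 8e-6, seed = 1)
  m <- summary(cs3)$metric
  expect_equal(which.max(m), 2L)
})
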