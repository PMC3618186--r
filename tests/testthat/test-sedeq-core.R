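test_that("reduced exponent matches an independent scalar evaluation", {
  b <- bufferSpec(1.000, 277)
  # hand evaluation of M(1 - vbar rho) omega^2 / (RT)
  omega <- 25000 * 2 * pi / 60
  byHand <- 13880 * (1 - 0.731 * 1.000) * omega^2 / (8.314e7 * 277)
  expect_equal(reducedExponent(13880, 0.731, b, 25000), byHand,
               tolerance = 1e-12)
  expect_equal(byHand, 1.11, tolerance = 0.01)

  # neutral buoyancy and zero field
  b2 <- bufferSpec(1.1764706, 290)
  expect_equal(reducedExponent(20000, 0.85, b2, 30000), 0, tolerance = 1e-6)
  expect_equal(reducedExponent(20000, 0.72, b, 0), 0)
})

test_that("a single ideal species is log-linear in r^2 with slope sigma/2", {
  b <- pbsBuffer()
  sp <- ccSpecies()
  sch <- associationScheme("SINGLE", list(sp))
  sc <- radialScan(25000, 277, coarseGrid, rep(0, length(coarseGrid)),
                   referenceRadius = 7.0)
  a <- radialProfile(sch, 5e-6, sc, b, pathlength = 1.2, baseline = 0.02)
  sigma <- reducedExponent(17000, 0.726, b, 25000)
  fitlm <- lm(log(a - 0.02) ~ I(radii(sc)^2))
  expect_equal(unname(coef(fitlm)[2]), sigma / 2, tolerance = 1e-10)
  # strictly increasing when sigma > 0
  expect_true(all(diff(a) > 0))
})

test_that("monomer-dimer converges to the single-species profile as kd -> Inf", {
  b <- pbsBuffer()
  # compare on the concentration scale (epsilon = pathlength = 1) where the
  # sup-norm bound is meaningful: the dimer carries a fraction c/kd = 1e-10
  # of the monomer signal
  sp <- species("cc", 17000, 0.726, 1)
  conc <- 5e-6
  sc <- radialScan(25000, 277, coarseGrid, rep(0, length(coarseGrid)))
  single <- radialProfile(associationScheme("SINGLE", list(sp)), conc, sc,
                          b, pathlength = 1)
  md <- radialProfile(associationScheme("MONOMER_DIMER", list(sp),
                                        kd = 1e10 * conc), conc, sc, b,
                      pathlength = 1)
  expect_lt(max(abs(md - single)), 1e-10)
})

test_that("mass-weighted complex vbar makes buoyant masses additive and mass action radius-free", {
  b <- pbsBuffer()
  A <- species("A", 13880, 0.731, extinction230(124))
  B2 <- species("B2", 34000, 0.726, 2 * extinction230(150))
  kd <- 1e-12
  sch <- associationScheme("HETERO_2_2", list(A, B2), kd = kd)
  tab <- sedeq:::.speciesTable(sch)
  sig <- reducedExponent(tab$mass, tab$vbar, b, 25000)
  # sigma_complex = sigma_B2 + 2 sigma_A to machine precision
  expect_equal(sig[3], sig[2] + 2 * sig[1], tolerance = 1e-14)

  # therefore cA^2 cB2 / cC = kd at every radius, not just r0
  free <- totalToFree(sch, c(8e-6, 4e-6))
  r <- coarseGrid; r0 <- 7.0
  dr2 <- (r^2 - r0^2) / 2
  cA <- free[1] * exp(sig[1] * dr2)
  cB <- free[2] * exp(sig[2] * dr2)
  cC <- (free[1]^2 * free[2] / kd) * exp(sig[3] * dr2)
  expect_lt(max(abs(cA^2 * cB / cC - kd) / kd), 1e-12)
})

test_that("only the product epsilon * pathlength enters the signal", {
  b <- pbsBuffer()
  sc <- radialScan(20000, 277, coarseGrid, rep(0, length(coarseGrid)))
  s1 <- species("x", 17000, 0.726, 50000)
  s2 <- species("x", 17000, 0.726, 100000)
  a1 <- radialProfile(associationScheme("SINGLE", list(s1)), 4e-6, sc, b,
                      pathlength = 1.2)
  a2 <- radialProfile(associationScheme("SINGLE", list(s2)), 4e-6, sc, b,
                      pathlength = 0.6)
  expect_equal(a1, a2, tolerance = 1e-14)
})

test_that("totalToFree inverts mass action for both association schemes", {
  sp <- ccSpecies()
  md <- associationScheme("MONOMER_DIMER", list(sp), kd = 40e-9)
  free <- totalToFree(md, 10e-6)
  expect_equal(free + 2 * free^2 / 40e-9, 10e-6, tolerance = 1e-12 * 10e-6)

  A <- species("A", 13880, 0.731)
  B2 <- species("B2", 34000, 0.726)
  h <- associationScheme("HETERO_2_2", list(A, B2), kd = 1e-12)
  fr <- totalToFree(h, c(10e-6, 5e-6))
  cc <- fr[1]^2 * fr[2] / 1e-12
  expect_equal(fr[1] + 2 * cc, 10e-6, tolerance = 1e-9 * 10e-6)
  expect_equal(fr[2] + cc, 5e-6, tolerance = 1e-9 * 5e-6)

  expect_error(radialProfile(md, -1e-6,
                             radialScan(20000, 277, coarseGrid,
                                        rep(0, length(coarseGrid))),
                             pbsBuffer()), ">= 0")
})
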