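test_that("net charge reproduces limiting protonation states and a term-by-term sum", {
  # far below every pKa only the amino terminus carries charge
  expect_equal(netCharge("GGG", 0), 1, tolerance = 1e-3)
  expect_gt(netCharge("K", 7), 0)

  # independent term-by-term Henderson-Hasselbalch evaluation for DDKKH
  pk <- pkaSet("emboss")
  pH <- 7.0
  pos <- 1 / (1 + 10^(pH - pk["Nterm"])) +
    2 / (1 + 10^(pH - pk["K"])) +
    1 / (1 + 10^(pH - pk["H"]))
  neg <- 1 / (1 + 10^(pk["Cterm"] - pH)) +
    2 / (1 + 10^(pk["D"] - pH))
  expect_equal(netCharge("DDKKH", pH), unname(pos - neg), tolerance = 1e-12)

  expect_error(netCharge("GXZ", 7), "non-standard")
})

test_that("net charge is strictly decreasing in pH for random sequences", {
  set.seed(42)
  grid <- seq(0, 14, by = 0.5)
  for (i in 1:100) {
    q <- netCharge(randomSeq(sample(5:60, 1)), grid)
    expect_true(all(diff(q) < 0))
  }
})

test_that("isoelectric point matches symmetric and grid-scan oracles", {
  pk <- pkaSet("emboss")
  # single acid/base pair: crossing is exactly the pKa midpoint
  expect_equal(isoelectricPoint("GGGGG"),
               unname((pk["Nterm"] + pk["Cterm"]) / 2), tolerance = 2e-4)

  # fine-grid zero crossing as independent oracle (coarse scan, then 1e-5)
  seq <- "DDDDKKHH"
  coarse <- seq(0, 14, by = 0.01)
  qc <- netCharge(seq, coarse)
  i <- max(which(qc > 0))
  fine <- seq(coarse[i] - 0.02, coarse[i] + 0.02, by = 1e-5)
  qf <- netCharge(seq, fine)
  oracle <- fine[which.min(abs(qf))]
  expect_equal(isoelectricPoint(seq), oracle, tolerance = 2e-4)

  # the charge at the computed pI is numerically zero
  for (s in c("DDKKH", "KRDE", "MSDKSDLKAELERKK")) {
    expect_lt(abs(netCharge(s, isoelectricPoint(s))), 1e-3)
  }
})

test_that("windowed pI covers complete windows only and is translation invariant", {
  set.seed(7)
  s151 <- randomSeq(151)
  prof <- windowedPI(s151, window = 28, step = 7)
  expect_equal(nrow(prof), 18)  # floor((151-28)/7)+1
  expect_equal(prof$window_start, seq(1, by = 7, length.out = 18))
  expect_true(all(prof$window_end - prof$window_start == 27))

  # homopolymer: every window identical
  hp <- windowedPI(strrep("K", 40), window = 28, step = 7)
  expect_true(all(hp$pI == hp$pI[1]))

  # single window equals the whole-chain pI
  s28 <- randomSeq(28)
  one <- windowedPI(s28, window = 28, step = 7)
  expect_equal(nrow(one), 1)
  expect_equal(one$pI, isoelectricPoint(s28))

  # appending residues never changes earlier windows
  ext <- windowedPI(paste0(s151, randomSeq(14)), window = 28, step = 7)
  expect_equal(ext$pI[1:18], prof$pI)

  expect_error(windowedPI(randomSeq(10), window = 28), "exceeds")
})

test_that("average mass sums residue masses plus one water", {
  expect_equal(averageMass("G"), 75.07, tolerance = 0.005)
  expect_equal(averageMass("GG"), 2 * 57.0519 + 18.0153, tolerance = 1e-6)
  expect_equal(averageMass("AG"), averageMass("GA"))
  # residue-increment property for every standard residue
  set.seed(11)
  base <- randomSeq(12)
  for (x in c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")) {
    inc <- averageMass(paste0(x, base)) - averageMass(base)
    expect_equal(inc, averageMass(paste0(x, "G")) - averageMass("G"),
                 tolerance = 1e-9)
  }
})

test_that("230-nm extinction and helix geometry follow their defining rules", {
  expect_equal(extinction230(1), 900)
  expect_equal(extinction230(45), 40500)
  expect_equal(extinction230(150), 135000)
  expect_error(extinction230(0), ">= 1")

  expect_equal(round(helixEndToEnd(149, 0.30)), 67)
  expect_equal(helixEndToEnd(100, 1.0), 150)
  expect_equal(helixEndToEnd(145, 0.73), 158.775, tolerance = 1e-9)
  expect_error(helixEndToEnd(100, 1.2), "\\[0, 1\\]")

  expect_equal(heptadCount(415, 530), 16L)
  expect_equal(heptadCount(1, 7), 1L)
  expect_equal(heptadCount(1, 6), 0L)
  expect_error(heptadCount(10, 5), "<=")
})
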