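estimateCorrected <- function(records) {
  comp <- records[records$set == "competition", ]
  ctrl <- records[records$set == "control", ]
  sTot <- perGeneration(logRatioSelection(comp), comp$transfers,
                        comp$foldGrowth)
  sMar <- perGeneration(logRatioSelection(ctrl), ctrl$transfers,
                        ctrl$foldGrowth)
  markerCorrect(sTot, mean(sMar))
}

test_that("the no-noise limit recovers the truth to machine precision", {
  spec <- GeneratorSpec(trueS = 0.035, markerEffect = 0.012, markerOn = "i",
                        nReplicates = 3, seed = 11)
  rec <- generateAsexual(spec, infiniteDepth = TRUE)
  est <- estimateCorrected(rec)
  expect_equal(mean(est), 0.035, tolerance = 1e-12)

  # neutral competition with no marker: estimates are exactly zero
  rec0 <- generateAsexual(GeneratorSpec(trueS = 0, markerEffect = 0,
                                        nReplicates = 2, seed = 1),
                          infiniteDepth = TRUE)
  expect_equal(logRatioSelection(rec0[rec0$set == "competition", ]),
               c(0, 0))
})

test_that("multinomial counting noise leaves the estimator unbiased", {
  spec <- GeneratorSpec(trueS = 0.035, markerEffect = 0.01, markerOn = "j",
                        samplingDepth = 5e4, nReplicates = 8, seed = 42)
  est <- estimateCorrected(generateAsexual(spec))
  s <- replicateSummary(est)
  expect_lt(abs(s$mean - 0.035), 3 * s$se)
})

test_that("marker-swapped record sets agree after correction", {
  spec <- GeneratorSpec(trueS = 0.02, markerEffect = 0.01, markerOn = "i",
                        samplingDepth = 1e5, nReplicates = 8, seed = 17)
  rec <- generateAsexual(spec, markerSwap = TRUE)
  byOrientation <- lapply(c("i", "j"), function(side) {
    r <- rec[rec$markerOn == side, ]
    replicateSummary(estimateCorrected(r))
  })
  for (s in byOrientation)
    expect_lt(abs(s$mean - 0.02), 3 * s$se)
  # the two orientations agree with each other within combined error
  d <- abs(byOrientation[[1]]$mean - byOrientation[[2]]$mean)
  expect_lt(d, 3 * sqrt(byOrientation[[1]]$se^2 + byOrientation[[2]]$se^2))
})

test_that("estimator scatter shrinks roughly as depth^(-1/2)", {
  scatter <- function(depth) {
    spec <- GeneratorSpec(trueS = 0.03, markerEffect = 0, samplingDepth = depth,
                          nReplicates = 40, seed = 23)
    rec <- generateAsexual(spec, includeControls = FALSE)
    sd(perGeneration(logRatioSelection(rec), rec$transfers, rec$foldGrowth))
  }
  ratio <- scatter(1e3) / scatter(1e5)
  # expected sqrt(100) = 10; allow generous Monte-Carlo slack
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})

test_that("generator output is reproducible and latent overflows error", {
  spec <- GeneratorSpec(trueS = 0.05, seed = 9)
  expect_identical(generateAsexual(spec), generateAsexual(spec))
  # a huge effect over many generations drives the frequency to the boundary
  bad <- GeneratorSpec(trueS = 5, transfers = 50, foldGrowth = 1000, seed = 1)
  expect_error(generateAsexual(bad, infiniteDepth = TRUE), "outside")
})

test_that("sexual generator reproduces an assigned relative fitness", {
  # w = 1 at all densities: selection estimates scatter around zero
  spec <- GeneratorSpec(initialFreqI = 0.5, samplingDepth = 1e5,
                        nReplicates = 8, regime = "sexual", seed = 31)
  rec1 <- generateSexual(spec, w = 1, densities = c(1, 0.1))
  s1 <- replicateSummary(sexualSelection(rec1))
  expect_lt(abs(s1$mean), 3 * s1$se + 1e-12)

  # strong selection against the focal strain: s = 0.837 at low density
  recS <- generateSexual(spec, w = 1 - 0.837, densities = 0.001)
  sS <- replicateSummary(sexualSelection(recS))
  expect_lt(abs(sS$mean - 0.837), 3 * sS$se)

  # frequency-independent w: 9:1 and 1:9 starting ratios agree in expectation
  est_at <- function(f) {
    sp <- GeneratorSpec(initialFreqI = f, samplingDepth = 1e5,
                        nReplicates = 8, regime = "sexual", seed = 7)
    replicateSummary(sexualSelection(generateSexual(sp, w = 0.7)))
  }
  a <- est_at(0.9); b <- est_at(0.1)
  expect_lt(abs(a$mean - b$mean), 3 * sqrt(a$se^2 + b$se^2))

  # frequency-dependent w as a function of the before-frequency
  recF <- generateSexual(spec, w = function(f) 0.5 + 0.4 * f,
                         infiniteDepth = TRUE)
  expect_equal(unique(round(sexualSelection(recF), 10)), 1 - 0.7)
})

test_that("fixture grids encode their documented mating structure", {
  expect_error(fixtureGrids("nonesuch"), "available")

  set.seed(1)
  out <- matingRound(fixtureGrids("all_P_3x3"),
                     SimParams(sideLength = 4, density = 1))
  expect_equal(nrow(zygotes(out)), 0)

  # checkerboard: every cell has an eligible partner; the maximum matching
  # pairs all 16 cells
  cb <- fixtureGrids("checkerboard_4x4")
  expect_equal(maxMatchingMoore(cb), 8)
  set.seed(2)
  outCb <- matingRound(cb, SimParams(sideLength = 4, density = 1))
  expect_gt(nrow(zygotes(outCb)), 0)
  expect_lte(nrow(zygotes(outCb)), 8)

  # two non-switcher clones: mating only across the contact zone
  tc <- fixtureGrids("two_clone_10x10")
  expect_equal(maxMatchingMoore(tc), 10)
  set.seed(3)
  outTc <- matingRound(tc, SimParams(sideLength = 10, density = 1))
  z <- zygotes(outTc)
  expect_lte(nrow(z), 10)
  cols <- ((c(z$siteA, z$siteB) - 1) %/% 10) + 1
  expect_true(all(cols %in% c(5, 6)))
  expect_true(all(!z$intraclonal))

  # switcher variant: mixed types inside each clone let interior cells mate,
  # including intraclonally
  sw <- fixtureGrids("two_clone_10x10_switcher")
  expect_equal(maxMatchingMoore(sw), 50)
  set.seed(4)
  outSw <- matingRound(sw, SimParams(sideLength = 10, density = 1))
  expect_gt(nrow(zygotes(outSw)), 10)
  expect_true(any(zygotes(outSw)$intraclonal))
  # mated fraction far exceeds the non-switcher arrangement
  fracNs <- 2 * nrow(z) / 100
  fracSw <- 2 * nrow(zygotes(outSw)) / 100
  expect_gt(fracSw, 0.8)
  expect_lte(fracNs, 0.2)
})
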