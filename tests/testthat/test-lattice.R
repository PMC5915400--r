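test_that("seeding honours density, clone identity and strategy frequency", {
  p <- SimParams(sideLength = 50, density = 0.01, seed = 3)
  set.seed(3)
  lat <- seedGrid(p)
  expect_equal(occupancy(lat), 25)  # round(0.01 * 2500)
  cl <- lat@cloneId[lat@cloneId != 0L]
  expect_length(unique(cl), 25)

  # degenerate frequency: all founders non-switchers, both types present
  set.seed(4)
  lat0 <- seedGrid(SimParams(sideLength = 40, density = 0.5), switcherFreq = 0)
  st <- lat0@strategy[lat0@matingType != 0L]
  expect_true(all(st == 2L))
  expect_true(all(lat0@switchPhase[lat0@matingType != 0L] == 0L))
  types <- lat0@matingType[lat0@matingType != 0L]
  expect_setequal(unique(types), c(1L, 2L))

  # switchers start in either phase, about half and half
  set.seed(5)
  lat1 <- seedGrid(SimParams(sideLength = 40, density = 0.5),
                   switcherFreq = 1)
  ph <- lat1@switchPhase[lat1@matingType != 0L]
  expect_setequal(unique(ph), c(1L, 2L))

  # fewer than two founders is a configuration error
  expect_error(SimParams(sideLength = 10, density = 0.005),
               "fewer than 2 founders")
  expect_error(seedGrid(SimParams(sideLength = 10, density = 0.02),
                        switcherFreq = 2), "switcherFreq")
})

test_that("division follows the switching pedigree", {
  p1 <- SimParams(sideLength = 4, density = 0.5, growthChance = 1)
  # single non-switcher P cell with R = 1: forced division, type conserved
  mt <- matrix(0L, 4, 4); mt[2, 2] <- 1L
  lat <- makeLattice(mt)
  set.seed(1)
  g <- growthRound(lat, p1)
  expect_equal(occupancy(g), 2)
  expect_true(all(g@matingType[g@matingType != 0L] == 1L))
  expect_length(unique(g@cloneId[g@cloneId != 0L]), 1)

  # will-switch P switcher: exactly one resulting cell is M and won't-switch,
  # the other stays P and competent
  st <- matrix(0L, 4, 4); st[2, 2] <- 1L
  ph <- matrix(0L, 4, 4); ph[2, 2] <- 1L
  for (seed in 1:5) {
    set.seed(seed)
    g <- growthRound(makeLattice(mt, st, ph), p1)
    types <- g@matingType[g@matingType != 0L]
    phases <- g@switchPhase[g@matingType != 0L]
    expect_setequal(types, c(1L, 2L))
    expect_equal(g@switchPhase[g@matingType == 2L], 2L)  # switched: wont
    expect_equal(g@switchPhase[g@matingType == 1L], 1L)  # original: will
  }

  # won't-switch switcher: both cells keep the type, one becomes competent
  ph[2, 2] <- 2L
  set.seed(9)
  g <- growthRound(makeLattice(mt, st, ph), p1)
  expect_true(all(g@matingType[g@matingType != 0L] == 1L))
  expect_setequal(g@switchPhase[g@matingType != 0L], c(1L, 2L))

  # fully occupied grid is unchanged by a growth round
  full <- makeLattice(matrix(1L, 4, 4))
  set.seed(2)
  g <- growthRound(full, p1)
  expect_identical(g@matingType, full@matingType)
  expect_identical(g@cloneId, full@cloneId)
})

test_that("growth fills the grid and occupancy never decreases", {
  p <- SimParams(sideLength = 10, density = 0.02, seed = 7)
  mt <- matrix(0L, 10, 10); mt[5, 5] <- 2L
  lat <- makeLattice(mt)
  set.seed(7)
  full <- runGrowth(lat, p)
  expect_equal(occupancy(full), 100)
  expect_true(attr(full, "filled"))
  expect_true(all(full@cloneId == 1L))
  expect_true(all(full@matingType == 2L))  # non-switcher conserves type

  # occupancy is non-decreasing round by round
  set.seed(8)
  cur <- seedGrid(SimParams(sideLength = 15, density = 0.1))
  occ <- occupancy(cur)
  for (i in 1:5) {
    cur <- growthRound(cur, SimParams(sideLength = 15, density = 0.1))
    expect_gte(occupancy(cur), occ)
    occ <- occupancy(cur)
  }

  # near-zero effective division probability trips the round safeguard
  mtz <- matrix(0L, 6, 6); mtz[3, 3] <- 1L
  icz <- matrix(0L, 6, 6); icz[3, 3] <- 1L
  latz <- makeLattice(mtz, intraclonal = icz)
  set.seed(1)
  expect_error(
    runGrowth(latz, SimParams(sideLength = 6, density = 0.5,
                              growthChance = 0.01,
                              intraclonalCost = 1e-9)),
    "safeguard")
})

test_that("two symmetric founders grow patches of equal expected size", {
  # Monte-Carlo oracle: with s = 0 the two clones are exchangeable, so the
  # mean size of clone 1 is half the grid; with the switcher at s = 0.5 its
  # mean patch is smaller.
  p0 <- SimParams(sideLength = 10, density = 0.02, growthChance = 0.5)
  mt <- matrix(0L, 10, 10); mt[3, 3] <- 1L; mt[8, 8] <- 2L
  sizes0 <- vapply(1:200, function(i) {
    set.seed(i)
    g <- runGrowth(makeLattice(mt), p0)
    sum(g@cloneId == 1L)
  }, numeric(1))
  se <- sd(sizes0) / sqrt(length(sizes0))
  expect_lt(abs(mean(sizes0) - 50), 3 * se)

  st <- matrix(0L, 10, 10); st[3, 3] <- 1L; st[8, 8] <- 2L
  ph <- matrix(0L, 10, 10); ph[3, 3] <- 1L
  ps <- SimParams(sideLength = 10, density = 0.02, growthChance = 0.5,
                  switchingCost = 0.5)
  sizesS <- vapply(1:200, function(i) {
    set.seed(i)
    g <- runGrowth(makeLattice(mt, st, ph), ps)
    sum(g@cloneId == 1L)  # the switcher clone
  }, numeric(1))
  expect_lt(mean(sizesS), mean(sizes0) - 3 * se)
})

test_that("mating pairs opposite types, each cell at most once", {
  # forced pairing of one P and one M
  mt <- matrix(0L, 4, 4); mt[1, 1] <- 1L; mt[1, 2] <- 2L
  set.seed(1)
  out <- matingRound(makeLattice(mt), SimParams(sideLength = 4, density = 0.5),
                     requireFull = FALSE)
  expect_equal(nrow(zygotes(out)), 1)

  # incompatible monoculture
  set.seed(1)
  out0 <- matingRound(fixtureGrids("all_P_3x3"),
                      SimParams(sideLength = 4, density = 1))
  expect_equal(nrow(zygotes(out0)), 0)

  # mating requires a full grid unless growth was truncated
  expect_error(matingRound(makeLattice(mt),
                           SimParams(sideLength = 4, density = 0.5)),
               "fully occupied")

  # property: random grids obey the zygote contract
  p <- SimParams(sideLength = 8, density = 1)
  for (seed in 1:10) {
    set.seed(seed)
    lat <- seedGrid(p)
    out <- matingRound(lat, p)
    z <- zygotes(out)
    sites <- c(z$siteA, z$siteB)
    expect_false(anyDuplicated(sites) > 0)
    expect_true(all(lat@matingType[z$siteA] != lat@matingType[z$siteB]))
    expect_lte(nrow(z), floor(occupancy(lat) / 2))
    # mated matrix agrees with the zygote list
    expect_setequal(which(matedMatrix(out) == 1L), sites)
  }
})

test_that("global mating realises the mass-action maximum matching", {
  # with nP = nM = k every cell finds a partner: exactly k zygotes
  pg <- SimParams(sideLength = 4, density = 1, matingMode = "global")
  for (seed in 1:8) {
    set.seed(seed)
    types <- sample(rep(c(1L, 2L), 8))
    lat <- makeLattice(matrix(types, 4, 4))
    out <- matingRound(lat, pg)
    expect_equal(nrow(zygotes(out)), 8)
  }
  # unbalanced types: min(nP, nM) zygotes
  for (k in c(1, 3, 5)) {
    set.seed(k)
    types <- sample(c(rep(1L, k), rep(2L, 16 - k)))
    out <- matingRound(makeLattice(matrix(types, 4, 4)), pg)
    expect_equal(nrow(zygotes(out)), k)
  }
})

test_that("moore mating cannot exceed, and global attains, the matching bound", {
  p <- SimParams(sideLength = 6, density = 1)
  for (seed in 1:6) {
    set.seed(seed)
    lat <- seedGrid(p)
    bound <- maxMatchingMoore(lat)
    set.seed(seed + 100)
    out <- matingRound(lat, p)
    expect_lte(nrow(zygotes(out)), bound)
  }
})

test_that("the gamete pool follows Mendelian segregation", {
  expect_equal(nextFounderPool(makeOutcome(c(1, 1), c(1, 1)))$switcherFreq, 1)
  expect_equal(nextFounderPool(makeOutcome(1, 2))$switcherFreq, 0.5)
  expect_equal(
    nextFounderPool(makeOutcome(c(1, 1, 1, 2), c(1, 1, 1, 2)))$switcherFreq,
    0.75)  # (2*3 + 0) / (2*4)

  # intraclonal fractions weight heterozygous zygotes half to each strategy:
  # one intraclonal SWxSW and one outcrossed SWxNS zygote gives switcher
  # gametes 2 (intra) + 1 (out) and non-switcher gametes 1 (out)
  out <- makeOutcome(c(1, 1), c(1, 2), intraclonal = c(TRUE, FALSE))
  pool <- nextFounderPool(out)
  expect_equal(pool$switcherFreq, 0.75)
  expect_equal(pool$intraclonalFracs[["switcher"]], 2 / 3)
  expect_equal(pool$intraclonalFracs[["nonswitcher"]], 0)

  # extinction is a distinct condition
  empty <- new("MatingOutcome",
               zygotes = data.frame(siteA = integer(), siteB = integer(),
                                    strategyA = integer(),
                                    strategyB = integer(),
                                    cloneA = integer(), cloneB = integer(),
                                    intraclonal = logical()),
               mated = matrix(0L, 2, 2), nOccupied = 4L)
  expect_error(nextFounderPool(empty), class = "switchsim_extinction")
})

test_that("intraclonal cost slows intraclonal-origin clones", {
  # two founders differing only in the intraclonal flag; with c = 0.2 the
  # flagged clone should end up smaller on average
  mt <- matrix(0L, 10, 10); mt[3, 3] <- 1L; mt[8, 8] <- 2L
  ic <- matrix(0L, 10, 10); ic[3, 3] <- 1L
  p <- SimParams(sideLength = 10, density = 0.02, intraclonalCost = 0.2)
  sizes <- vapply(1:100, function(i) {
    set.seed(i)
    g <- runGrowth(makeLattice(mt, intraclonal = ic), p)
    sum(g@cloneId == 1L)
  }, numeric(1))
  expect_lt(mean(sizes), 35)
})

test_that("the Bernoulli pedigree variant runs and stays reproducible", {
  p <- SimParams(sideLength = 15, density = 0.1, pedigree = "bernoulli",
                 maxTransfers = 5, seed = 13)
  a <- runSimulation(p)
  b <- runSimulation(p)
  expect_identical(trajectory(a), trajectory(b))
  # switching still happens: a single switcher founder yields both types
  mt <- matrix(0L, 10, 10); mt[5, 5] <- 1L
  st <- matrix(0L, 10, 10); st[5, 5] <- 1L
  ph <- matrix(0L, 10, 10); ph[5, 5] <- 1L
  set.seed(3)
  g <- runGrowth(makeLattice(mt, st, ph),
                 SimParams(sideLength = 10, density = 0.02,
                           pedigree = "bernoulli"))
  expect_setequal(unique(as.vector(g@matingType)), c(1L, 2L))
})

test_that("torus and bounded boundaries agree qualitatively", {
  mean_ratio <- function(boundary, cost) {
    base <- SimParams(sideLength = 30, density = 0.1, boundary = boundary,
                      maxTransfers = 40, initialSwitcherFreq = 0.9,
                      switchingCost = cost)
    r <- vapply(1:6, function(i) {
      p <- base; p@seed <- 300L + i
      finalNonSwitcherFreq(runSimulation(p))
    }, numeric(1))
    mean(r)
  }
  # no cost: non-switchers cannot invade under either boundary
  expect_lt(mean_ratio("bounded", 0), 0.05)
  expect_lt(mean_ratio("torus", 0), 0.05)
  # strong cost at moderate density: invasion under both boundaries
  expect_gt(mean_ratio("bounded", 0.5), 0.5)
  expect_gt(mean_ratio("torus", 0.5), 0.5)
})
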