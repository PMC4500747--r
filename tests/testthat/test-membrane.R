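test_that("total sodium conductance is conserved across distributions", {
  mesh <- buildTissueSheet(modelConfig(nRows = 2, nCols = 3))
  area <- mesh@patches$area
  total <- 16 * sum(area)
  for (f in c(0, 0.11, 0.5, 0.9, 1)) {
    g <- partitionChannels(mesh, f, 16)
    expect_equal(sum(g * area), total, tolerance = 1e-10)
  }
  jun <- mesh@patches$class == "junctional"
  g1 <- partitionChannels(mesh, 1, 16)
  expect_true(all(g1[!jun] == 0))
  g9 <- partitionChannels(mesh, 0.9, 16)
  expect_equal(sum(g9[jun] * area[jun]), 0.9 * total, tolerance = 1e-10)
  expect_equal(unique(round(g9[jun], 9)),
               round(0.9 * total / sum(area[jun]), 9))
  expect_error(partitionChannels(mesh, 1.2, 16), "junctionalFraction")
})

test_that("ionic current vanishes at rest and scales with gNa", {
  ionic <- ionicModel()
  Vr <- ephapse:::resting_potential(ionic)
  g <- gatingSteadyState(Vr)
  st <- list(m = g$mInf, h = g$hInf)
  expect_lt(abs(ionicCurrent(Vr, st, ionic)), 1e-8)

  # sodium component scales exactly with the gNaScale factor
  V <- -20; st2 <- list(m = 0.6, h = 0.4)
  iK <- ionic$gK * (V - ionic$EK)
  i1 <- ionicCurrent(V, st2, ionic)
  ionic86 <- ionic; ionic86$gNaScale <- 0.86
  i2 <- ionicCurrent(V, st2, ionic86)
  expect_equal(i2 - iK, 0.86 * (i1 - iK), tolerance = 1e-12)

  # peak inward current in a voltage-step simulation is proportional to gNa
  step_peak <- function(gNa) {
    io <- ionicModel(gNa = gNa)
    st <- with(gatingSteadyState(-83), list(m = mInf, h = hInf))
    peak <- 0
    for (k in 1:400) {
      st <- stepGating(st, -30, 0.005)
      peak <- min(peak, ionicCurrent(-30, st, io) - io$gK * (-30 - io$EK))
    }
    peak
  }
  expect_equal(step_peak(32) / step_peak(16), 2, tolerance = 1e-9)
})

test_that("exponential gating updates match the closed-form gate solution", {
  V <- -40; dt <- 0.01
  g <- gatingSteadyState(V)
  st <- list(m = 0.1, h = 0.9)
  cur <- st
  for (k in 1:500) cur <- stepGating(cur, V, dt)
  t <- 500 * dt
  expect_equal(cur$m, g$mInf + (st$m - g$mInf) * exp(-t / g$tauM),
               tolerance = 1e-12)
  expect_equal(cur$h, g$hInf + (st$h - g$hInf) * exp(-t / g$tauH),
               tolerance = 1e-12)

  # long integration converges to the analytic steady state
  for (k in 1:4000) cur <- stepGating(cur, V, 0.05)
  expect_equal(cur$m, g$mInf, tolerance = 1e-9)
  expect_equal(cur$h, g$hInf, tolerance = 1e-9)
})

test_that("gating update reduces to forward Euler as dt shrinks", {
  V <- -50; st <- list(m = 0.2, h = 0.7)
  g <- gatingSteadyState(V)
  euler <- function(dt) st$m + (g$mInf - st$m) / g$tauM * dt
  err <- vapply(c(1e-3, 5e-4), function(dt)
    abs(stepGating(st, V, dt)$m - euler(dt)), 0)
  # halving dt shrinks the discrepancy ~4x (second-order difference)
  expect_lt(err[2], err[1] / 3)
})

test_that("gating variables stay within [0, 1] for arbitrary inputs", {
  set.seed(7)
  st <- list(m = runif(200), h = runif(200))
  for (k in 1:20) {
    V <- runif(200, -110, 60)
    st <- stepGating(st, V, 0.2)
    expect_true(all(st$m >= 0 & st$m <= 1))
    expect_true(all(st$h >= 0 & st$h <= 1))
  }
})

test_that("a single cell is excitable with a threshold", {
  cfg <- modelConfig(nRows = 1, nCols = 1, duration = 15,
                     junctionalFraction = 0)
  mesh <- buildTissueSheet(cfg)
  sys <- assembleSystem(mesh, cfg)
  sup <- runProtocol(cfg, stimulusCells = 1, system = sys)
  expect_gt(max(sup@traces) - sup@traces[1, 1], 80)

  cfgSub <- cfg
  cfgSub@solver$stimAmplitude <- 1
  sub <- runProtocol(cfgSub, stimulusCells = 1, system = sys)
  expect_lt(max(sub@traces) - sub@traces[1, 1], 20)
  expect_lt(abs(sub@traces[1, ncol(sub@traces)] -
                  sub@meta$restingPotential), 2)
})

test_that("maximum upstroke velocity is non-decreasing in gNa", {
  vmax <- vapply(c(10, 16, 30), function(gna) {
    cfg <- modelConfig(nRows = 1, nCols = 1, duration = 10,
                       junctionalFraction = 0,
                       ionic = ionicModel(gNa = gna))
    r <- runProtocol(cfg, stimulusCells = 1)
    max(diff(r@traces[1, ]) / diff(r@time))
  }, 0)
  expect_true(all(diff(vmax) >= 0))
})
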