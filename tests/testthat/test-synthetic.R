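test_that("scenario configs validate their knobs", {
  expect_error(scenarioConfig(cadence = 2), "cadence")
  expect_error(scenarioConfig(carbonFraction = 0), "carbonFraction")
  expect_error(scenarioConfig(carbonFraction = 1.2), "carbonFraction")
  expect_error(scenarioConfig(backgroundMean = 1, seasonalAmplitude = 2),
               "positivity")
  expect_error(scenarioConfig(ar1 = 1), "ar1")
})

test_that("background is constant when noise and seasonality vanish", {
  cfg <- scenarioConfig(nCols = 3, nRows = 3, nYears = 1,
                        seasonalAmplitude = 0, noiseSd = 0,
                        backgroundMean = 4.2, seed = 1)
  bg <- simulateBackground(cfg)
  expect_true(all(bg$values == 4.2))
  expect_equal(length(bg$dates), 365L)
})

test_that("generators are deterministic and independently streamed", {
  cfg <- scenarioConfig(nYears = 1, nMonitors = 4, seed = 99)
  s1 <- simulateScenario(cfg)
  s2 <- simulateScenario(cfg)
  expect_identical(assay(s1$fields, "all_sources"),
                   assay(s2$fields, "all_sources"))
  expect_identical(s1$monitors, s2$monitors)
  expect_identical(s1$population, s2$population)
  # adding monitors must not perturb the fields (per-generator streams)
  s3 <- simulateScenario(scenarioConfig(nYears = 1, nMonitors = 9, seed = 99))
  expect_identical(assay(s1$fields, "all_sources"),
                   assay(s3$fields, "all_sources"))
  # a different seed changes the fields
  s4 <- simulateScenario(scenarioConfig(nYears = 1, nMonitors = 4, seed = 100))
  expect_false(identical(assay(s1$fields, "all_sources"),
                         assay(s4$fields, "all_sources")))
})

test_that("background log-values have the configured lag-1 autocorrelation", {
  cfg <- scenarioConfig(nCols = 1, nRows = 1, nYears = 28,
                        seasonalAmplitude = 0, ar1 = 0.5, noiseSd = 0.4,
                        backgroundMean = 4, seed = 31)
  bg <- simulateBackground(cfg)
  x <- log(as.vector(bg$values))
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.5), 0.05)
  expect_true(all(bg$values > 0))
})

test_that("fire plumes follow the closed-form Gaussian formula", {
  cfg <- scenarioConfig(nCols = 10, nRows = 10, nYears = 1, seed = 1)
  # no events: zero field
  f0 <- simulateFire(cfg, events = list())
  expect_true(all(f0$values == 0))

  ev <- fireEvent(originCol = 4, originRow = 6, start = "2007-06-10",
                  duration = 4, peak = 120, sigma = 1.5, vx = 0.5, vy = -0.25,
                  riseFrac = 0.25, decayFrac = 0.25)
  f <- simulateFire(cfg, events = list(ev))
  # closed-form oracle at an off-centre cell-day: day k = 2, cell (6, 5)
  k <- 2
  cx <- 4 + k * 0.5; cy <- 6 + k * (-0.25)
  d2 <- (6 - cx)^2 + (5 - cy)^2
  u <- (k + 0.5) / 4
  prof <- min(1, u / 0.25, (1 - u) / 0.25)
  want <- 120 * prof * exp(-d2 / (2 * 1.5^2))
  j <- which(f$dates == as.Date("2007-06-12"))
  cell <- (5 - 1) * 10 + 6
  expect_equal(unname(f$values[cell, j]), want)

  # near-zero sigma: mass confined to the origin cell, value = peak * profile
  evp <- fireEvent(5, 5, "2007-07-01", duration = 2, peak = 80, sigma = 1e-9,
                   riseFrac = 0, decayFrac = 0)
  fp <- simulateFire(cfg, events = list(evp))
  jj <- which(fp$dates == as.Date("2007-07-01"))
  org <- (5 - 1) * 10 + 5
  expect_equal(unname(fp$values[org, jj]), 80)
  expect_equal(sum(fp$values[-org, jj] != 0), 0)
})

test_that("event days outside the date range are clipped with a warning", {
  cfg <- scenarioConfig(nCols = 5, nRows = 5, nYears = 1, seed = 1)
  ev <- fireEvent(3, 3, "2007-12-30", duration = 5, peak = 50, sigma = 1)
  expect_warning(f <- simulateFire(cfg, events = list(ev)), "clipped")
  expect_gt(f$values[(3 - 1) * 5 + 3, ncol(f$values)], 0)
})

test_that("composition stores the recoverable truth and zero fire collapses the runs", {
  cfg <- scenarioConfig(nCols = 6, nRows = 6, nYears = 1, seed = 12)
  bg <- simulateBackground(cfg)
  f0 <- simulateFire(cfg, events = list())
  fs0 <- composeFields(bg, f0, smokeGrid(0, 0, cfg$cellSize, 6, 6, cfg$crs))
  expect_identical(assay(fs0, "all_sources"), assay(fs0, "no_fire"))

  fire <- simulateFire(cfg)
  fs <- composeFields(bg, fire, smokeGrid(0, 0, cfg$cellSize, 6, 6, cfg$crs))
  rec <- fireDifference(fs)
  expect_identical(assay(rec, "fire"), assay(rec, "fire_truth"))
  expect_error(composeFields(bg, list(values = fire$values[, 1:10],
                                      dates = fire$dates[1:10]),
                             smokeGrid(0, 0, cfg$cellSize, 6, 6)),
               "share")
})

test_that("unit tiling covers the grid with near-equal blocks", {
  cfg <- scenarioConfig(nCols = 4, nRows = 4, unitsX = 2, unitsY = 2,
                        includeTinyUnit = FALSE, nYears = 1, seed = 1)
  un <- generateUnits(cfg)
  expect_length(un, 4)
  asg <- assignCells(smokeGrid(0, 0, cfg$cellSize, 4, 4), un)
  counts <- table(assignmentTable(asg)$unit_id)
  expect_true(all(counts == 4))
  expect_length(unassignedCells(asg), 0)

  cfgT <- scenarioConfig(nCols = 4, nRows = 4, unitsX = 2, unitsY = 2,
                         includeTinyUnit = TRUE, nYears = 1, seed = 1)
  unT <- generateUnits(cfgT)
  asgT <- assignCells(smokeGrid(0, 0, cfgT$cellSize, 4, 4), unT)
  expect_equal(emptyUnits(asgT), "U_TINY")
})

test_that("population tables are valid and seeded", {
  cfg <- scenarioConfig(nYears = 1, seed = 5)
  un <- generateUnits(cfg)
  p1 <- generatePopulation(cfg, unitIds(un))
  p2 <- generatePopulation(cfg, unitIds(un))
  expect_identical(p1, p2)
  expect_true(all(p1$total_population > 0))
  expect_true(all(p1$under18 <= p1$total_population))
  # the sub-cell unit is small so it lands in the Missing row realistically
  expect_lt(p1$total_population[p1$unit_id == "U_TINY"],
            min(p1$total_population[p1$unit_id != "U_TINY"]))
})

test_that("noise-free unbiased monitors reproduce predictions exactly", {
  cfg <- scenarioConfig(nYears = 1, nMonitors = 6, monitorNoiseSd = 0,
                        biasFactor = 1, seed = 3)
  sc <- simulateScenario(cfg)
  mon <- sc$monitors
  expect_equal(mon$obs_carbon, mon$pred_carbon)
  lab <- stratifyByFireImpact(mon$pred_fire_carbon)
  out <- stratumSummary(mon$obs_carbon, mon$pred_carbon, lab,
                        format(mon$date, "%Y"))
  expect_true(all(out$difference == 0))
})

test_that("per-year bias factors must cover every simulated year", {
  cfg <- scenarioConfig(nYears = 2, nMonitors = 2,
                        biasFactor = c("2007" = 0.8), seed = 3)
  expect_error(simulateScenario(cfg), "every simulated year")
  cfg2 <- scenarioConfig(nYears = 1, nMonitors = 2, monitorNoiseSd = 0,
                         biasFactor = c("2007" = 0.5), seed = 3)
  mon <- simulateScenario(cfg2)$monitors
  expect_equal(mon$obs_carbon, 0.5 * mon$pred_carbon)
})

test_that("replication scenario shows the sparse-peak exposure pattern", {
  sc <- simulateScenario(replicationScenarioConfig(seed = 1))
  fs <- fireDifference(sc$fields)
  uf <- unitDailyMean(fs, sc$assignment, "fire")
  uf <- uf[rownames(uf) != "U_TINY", ]
  # most unit-days essentially smoke-free ...
  expect_gte(mean(uf < 1), 0.8)
  # ... punctuated by multi-day unit-level peaks above the NAAQS level
  cnt <- smokewaveCounts(uf)
  expect_gt(sum(cnt$total, na.rm = TRUE), 0)
  expect_gt(max(uf, na.rm = TRUE), 35)
})
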