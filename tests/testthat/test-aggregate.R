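test_that("unit daily means are unweighted averages over member cells", {
  g <- smokeGrid(0, 0, 1, nCols = 2, nRows = 1)
  d <- as.Date("2008-07-01")
  fs <- smokeFieldSet(g, d, fire = matrix(c(2, 4), 2, 1),
                      all_sources = matrix(c(2, 4), 2, 1),
                      no_fire = matrix(0, 2, 1))
  both <- adminUnits("AB", list(rectRing(0, 0, 2, 1)))
  asg <- assignCells(g, both)
  expect_equal(as.vector(unitDailyMean(fs, asg, "fire")), 3)

  one <- adminUnits(c("L", "R"),
                    list(rectRing(0, 0, 1, 1), rectRing(1, 0, 2, 1)))
  asgLR <- assignCells(g, one)
  m <- unitDailyMean(fs, asgLR, "fire")
  expect_equal(unname(m["L", ]), 2)  # singleton mean = the cell itself
  expect_equal(unname(m["R", ]), 4)
})

test_that("empty units yield missing series, not zeros", {
  g <- smokeGrid(0, 0, 1, nCols = 2, nRows = 2)
  d <- as.Date("2008-01-01") + 0:1
  fs <- smokeFieldSet(g, d, fire = matrix(5, 4, 2),
                      all_sources = matrix(5, 4, 2),
                      no_fire = matrix(0, 4, 2))
  un <- adminUnits(c("BIG", "TINY"),
                   list(rectRing(0, 0, 2, 2), rectRing(0.9, 0.9, 1.1, 1.1)))
  m <- unitDailyMean(fs, assignCells(g, un), "fire")
  expect_true(all(is.na(m["TINY", ])))
  expect_true(all(m["BIG", ] == 5))
})

test_that("random field unit means equal the brute-force oracle", {
  set.seed(5)
  g <- smokeGrid(0, 0, 1, nCols = 5, nRows = 5)
  d <- as.Date("2010-01-01") + 0:9
  vals <- matrix(rlnorm(250), 25, 10)
  fs <- smokeFieldSet(g, d, all_sources = vals, no_fire = vals * 0, fire = vals)
  rings <- list(A = rectRing(0, 0, 2.25, 5), B = rectRing(2.25, 0, 5, 2.25),
                C = rectRing(2.25, 2.25, 5, 5))
  asg <- assignCells(g, adminUnits(names(rings), rings))
  m <- unitDailyMean(fs, asg, "fire")
  cen <- cellCentroids(g)
  for (nm in names(rings)) {
    members <- cen$cell[vapply(seq_len(25), function(i)
      oraclePointInRing(cen$x[i], cen$y[i], rings[[nm]]), logical(1))]
    expect_equal(m[nm, ], colMeans(vals[members, , drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("annual summary gives closed-form mean and sd conventions", {
  d <- as.Date("2011-01-01") + 0:2
  s <- matrix(c(1, 2, 3), 1, 3, dimnames = list("U", as.character(d)))
  a <- annualSummary(s)
  expect_equal(a$mean, 2)
  expect_equal(a$sd, sqrt(2 / 3))  # population convention by default
  expect_equal(a$n_days, 3L)
  expect_equal(annualSummary(s, sdType = "sample")$sd, 1)

  cst <- matrix(4.2, 1, 3, dimnames = list("U", as.character(d)))
  ac <- annualSummary(cst)
  expect_equal(ac$mean, 4.2)
  expect_equal(ac$sd, 0)
})

test_that("empty selections are missing, never zero", {
  d <- as.Date("2011-06-01") + 0:4
  s <- matrix(1:5, 1, 5, dimnames = list("U", as.character(d)))
  a <- annualSummary(s, years = 2012)
  expect_true(is.na(a$mean) && is.na(a$sd))
  expect_equal(a$n_days, 0L)
  # a coverage rule blanks sparsely observed unit-years
  expect_true(is.na(annualSummary(s, minFraction = 0.5)$mean))
  expect_false(is.na(annualSummary(s, minFraction = 0.01)$mean))
})

test_that("aggregation commutes: day-mean of unit series equals cell-day mean", {
  set.seed(9)
  g <- smokeGrid(0, 0, 1, nCols = 4, nRows = 4)
  d <- as.Date("2012-01-01") + 0:364
  vals <- matrix(rlnorm(16 * 365), 16, 365)
  fs <- smokeFieldSet(g, d, fire = vals, all_sources = vals,
                      no_fire = vals * 0)
  un <- adminUnits(c("W", "E"),
                   list(rectRing(0, 0, 2, 4), rectRing(2, 0, 4, 4)))
  asg <- assignCells(g, un)
  m <- unitDailyMean(fs, asg, "fire")
  per <- periodSummary(m)
  for (u in c("W", "E")) {
    cells <- cellsForUnit(asg, u)
    expect_equal(per$mean[per$unit_id == u], mean(vals[cells, ]))
  }
})

test_that("percent attributable reproduces published arithmetic", {
  expect_equal(round(percentAttributable(4.40, 8.90), 1), 49.4)
  expect_equal(round(percentAttributable(0.57, 8.41), 1), 6.8)
  expect_equal(percentAttributable(0, 5), 0)
  expect_warning(out <- percentAttributable(1, 0), "non-positive")
  expect_true(is.na(out))
})

test_that("quartile breaks interpolate order statistics and bound classes", {
  b <- quartileBreaks(1:8)
  expect_equal(unname(breakPoints(b)), c(2.75, 4.5, 6.25, 8))
  expect_error(quartileBreaks(c(1, 2, 3)), "at least 4")
  expect_error(quartileBreaks(c(1, 2, NA, NA, NA)), "at least 4")

  # degenerate: identical values collapse all units into class 1
  bd <- quartileBreaks(rep(3.3, 10))
  expect_equal(classifyExposure(rep(3.3, 5), bd), rep(1L, 5))
})

test_that("exposure classes are lower-open upper-closed intervals", {
  b <- californiaBreaks()
  expect_equal(classifyExposure(c(0, 0.34, 0.35, 0.56, 0.57, 0.86, 0.87,
                                  20.3, 25), b),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L))
  expect_warning(cl <- classifyExposure(-0.01, b), "negative")
  expect_equal(cl, 1L)
  expect_equal(classifyExposure(NA, b), NA_integer_)
})

test_that("class occupancy is near-uniform for continuous pooled values", {
  set.seed(21)
  v <- rlnorm(4000)
  cl <- classifyExposure(v, quartileBreaks(v))
  expect_equal(as.vector(table(cl)) / 4000, rep(0.25, 4), tolerance = 0.002)
})
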