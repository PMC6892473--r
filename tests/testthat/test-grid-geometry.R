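test_that("grid centroids follow the half-cell offset formula", {
  g1 <- smokeGrid(0, 0, 2, nCols = 1, nRows = 1)
  cen <- cellCentroids(g1)
  expect_equal(cen$x, 1)
  expect_equal(cen$y, 1)

  g2 <- smokeGrid(0, 0, 10, nCols = 3, nRows = 2)
  cen2 <- cellCentroids(g2)
  i <- which(cen2$col == 3 & cen2$row == 2)
  expect_equal(c(cen2$x[i], cen2$y[i]), c(25, 15))
  expect_equal(cen2$cell, seq_len(6))

  # study-resolution grid: centroids spaced one cell size apart
  g3 <- smokeGrid(-100000, 50000, 12000, nCols = 5, nRows = 4)
  cen3 <- cellCentroids(g3)
  expect_equal(unique(diff(sort(unique(cen3$x)))), 12000)
  expect_equal(unique(diff(sort(unique(cen3$y)))), 12000)
})

test_that("degenerate grid arguments are rejected", {
  expect_error(smokeGrid(0, 0, 0, nCols = 2, nRows = 2), "positive")
  expect_error(smokeGrid(0, 0, -5, nCols = 2, nRows = 2), "positive")
  expect_error(smokeGrid(0, 0, 10, nCols = 0, nRows = 2), "positive integers")
})

test_that("a unit covering the whole extent captures every cell", {
  g <- smokeGrid(0, 0, 1, nCols = 4, nRows = 3)
  un <- adminUnits("A", list(rectRing(0, 0, 4, 3)))
  asg <- assignCells(g, un)
  expect_equal(nrow(assignmentTable(asg)), 12)
  expect_length(unassignedCells(asg), 0)
  expect_length(emptyUnits(asg), 0)
})

test_that("a sub-cell unit avoiding all centroids is flagged empty", {
  g <- smokeGrid(0, 0, 1, nCols = 4, nRows = 4)
  un <- adminUnits(c("BIG", "TINY"),
                   list(rectRing(0, 0, 4, 4),
                        rectRing(0.9, 0.9, 1.1, 1.1)))  # centred on a corner
  asg <- assignCells(g, un)
  expect_equal(emptyUnits(asg), "TINY")
  expect_equal(sort(unique(assignmentTable(asg)$unit_id)), "BIG")
})

test_that("two abutting rectangles match the brute-force containment oracle", {
  g <- smokeGrid(0, 0, 1, nCols = 4, nRows = 4)
  rings <- list(L = rectRing(0, 0, 2, 4), R = rectRing(2, 0, 4, 4))
  un <- adminUnits(names(rings), rings)
  asg <- assignCells(g, un)
  cen <- cellCentroids(g)
  expected <- vapply(seq_len(16), function(i) {
    hits <- names(rings)[vapply(rings, function(r)
      oraclePointInRing(cen$x[i], cen$y[i], r), logical(1))]
    if (length(hits)) hits[1] else NA_character_
  }, character(1))
  tb <- assignmentTable(asg)
  got <- tb$unit_id[match(cen$cell, tb$cell)]
  expect_equal(got, expected)
  expect_equal(nrow(tb), 16)  # partition: every cell assigned
})

test_that("random rectangle partitions agree with the oracle and mgcv", {
  skip_if_not_installed("mgcv")
  set.seed(42)
  for (rep in 1:20) {
    nc <- sample(3:7, 1); nr <- sample(3:7, 1)
    g <- smokeGrid(0, 0, 1, nCols = nc, nRows = nr)
    # interior split at x.25 so no centroid (at .5 offsets) sits on it
    split <- round(runif(1, 1, nc - 1)) + 0.25
    rings <- list(A = rectRing(0, 0, split, nr), B = rectRing(split, 0, nc, nr))
    un <- adminUnits(names(rings), rings)
    asg <- assignCells(g, un)
    cen <- cellCentroids(g)
    for (nm in names(rings)) {
      ours <- sort(cellsForUnit(asg, nm))
      oracle <- cen$cell[vapply(seq_len(nrow(cen)), function(i)
        oraclePointInRing(cen$x[i], cen$y[i], rings[[nm]]), logical(1))]
      expect_equal(ours, sort(oracle))
      ring <- rbind(rings[[nm]], rings[[nm]][1, ])
      io <- mgcv::in.out(ring, cbind(cen$x, cen$y))
      expect_equal(ours, sort(cen$cell[io]))
    }
    # partition property: per-unit counts sum to the full grid
    expect_equal(nrow(assignmentTable(asg)), nc * nr)
  }
})

test_that("assignment depends only on centroids and is order-independent", {
  g <- smokeGrid(0, 0, 1, nCols = 5, nRows = 5)
  rings <- list(B = rectRing(0, 0, 2.25, 5), A = rectRing(2.25, 0, 5, 5))
  a1 <- assignCells(g, adminUnits(names(rings), rings))
  a2 <- assignCells(g, adminUnits(rev(names(rings)), rev(rings)))
  t1 <- assignmentTable(a1); t2 <- assignmentTable(a2)
  expect_equal(t1[order(t1$cell), ], t2[order(t2$cell), ],
               ignore_attr = TRUE)
})

test_that("boundary centroids and overlaps resolve to the first unit id with a warning", {
  # 3x1 grid, shared edge exactly through the middle centroid (x = 1.5)
  g <- smokeGrid(0, 0, 1, nCols = 3, nRows = 1)
  un <- adminUnits(c("B", "A"),
                   list(rectRing(0, 0, 1.5, 1), rectRing(1.5, 0, 3, 1)))
  expect_warning(asg <- assignCells(g, un), "more than one unit|boundary")
  tb <- assignmentTable(asg)
  expect_equal(tb$unit_id[tb$cell == 2], "A")  # lexicographic winner

  # full overlap: both polygons contain every centroid
  un2 <- adminUnits(c("ZED", "ALF"),
                    list(rectRing(0, 0, 3, 1), rectRing(0, 0, 3, 1)))
  expect_warning(asg2 <- assignCells(g, un2), "more than one unit")
  expect_equal(unique(assignmentTable(asg2)$unit_id), "ALF")
  expect_equal(emptyUnits(asg2), "ZED")
})

test_that("holes are honoured under the parity rule", {
  g <- smokeGrid(0, 0, 1, nCols = 3, nRows = 3)
  donut <- list(rectRing(0, 0, 3, 3), rectRing(1, 1, 2, 2))  # hole over centre
  asg <- assignCells(g, adminUnits("D", list(donut)))
  expect_equal(sort(unassignedCells(asg)), 5L)  # centre cell in the hole
  expect_equal(nrow(assignmentTable(asg)), 8)
})

test_that("self-intersecting rings are rejected", {
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(adminUnits("X", list(bowtie)), "self-intersecting")
})

test_that("GeoJSON units round-trip through write and read", {
  un <- adminUnits(c("A", "B"),
                   list(rectRing(0, 0, 2, 4), rectRing(2, 0, 4, 4)),
                   unitNames = c("Alpha", "Beta"))
  tmp <- tempfile(fileext = ".geojson")
  writeUnitsGeoJSON(un, tmp, attributes = data.frame(unit_id = c("A", "B"),
                                                     total = c(3L, 0L)))
  back <- readUnitsGeoJSON(tmp)
  expect_equal(unitIds(back), unitIds(un))
  expect_equal(unitNames(back), unitNames(un))
  # same assignment from both representations
  g <- smokeGrid(0, 0, 1, nCols = 4, nRows = 4)
  expect_equal(assignmentTable(assignCells(g, back)),
               assignmentTable(assignCells(g, un)))
  unlink(tmp)
})
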