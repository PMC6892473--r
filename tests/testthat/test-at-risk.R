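popTable <- function(n, seed = 3) {
  set.seed(seed)
  data.frame(unit_id = sprintf("U%02d", seq_len(n)),
             total_population = round(runif(n, 1e4, 1e6)),
             under18 = round(runif(n, 1e3, 1e5)),
             asthma_ed = rpois(n, 500))
}

test_that("at-risk tabulation matches brute-force per-class sums", {
  set.seed(14)
  pop <- popTable(10)
  cl <- sample(c(1:4, NA), 10, replace = TRUE)
  names(cl) <- pop$unit_id
  tab <- tabulateAtRisk(cl, pop)
  for (v in c("total_population", "under18", "asthma_ed")) {
    for (k in 1:4)
      expect_equal(tab[[v]][tab$class == as.character(k)],
                   sum(pop[[v]][!is.na(cl) & cl == k]))
    expect_equal(tab[[v]][tab$class == "Missing"], sum(pop[[v]][is.na(cl)]))
    expect_equal(tab[[v]][tab$class == "Total"], sum(pop[[v]]))
  }
})

test_that("class rows plus Missing conserve the column totals", {
  set.seed(15)
  for (rep in 1:10) {
    pop <- popTable(12, seed = rep)
    cl <- sample(c(1:4, NA), 12, replace = TRUE)
    names(cl) <- pop$unit_id
    tab <- tabulateAtRisk(cl, pop)
    for (v in c("total_population", "under18", "asthma_ed"))
      expect_equal(sum(tab[[v]][tab$class != "Total"]),
                   tab[[v]][tab$class == "Total"])
  }
})

test_that("single-class degenerate tables behave", {
  pop <- popTable(5)
  cl <- rep(2L, 5); names(cl) <- pop$unit_id
  tab <- tabulateAtRisk(cl, pop)
  expect_equal(tab$total_population[tab$class == "2"],
               tab$total_population[tab$class == "Total"])
  expect_equal(tab$total_population[tab$class %in% c("1", "3", "4", "Missing")],
               rep(0, 4))
  fa <- fractionAbove(tab, minClass = 2)
  expect_equal(fa$percent[fa$variable == "total_population"], 100)
  expect_equal(fractionAbove(tab, minClass = 3)$percent[1], 0)
})

test_that("duplicate unit ids and bad classes are rejected", {
  pop <- popTable(4)
  pop$unit_id[2] <- pop$unit_id[1]
  cl <- c(1L, 2L, 3L, 4L); names(cl) <- pop$unit_id
  expect_error(tabulateAtRisk(cl, pop), "duplicate")
  pop2 <- popTable(4)
  cl2 <- c(0L, 2L, 3L, 4L); names(cl2) <- pop2$unit_id
  expect_error(tabulateAtRisk(cl2, pop2), "1..4")
})

test_that("published at-risk table reproduces the printed shares", {
  tab <- californiaAtRiskTable()
  fa <- fractionAbove(tab, minClass = 2)
  g <- function(v) fa$percent[fa$variable == v]
  expect_equal(round(g("over65"), 1), 56.5)
  expect_equal(round(g("under18"), 1), 57.2)
  expect_equal(round(g("asthma_ed")), 75)
  # the printed Total row is preserved as published, not recomputed
  expect_equal(tab$total_population[tab$class == "Total"], 36.78)
})

test_that("fraction above is non-increasing in the class cut", {
  tab <- californiaAtRiskTable()
  p <- vapply(1:4, function(k)
    fractionAbove(tab, minClass = k)$percent[
      fractionAbove(tab, minClass = k)$variable == "total_population"],
    numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_equal(p[1], 100 * sum(tab$total_population[tab$class %in% as.character(1:4)]) /
                 tab$total_population[tab$class == "Total"])
})

test_that("smokewave population tabulation follows the episode threshold", {
  pop <- data.frame(unit_id = c("A", "B", "C"),
                    total_population = c(1, 2, 3))
  counts <- c(A = 0, B = 7, C = 14)
  out <- smokewavePopulation(counts, pop, 7)
  expect_equal(out$population, 5)
  expect_equal(out$percent, 100 * 5 / 6, tolerance = 1e-12)
  expect_equal(out$n_units, 2L)

  # everyone qualifies at one episode when all units have at least one
  all1 <- smokewavePopulation(c(A = 1, B = 7, C = 14), pop, 1)
  expect_equal(all1$percent, 100)

  # monotone non-increasing in the threshold
  p <- vapply(c(1, 7, 14, 15), function(m)
    smokewavePopulation(counts, pop, m)$percent, numeric(1))
  expect_true(all(diff(p) <= 0))
  # NA counts (missing units) never qualify
  expect_equal(smokewavePopulation(c(A = NA, B = 7, C = 14), pop, 1)$population, 5)
})

test_that("pooled counts are allocated proportionally to population", {
  pop <- data.frame(unit_id = c("A", "B", "POOL"),
                    total_population = c(100, 300, 0),
                    births = c(10, 20, 40))
  out <- allocatePooledCounts(pop, "births", "POOL", to = c("A", "B"))
  expect_equal(out$births[out$unit_id == "A"], 10 + 40 * 0.25)
  expect_equal(out$births[out$unit_id == "B"], 20 + 40 * 0.75)
  expect_false("POOL" %in% out$unit_id)
  expect_equal(sum(out$births), 70)  # counts conserved
  expect_error(allocatePooledCounts(pop, "births", "NOPE", to = "A"), "not found")
})
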