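test_that("the pooled t test matches the closed-form oracle", {
  # hand-derived: means 12 vs 6, pooled var 4, t = 6/sqrt(8/3), df = 4
  res <- unpairedTTest(c(10, 12, 14), c(4, 6, 8))
  expect_equal(res$statistic, 3.6742346142, tolerance = 1e-8)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.0213116411, tolerance = 1e-7)
  expect_equal(res$stars, "*")
  expect_equal(res$reduction_pct, 50)
})

test_that("the t test is symmetric in sign and handles no-variance input", {
  a <- c(10, 12, 14); b <- c(4, 6, 8)
  expect_equal(unpairedTTest(b, a)$statistic, -unpairedTTest(a, b)$statistic)
  expect_equal(unpairedTTest(b, a)$p_value, unpairedTTest(a, b)$p_value)
  same <- unpairedTTest(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(unpairedTTest(c(5, 5, 5), c(7, 7, 7)), "zero variance")
  welch <- unpairedTTest(c(1, 2, 3, 9), c(2, 2.1, 1.9, 2.05),
                         varEqual = FALSE)
  expect_match(welch$test, "Welch")
})

test_that("two-way ANOVA on constant data reports F = 0, p = 1", {
  tab <- expand.grid(group = c("control", "ablated"), quarter = 1:4,
                     rep = 1:3)
  tab$count <- 7
  res <- twoWayANOVA(tab)
  expect_equal(res$statistic[1:3], c(0, 0, 0))
  expect_equal(res$p_value[1:3], c(1, 1, 1))
})

test_that("a pure group effect leaves quarter and interaction SS at zero", {
  tab <- expand.grid(group = c("control", "ablated"), quarter = 1:4,
                     rep = 1:4)
  tab$count <- ifelse(tab$group == "control", 10, 4)
  res <- twoWayANOVA(tab)
  expect_gt(res$sum_sq[res$effect == "group"], 0)
  expect_equal(res$sum_sq[res$effect == "quarter"], 0)
  expect_equal(res$sum_sq[res$effect == "group:quarter"], 0)
})

test_that("balanced ANOVA matches the cell-means oracle to 1e-9", {
  set.seed(55)
  for (rep in 1:5) {
    tab <- expand.grid(group = c("control", "ablated"), quarter = 1:4,
                       rep = 1:5)
    tab$count <- rpois(nrow(tab), 20) +
      ifelse(tab$group == "ablated", -3, 0) + as.integer(tab$quarter)
    res <- twoWayANOVA(tab)
    oracle <- cellMeansAnova(tab)
    expect_equal(res$sum_sq[res$effect == "group"],
                 unname(oracle$ss["group"]), tolerance = 1e-9)
    expect_equal(res$sum_sq[res$effect == "quarter"],
                 unname(oracle$ss["quarter"]), tolerance = 1e-9)
    expect_equal(res$sum_sq[res$effect == "group:quarter"],
                 unname(oracle$ss["interaction"]), tolerance = 1e-9)
    expect_equal(res$statistic[1:3], unname(oracle$F), tolerance = 1e-9)
    expect_equal(res$p_value[1:3], unname(oracle$p), tolerance = 1e-9)
    # exact decomposition
    expect_equal(sum(res$sum_sq), unname(oracle$ss["total"]),
                 tolerance = 1e-9)
  }
})

test_that("empty cells and single-level factors are rejected", {
  tab <- expand.grid(group = c("control", "ablated"), quarter = 1:4,
                     rep = 1:2)
  tab$count <- 1:16
  expect_error(twoWayANOVA(tab[tab$group == "control", ]), "2 levels")
  expect_error(twoWayANOVA(tab[!(tab$group == "control" &
                                   tab$quarter == 2), ]), "empty")
})

test_that("unbalanced designs run with Type II and Type III SS", {
  set.seed(56)
  tab <- expand.grid(group = c("control", "ablated"), quarter = 1:4,
                     rep = 1:6)
  tab$count <- rpois(nrow(tab), 15)
  tab <- tab[-c(1, 10, 20), ]   # unbalance
  t2 <- twoWayANOVA(tab, type = "II")
  t3 <- twoWayANOVA(tab, type = "III")
  expect_equal(t2$effect[1:3], c("group", "quarter", "group:quarter"))
  expect_true(all(is.finite(t2$p_value[1:3])))
  # interaction SS agrees between types; main effects generally differ
  expect_equal(t2$sum_sq[3], t3$sum_sq[t3$effect == "group:quarter"],
               tolerance = 1e-9)
})

test_that("Tukey with two groups reproduces the F-test p (q^2 = F)", {
  set.seed(57)
  tab <- expand.grid(group = c("control", "ablated"), quarter = 1:4,
                     rep = 1:5)
  tab$count <- rpois(nrow(tab), 20) - 4 * (tab$group == "ablated")
  an <- twoWayANOVA(tab)
  tk <- tukeyHSD(tab, "group")
  expect_equal(tk$p_adj, an$p_value[an$effect == "group"], tolerance = 1e-6)
})

test_that("Tukey flags only the separated level in a planted design", {
  set.seed(58)
  tab <- expand.grid(group = c("control", "ablated"), quarter = 1:4,
                     rep = 1:10)
  tab$count <- rnorm(nrow(tab), 20, 1)
  tab$count[tab$quarter == 3] <- tab$count[tab$quarter == 3] + 15  # >= 10 SD
  tk <- tukeyHSD(tab, "quarter")
  vs3 <- grepl("(^3-|-3$)", tk$comparison)
  expect_true(all(tk$p_adj[vs3] < 1e-4))
  expect_true(all(tk$p_adj[!vs3] > 0.05))
  # identical means: adjusted p near 1
  flat <- tab; flat$count <- rnorm(nrow(flat), 20, 1)
  expect_true(all(tukeyHSD(flat, "group")$p_adj > 0.05))
})

test_that("significance stars follow the figure-legend convention", {
  expect_equal(starAnnotation(c(0.5, 0.03, 0.002, 5e-5)),
               c("ns", "*", "**", "****"))
  # boundaries take the less significant label
  expect_equal(starAnnotation(c(0.05, 0.01, 0.001, 0.0001)),
               c("ns", "*", "**", "***"))
  expect_equal(starAnnotation(0.0005), "***")
  expect_error(starAnnotation(1.2), "0, 1")
  expect_error(starAnnotation(-0.1), "0, 1")
})

test_that("fish totals aggregate counts per fish across quarters", {
  tab <- simulateCounts(simCohortSpec(groupMeans = 10, nFishPerGroup = 3,
                                      seed = 60))
  tot <- fishTotals(tab)
  expect_equal(nrow(tot), 6)
  one <- tab[tab$fish_id == tot$fish_id[1] & tab$group == tot$group[1], ]
  expect_equal(tot$total[1], sum(one$count))
  # excluding qrt4 then totalling drops exactly the qrt4 counts
  tot3 <- fishTotals(excludeRegion(tab))
  expect_equal(sum(tot$total) - sum(tot3$total),
               sum(tab$count[tab$quarter == 4]))
})
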