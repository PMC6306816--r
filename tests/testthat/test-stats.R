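# Group statistics: ANOVA against hand-computed sums of squares, Holm-Sidak
# against hand-evaluated cases, invariances, and condition comparison.

test_that("ANOVA matches hand-computed sums of squares", {
  # groups {0,1} and {1,2}: SSB = 1, SSW = 1, df = (1, 2) -> F = 2
  res <- oneWayAnova(list(c(0, 1), c(1, 2)))
  expect_equal(res$fStatistic, 2)
  expect_equal(unname(res$df), c(1, 2))
  expect_equal(res$pValue, 1 - pf(2, 1, 2))
  # identical groups: F = 0, p = 1
  res0 <- oneWayAnova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res0$fStatistic, 0)
  expect_equal(res0$pValue, 1)
})

test_that("degenerate within-group variance yields the documented sentinels", {
  res <- oneWayAnova(list(c(1, 1), c(2, 2)))
  expect_identical(res$fStatistic, Inf)
  expect_identical(res$pValue, 0)
  resAll <- oneWayAnova(list(c(3, 3), c(3, 3)))
  expect_equal(resAll$fStatistic, 0)
  expect_equal(resAll$pValue, 1)
})

test_that("ANOVA rejects undersized or non-finite groups", {
  expect_error(oneWayAnova(list(c(1, 2))), "two groups")
  expect_error(oneWayAnova(list(c(1, 2), 3)), "at least two values")
  expect_error(oneWayAnova(list(c(1, 2), c(NA, 1))), "finite")
})

test_that("ANOVA F is invariant to location and scale changes", {
  withr::local_seed(5)
  g <- list(rnorm(8), rnorm(8, 0.5), rnorm(8, 1))
  f0 <- oneWayAnova(g)$fStatistic
  expect_equal(oneWayAnova(lapply(g, function(v) v + 13))$fStatistic, f0)
  expect_equal(oneWayAnova(lapply(g, function(v) v * 2.7))$fStatistic, f0)
})

test_that("Holm-Sidak reproduces hand-computed adjustments", {
  expect_equal(holmSidak(0.03), 0.03)
  # p = {0.01, 0.04}: 1 - 0.99^2 = 0.0199, step-down keeps 0.04
  expect_equal(holmSidak(c(0.01, 0.04)), c(0.0199, 0.04))
  # ties: each becomes 1 - 0.5^3 = 0.875 after the running maximum
  expect_equal(holmSidak(c(0.5, 0.5, 0.5)), rep(0.875, 3))
  expect_error(holmSidak(c(0.5, 1.2)), "0, 1")
})

test_that("Holm-Sidak is monotone, dominating, and order-equivariant", {
  withr::local_seed(8)
  for (i in 1:20) {
    p <- runif(7)
    adj <- holmSidak(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # step-down monotonicity in the sorted order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # permutation equivariance
    perm <- sample(7)
    expect_equal(holmSidak(p[perm]), adj[perm])
    # idempotence on already-adjusted values
    expect_true(all(holmSidak(adj) >= adj - 1e-12))
  }
})

test_that("null ANOVA keeps its nominal type-I error rate", {
  withr::local_seed(2024)
  reject <- 0L
  nRep <- 1000L
  for (i in seq_len(nRep)) {
    g <- list(rnorm(8), rnorm(8), rnorm(8))
    if (oneWayAnova(g)$pValue < 0.05) reject <- reject + 1L
  }
  expect_gte(reject / nRep, 0.03)
  expect_lte(reject / nRep, 0.07)
})

test_that("compareConditions assembles groups and flags unknown labels", {
  tab <- data.frame(
    condition = rep(c("serum-free", "PDGF", "TGFb"), each = 4),
    oi_percent = c(20, 25, 19, 30, 62, 70, 58, 66, 60, 68, 55, 71))
  cmp <- compareConditions(tab)
  expect_s4_class(cmp, "GroupComparison")
  expect_equal(sort(cmp@groupLabels), sort(c("serum-free", "PDGF", "TGFb")))
  expect_equal(nrow(cmp@pairwise), 3)
  expect_true(all(cmp@pairwise$p_adj >= cmp@pairwise$p_raw - 1e-12))
  df <- as.data.frame(cmp)
  expect_true(all(c("group1", "group2", "p_raw", "p_adj", "f_statistic",
                    "anova_p") %in% names(df)))
  expect_error(compareConditions(tab, conditions = c("serum-free", "PDGF")),
               "unknown condition")
  expect_error(compareConditions(tab[tab$condition == "PDGF", ]),
               "two conditions")
})

test_that("all-identical OI values across groups give F = 0, p = 1", {
  tab <- data.frame(condition = rep(c("a", "b"), each = 3),
                    oi_percent = rep(50, 6))
  cmp <- compareConditions(tab)
  expect_equal(cmp@fStatistic, 0)
  expect_equal(cmp@pValue, 1)
  expect_true(all(cmp@pairwise$p_adj == 1))
})

test_that("synthetic conditions reproduce the expected OI ordering", {
  # serum-free-like (kappa 2) vs growth-factor-like (kappa 20) substrates
  kappas <- c(`serum-free` = 2, PDGF = 20, TGFb = 20)
  rows <- list()
  for (j in seq_along(kappas)) {
    for (k in 1:8) {
      img <- smallFibrilField(meanAngleDeg = -90, kappa = kappas[j],
                              seed = 100 * j + k, sizePx = 256,
                              nFibrils = 80)
      oi <- oiPercent(orientationIndex(orientationDistribution(img), 90))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = names(kappas)[j], oi_percent = oi)
    }
  }
  tab <- do.call(rbind, rows)
  cmp <- compareConditions(tab)
  m <- vapply(cmp@oiSamples, mean, numeric(1))
  expect_lt(m[["serum-free"]], m[["PDGF"]])
  expect_lt(m[["serum-free"]], m[["TGFb"]])
  expect_lt(abs(m[["PDGF"]] - m[["TGFb"]]), 15)
})
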