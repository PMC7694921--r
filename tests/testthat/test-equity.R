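test_that("Lorenz curve handles perfect equality and full concentration", {
  eq <- lorenz_curve(c(1, 1), c(1, 1))
  expect_equal(eq$x, c(0, 0.5, 1))
  expect_equal(eq$y, c(0, 0.5, 1))

  conc <- lorenz_curve(c(0, 1), c(1, 1))
  expect_equal(conc$x, c(0, 0.5, 1))
  expect_equal(conc$y, c(0, 0, 1))

  expect_error(lorenz_curve(c(0, 0), c(1, 1)),
               class = "hera_degenerate_error")
})

test_that("Lorenz curve equals an explicit sort-then-cumsum recomputation", {
  set.seed(101)
  for (rep in 1:10) {
    n <- 4
    r <- runif(n, 0, 5)
    b <- runif(n, 0.5, 3)
    lc <- lorenz_curve(r, b)
    ord <- order(r / b)                       # oracle: sort by ratio
    expect_equal(lc$x, c(0, cumsum(b[ord]) / sum(b)))
    expect_equal(lc$y, c(0, cumsum(r[ord]) / sum(r)))
    # invariants: ends, monotone, below diagonal
    expect_equal(lc$x[1], 0); expect_equal(lc$y[1], 0)
    expect_equal(lc$x[n + 1], 1, tolerance = 1e-12)
    expect_equal(lc$y[n + 1], 1, tolerance = 1e-12)
    expect_true(all(diff(lc$x) >= 0) && all(diff(lc$y) >= 0))
    expect_true(all(lc$y <= lc$x + 1e-12))
  }
})

test_that("Gini matches hand values and the pairwise mean-difference oracle", {
  expect_equal(gini(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(gini(c(0, 1), c(0.5, 0.5)), 0.5)

  set.seed(7)
  for (rep in 1:20) {
    n <- 13
    r <- runif(n, 0.1, 5)
    b <- runif(n, 0.5, 3)
    expect_equal(gini(r, b), gini_pairwise(r, b), tolerance = 1e-12)
  }
})

test_that("Gini is invariant to resource scaling and to unit replication", {
  set.seed(8)
  r <- runif(10, 0.1, 4); b <- runif(10, 0.5, 2)
  g <- gini(r, b)
  expect_equal(gini(1000 * r, b), g, tolerance = 1e-12)
  # duplicate every unit with half the basis and half the resource each
  expect_equal(gini(c(r, r) / 2, c(b, b) / 2), g, tolerance = 1e-12)
})

test_that("Theil index matches hand evaluation and merge invariance", {
  expect_equal(theil_total(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(theil_total(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3))

  # merging two units with identical P/E ratios leaves T unchanged
  set.seed(9)
  p <- c(0.2, 0.3, 0.5)
  e <- c(0.2 * 1.4, 0.3 * 1.4, 0.5 * 0.2 / 0.26)
  e <- e / sum(e)
  # units 1 and 2 share the ratio; merge them
  p2 <- c(0.5, 0.5); e2 <- c(e[1] + e[2], e[3])
  expect_equal(theil_total(p, e), theil_total(p2, e2), tolerance = 1e-12)

  expect_error(theil_total(c(0.5, 0.5), c(1, 0)),
               class = "hera_divergence_error")
  expect_equal(theil_total(c(0.5, 0.5), c(0.25, 0.75), "base10"),
               theil_total(c(0.5, 0.5), c(0.25, 0.75)) / log(10))
})

test_that("Theil decomposition: single group, identity, contribution rates", {
  p <- c(0.2, 0.3, 0.5); e <- c(0.1, 0.4, 0.5)
  td1 <- theil_decompose(p, e, rep("all", 3))
  expect_equal(td1$inter, 0, tolerance = 1e-14)
  expect_equal(td1$intra, td1$total, tolerance = 1e-14)

  set.seed(10)
  for (rep in 1:25) {
    n <- sample(2:20, 1)
    g <- sample(letters[1:sample(1:5, 1)], n, replace = TRUE)
    p <- runif(n); p <- p / sum(p)
    e <- runif(n); e <- e / sum(e)
    td <- theil_decompose(p, e, g)
    expect_equal(td$total, theil_total(p, e), tolerance = 1e-10)
    expect_equal(td$intra + td$inter, td$total, tolerance = 1e-10)
    if (td$total > 0)
      expect_equal(td$contribution_intra + td$contribution_inter, 1,
                   tolerance = 1e-10)
    expect_equal(sum(td$per_group$p), 1, tolerance = 1e-12)
    expect_equal(sum(td$per_group$e), 1, tolerance = 1e-12)
  }
})

test_that("Theil is zero iff allocation is proportional to the basis", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    p <- runif(n); p <- p / sum(p)
    expect_equal(theil_total(p, p), 0, tolerance = 1e-14)
    e <- runif(n); e <- e / sum(e)
    if (max(abs(e - p)) > 1e-6) expect_gt(theil_total(p, e), 0)
  }
})

test_that("HRDI follows the geometric-mean form and its scaling law", {
  expect_equal(hrdi(1, 1, 1), 1)
  expect_equal(hrdi(10, 4, 9), 10 / 6)
  expect_equal(hrdi(10, 8, 18), 10 / 12)   # doubling A and P halves it

  expect_error(hrdi(1, 0, 1), class = "hera_validation_error")
  expect_error(hrdi(-1, 1, 1), class = "hera_validation_error")

  # merged region uses summed HR, A, P -- not the mean of member HRDIs
  hr <- c(1, 50); a <- c(1, 100); p <- c(1, 4)
  merged <- hrdi(sum(hr), sum(a), sum(p))
  expect_false(isTRUE(all.equal(merged, mean(hrdi(hr, a, p)))))
})

test_that("panel-level equity tables are consistent with the scalar functions", {
  p <- toy_panel(beds = c(10, 30, 20, 80))
  gt <- gini_table(p, "beds")
  sl <- p[p$year == 2014, ]
  expect_equal(gt$gini[gt$year == 2014 & gt$basis == "population"],
               gini(sl$beds, sl$population_thousand, sl$city))

  tt <- theil_table(p, "beds", "population")
  td <- theil_decompose(sl$population_thousand / sum(sl$population_thousand),
                        sl$beds / sum(sl$beds), sl$region)
  expect_equal(tt$totals$theil[tt$totals$year == 2014], td$total)
  expect_equal(tt$totals$contrib_intra_pct[tt$totals$year == 2014],
               100 * td$contribution_intra)

  ht <- hrdi_table(p, "beds", by = "region")
  s2014 <- ht[ht$year == 2014 & ht$unit == "s", "hrdi"]
  expect_equal(s2014, hrdi(sum(sl$beds[sl$region == "s"]),
                           sum(sl$area_km2[sl$region == "s"]),
                           sum(sl$population_thousand[sl$region == "s"])))
})
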