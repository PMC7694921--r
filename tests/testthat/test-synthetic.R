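test_that("generation is deterministic given the seed", {
  p1 <- generate_panel(panel_gen_config(seed = 5))
  p2 <- generate_panel(panel_gen_config(seed = 5))
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- generate_panel(panel_gen_config(seed = 6))
  expect_false(identical(p1$beds, p3$beds))
})

test_that("equal multipliers with zero dispersion produce perfect equality", {
  cfg <- panel_gen_config(seed = 5, year_jitter_sd = 0)
  cfg$cv[] <- 0
  for (r in names(cfg$multipliers)) cfg$multipliers[[r]][] <- 1
  p <- generate_panel(cfg)
  sl <- p[p$year == 2014, ]
  for (r in c("institutions", "beds", "gov_subsidy_bn")) {
    expect_equal(gini(sl[[r]], sl$population_thousand), 0, tolerance = 1e-12)
    expect_equal(theil_total(sl$population_thousand / sum(sl$population_thousand),
                             sl[[r]] / sum(sl[[r]])), 0, tolerance = 1e-12)
  }
})

test_that("generated panels validate and sit in the intended inequality regime", {
  interc <- ginst <- numeric(10)
  for (s in 1:10) {
    p <- generate_panel(panel_gen_config(seed = 100 + s))
    expect_s3_class(p, "resource_panel")      # construction implies validation
    sl <- p[p$year == 2014, ]
    td <- theil_decompose(sl$population_thousand / sum(sl$population_thousand),
                          sl$beds / sum(sl$beds), sl$region)
    interc[s] <- td$contribution_inter
    ginst[s] <- gini(sl$institutions, sl$population_thousand)
  }
  expect_gt(mean(interc), 0.5)    # beds inequality mostly inter-regional
  expect_lt(mean(ginst), 0.15)    # institutions near population-proportional
})

test_that("raising a region's multiplier weakly raises its HRDI for that resource", {
  cfg1 <- panel_gen_config(seed = 9)
  cfg2 <- panel_gen_config(seed = 9)
  cfg2$multipliers$beds["south"] <- cfg2$multipliers$beds["south"] * 1.5
  h1 <- hrdi_table(generate_panel(cfg1), "beds", by = "region")
  h2 <- hrdi_table(generate_panel(cfg2), "beds", by = "region")
  s1 <- h1$hrdi[h1$unit == "south"]
  s2 <- h2$hrdi[h2$unit == "south"]
  expect_true(all(s2 >= s1))
})

test_that("a noiseless frontier panel is fully efficient and hides no truth", {
  fp <- generate_frontier_panel(frontier_gen_config(sigma_u = 0, seed = 3),
                                panel_gen_config(seed = 3))
  expect_equal(fp$truth$true_efficiency, rep(1, nrow(fp$truth)))
  eff <- dea_efficiency(fp$panel, 2016, fp$model)
  expect_equal(eff$scores$pte, rep(1, 13), tolerance = 1e-7)
  expect_equal(eff$scores$te, rep(1, 13), tolerance = 1e-7)
})

test_that("DEA scores over-estimate true efficiency at small n", {
  # the frontier is estimated from the best peers, so estimated scores are
  # upward-biased for the true (drawn) efficiencies
  diffs <- sapply(1:8, function(s) {
    fp <- generate_frontier_panel(frontier_gen_config(sigma_u = 0.15, seed = s),
                                  panel_gen_config(seed = 300 + s))
    eff <- dea_efficiency(fp$panel, 2014, fp$model)
    tr <- fp$truth[fp$truth$year == 2014, ]
    mean(eff$scores$te[match(tr$city, eff$scores$city)]) -
      mean(tr$true_efficiency)
  })
  expect_gte(mean(diffs), -0.01)
})

test_that("generator configs reject invalid parameters", {
  expect_error(panel_gen_config(seed = 1, year_jitter_sd = -1),
               class = "hera_validation_error")
  cfg <- panel_gen_config()
  cfg$multipliers$beds["south"] <- -2
  expect_error(do.call(panel_gen_config,
                       list(multipliers = cfg$multipliers)),
               class = "hera_validation_error")
  expect_error(frontier_gen_config(g = 0), class = "hera_validation_error")
  expect_error(frontier_gen_config(sigma_u = -0.1),
               class = "hera_validation_error")
})
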