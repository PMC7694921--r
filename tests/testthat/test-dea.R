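test_that("single DMU is efficient under both returns-to-scale assumptions", {
  X <- matrix(2); Y <- matrix(3)
  expect_equal(solve_envelopment(1, X, Y, "crs")$theta, 1, tolerance = 1e-9)
  expect_equal(solve_envelopment(1, X, Y, "vrs")$theta, 1, tolerance = 1e-9)
})

test_that("three-DMU frontier reproduces the enumerated CRS/VRS scores", {
  X <- matrix(c(2, 4, 1), 3, 1, dimnames = list(c("A", "B", "C"), "x"))
  Y <- matrix(c(4, 4, 1), 3, 1, dimnames = list(c("A", "B", "C"), "y"))
  crs <- sapply(1:3, function(j) solve_envelopment(j, X, Y, "crs")$theta)
  vrs <- sapply(1:3, function(j) solve_envelopment(j, X, Y, "vrs")$theta)
  expect_equal(crs, c(1, 0.5, 0.5), tolerance = 1e-9)
  expect_equal(vrs, c(1, 0.5, 1), tolerance = 1e-9)
  # VRS lambdas sum to one
  lam <- solve_envelopment(2, X, Y, "vrs")$lambda
  expect_equal(sum(lam), 1, tolerance = 1e-9)
})

test_that("scores are invariant to input/output units", {
  set.seed(21)
  X <- matrix(runif(10, 1, 5), 5, 2)
  Y <- matrix(runif(10, 1, 5), 5, 2)
  th <- sapply(1:5, function(j) solve_envelopment(j, X, Y, "crs")$theta)
  X2 <- X; X2[, 1] <- X2[, 1] * 1000
  Y2 <- Y; Y2[, 2] <- Y2[, 2] / 500
  th2 <- sapply(1:5, function(j) solve_envelopment(j, X2, Y2, "crs")$theta)
  expect_equal(th, th2, tolerance = 1e-9)
})

test_that("CRS scores match the best-ratio closed form on 1x1 instances", {
  set.seed(22)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    x <- runif(n, 0.2, 5); y <- runif(n, 0.2, 5)
    oracle <- crs_ratio_oracle(x, y)
    for (j in seq_len(n)) {
      th <- solve_envelopment(j, matrix(x), matrix(y), "crs")$theta
      expect_equal(th, oracle[j], tolerance = 1e-9)
      expect_lte(th,
                 solve_envelopment(j, matrix(x), matrix(y), "vrs")$theta + 1e-9)
    }
  }
})

test_that("radially efficient but mix-inefficient DMU shows a positive slack", {
  X <- rbind(c(1, 2), c(2, 1), c(1, 3))
  Y <- matrix(1, 3, 1)
  th <- solve_envelopment(3, X, Y, "vrs")$theta
  expect_equal(th, 1, tolerance = 1e-9)
  sl <- max_slacks(3, th, X, Y, "vrs")
  expect_equal(unname(sl$input_slacks), c(0, 1), tolerance = 1e-7)
  # an efficient DMU has no slack at all
  sl1 <- max_slacks(1, 1, X, Y, "vrs")
  expect_equal(unname(sl1$input_slacks), c(0, 0), tolerance = 1e-7)
  expect_equal(unname(sl1$output_slacks), 0, tolerance = 1e-7)
})

test_that("slack solutions replay as feasible and slacks are non-negative", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(3:8, 1); m <- sample(1:3, 1); s <- sample(1:2, 1)
    X <- matrix(runif(n * m, 0.5, 5), n, m)
    Y <- matrix(runif(n * s, 0.5, 5), n, s)
    j <- sample(n, 1)
    rts <- sample(c("crs", "vrs"), 1)
    th <- solve_envelopment(j, X, Y, rts)$theta
    sl <- max_slacks(j, th, X, Y, rts)
    lam <- unname(sl$lambda)
    expect_true(all(sl$input_slacks >= -1e-9))
    expect_true(all(sl$output_slacks >= -1e-9))
    expect_equal(as.numeric(t(X) %*% lam + sl$input_slacks),
                 as.numeric(th * X[j, ]), tolerance = 1e-6)
    expect_equal(as.numeric(t(Y) %*% lam - sl$output_slacks),
                 as.numeric(Y[j, ]), tolerance = 1e-6)
    if (rts == "vrs") expect_equal(sum(lam), 1, tolerance = 1e-7)
  }
})

test_that("frontier-level invariants: TE <= PTE, someone efficient, duplicates harmless", {
  set.seed(24)
  X <- matrix(runif(16, 1, 5), 8, 2)
  Y <- matrix(runif(8, 1, 5), 8, 1)
  crs <- sapply(1:8, function(j) solve_envelopment(j, X, Y, "crs")$theta)
  vrs <- sapply(1:8, function(j) solve_envelopment(j, X, Y, "vrs")$theta)
  expect_true(all(crs <= vrs + 1e-9))
  expect_gte(max(vrs), 1 - 1e-9)
  # exact duplicate of a DMU changes no score
  Xd <- rbind(X, X[3, ]); Yd <- rbind(Y, Y[3, , drop = FALSE])
  crs_d <- sapply(1:8, function(j) solve_envelopment(j, Xd, Yd, "crs")$theta)
  expect_equal(crs_d, crs, tolerance = 1e-9)
  # worsening an inefficient DMU's input never raises its score
  j <- which.min(crs)
  Xw <- X; Xw[j, 1] <- Xw[j, 1] * 1.5
  expect_lte(solve_envelopment(j, Xw, Y, "crs")$theta, crs[j] + 1e-9)
})

test_that("dea_efficiency decomposes TE = PTE x SE with the published summary layout", {
  p <- toy_panel(cities = letters[1:5], regions = c("s", "s", "n", "n", "n"),
                 years = 2014,
                 population = c(10, 12, 8, 15, 9),
                 area = c(50, 60, 40, 80, 45),
                 beds = c(60, 80, 44, 100, 50),
                 outpatient_10k = c(9, 7, 5.3, 10, 5.6))
  eff <- dea_efficiency(p, 2014,
                        dea_model(inputs = "beds_per1000",
                                  outputs = "outpatient_10k"))
  expect_equal(eff$scores$se, eff$scores$te / eff$scores$pte,
               tolerance = 1e-12)
  expect_true(all(eff$scores$te <= eff$scores$pte + 1e-9))
  expect_equal(eff$summary$stat, c("mean", "max", "min"))
  expect_equal(eff$summary$te,
               c(mean(eff$scores$te), max(eff$scores$te), min(eff$scores$te)))
  # identical DMUs are all efficient
  pid <- toy_panel(cities = letters[1:4], regions = c("s", "s", "n", "n"),
                   years = 2014, population = rep(10, 4), area = rep(50, 4))
  eid <- dea_efficiency(pid, 2014,
                        dea_model(inputs = "beds_per1000",
                                  outputs = "outpatient_10k"))
  expect_equal(eid$scores$te, rep(1, 4), tolerance = 1e-9)
  expect_equal(eid$scores$pte, rep(1, 4), tolerance = 1e-9)
})

test_that("adjustment targets combine radial contraction and slacks correctly", {
  p <- toy_panel(cities = letters[1:5], regions = c("s", "s", "n", "n", "n"),
                 years = 2014,
                 population = c(10, 12, 8, 15, 9),
                 area = c(50, 60, 40, 80, 45),
                 beds = c(60, 96, 44, 100, 63),
                 health_workers = c(90, 100, 70, 140, 100),
                 outpatient_10k = c(9, 7, 5.3, 10, 5.6))
  model <- dea_model(inputs = c("beds_per1000", "health_workers_per1000"),
                     outputs = "outpatient_10k")
  eff <- dea_efficiency(p, 2014, model)
  adj <- dea_adjustments(eff)
  din <- as.matrix(adj[paste0("d_", model$inputs)])
  dout <- as.matrix(adj[paste0("d_", model$outputs)])
  expect_true(all(din <= 1e-9))
  expect_true(all(dout >= -1e-9))
  # formula replay: variation = (pte - 1) * x - slack
  expect_equal(unname(din),
               unname(sweep(eff$X, 1, eff$scores$pte - 1, "*") - eff$input_slacks),
               tolerance = 1e-9)
  # efficient, zero-slack DMUs emit all-zero rows
  zero_slack <- rowSums(eff$input_slacks) + rowSums(eff$output_slacks) < 1e-7
  effd <- eff$scores$pte > 1 - 1e-9 & zero_slack
  expect_true(any(effd))
  expect_true(all(abs(cbind(din, dout)[effd, ]) < 1e-9))
  # projected points are efficient when re-evaluated
  for (j in which(!effd)) {
    xs <- eff$scores$pte[j] * eff$X[j, ] - eff$input_slacks[j, ]
    ys <- eff$Y[j, ] + eff$output_slacks[j, ]
    th <- solve_envelopment(NULL, eff$X, eff$Y, "vrs", x0 = xs, y0 = ys)$theta
    expect_equal(th, 1, tolerance = 1e-6)
  }
})
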