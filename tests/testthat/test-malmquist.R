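test_that("radial distance reproduces hand-solved cases", {
  # unit on its own single-unit CRS frontier
  pd1 <- panel_dataset(data.frame(unit = "A", period = 1L, x = 1, y = 1),
                       inputs = "x", outputs = "y")
  expect_equal(radial_distance(pd1, "A", 1, 1, "CRS")$value, 1.0,
               tolerance = 1e-7)
  # frontier {(1,1)}, evaluated point (1,2): phi* = 1/2, D = 2
  pd2 <- panel_dataset(data.frame(unit = c("A", "A2"), period = c(1L, 2L),
                                  x = c(1, 1), y = c(1, 2)),
                       inputs = "x", outputs = "y")
  d <- radial_distance(pd2, "A2", 2, 1, "CRS")
  expect_equal(d$value, 2.0, tolerance = 1e-7)
  # cross-period VRS infeasibility: frontier unit has more input than the
  # evaluated point can cover with sum(lambda) = 1
  pd3 <- panel_dataset(data.frame(unit = c("F", "E"), period = c(1L, 2L),
                                  x = c(5, 1), y = c(1, 1)),
                       inputs = "x", outputs = "y")
  d3 <- radial_distance(pd3, "E", 2, 1, "VRS")
  expect_equal(d3$status, "infeasible")
})

test_that("radial distance matches brute-force phi search", {
  set.seed(2025)
  for (rep in 1:8) {
    inst <- random_instance(h = 0)
    o <- sample(inst$n, 1)
    d <- radial_distance(inst$pd, paste0("u", o), 1, 1, "CRS")
    phi <- bf_phi(inst$X[, o], inst$Y[, o], inst$X, inst$Y)
    expect_equal(d$value, 1 / phi, tolerance = 1e-4)
  }
})

test_that("contemporaneous CRS distances are <= 1 with one unit at 1", {
  set.seed(401)
  inst <- random_instance(n = 4, m = 2, q = 1, h = 0)
  vals <- sapply(paste0("u", 1:4), function(u)
    radial_distance(inst$pd, u, 1, 1, "CRS")$value)
  expect_true(all(vals <= 1 + 1e-7))
  expect_gt(max(vals), 1 - 1e-7)
})

test_that("identical periods give all Malmquist components equal to 1", {
  df <- data.frame(unit = rep(c("A", "B"), each = 2),
                   period = rep(1:2, 2),
                   x = c(1, 1, 2, 2), y = c(2, 2, 3, 3))
  pd <- panel_dataset(df, inputs = "x", outputs = "y")
  mal <- malmquist(pd)
  for (col in c("mi", "effch", "techch", "pech", "sech")) {
    expect_equal(mal[[col]], c(1, 1), tolerance = 1e-7)
  }
})

test_that("single-unit output doubling decomposes as pure frontier shift", {
  pd <- panel_dataset(data.frame(unit = "A", period = 1:2,
                                 x = c(1, 1), y = c(1, 2)),
                      inputs = "x", outputs = "y")
  mal <- malmquist_pair(pd, "A", 1, 2)
  expect_equal(mal$mi, 2, tolerance = 1e-7)
  expect_equal(mal$effch, 1, tolerance = 1e-7)
  expect_equal(mal$techch, 2, tolerance = 1e-7)
})

test_that("decomposition identities hold exactly and swap inverts mi", {
  set.seed(66)
  for (rep in 1:6) {
    n <- 3
    df <- data.frame(unit = rep(paste0("u", 1:n), each = 2),
                     period = rep(1:2, n),
                     x = runif(2 * n, 0.5, 3), y = runif(2 * n, 0.5, 3))
    pd <- panel_dataset(df, inputs = "x", outputs = "y")
    mal <- malmquist(pd)
    ok <- stats::complete.cases(mal[c("mi", "effch", "techch")])
    expect_equal(mal$mi[ok], (mal$effch * mal$techch)[ok],
                 tolerance = 1e-12)
    ok2 <- stats::complete.cases(mal[c("effch", "pech", "sech")])
    expect_equal(mal$effch[ok2], (mal$pech * mal$sech)[ok2],
                 tolerance = 1e-12)
    # period swap: relabel periods and invert
    df2 <- df; df2$period <- 3 - df$period
    pd2 <- panel_dataset(df2, inputs = "x", outputs = "y")
    mal2 <- malmquist(pd2)
    both <- !is.na(mal$mi) & !is.na(mal2$mi)
    expect_equal(mal2$mi[both], 1 / mal$mi[both], tolerance = 1e-7)
  }
})

test_that("scaling all outputs in the later period appears as techch", {
  c_shift <- 1.4
  pd <- panel_dataset(data.frame(unit = "A", period = 1:2,
                                 x = c(2, 2), y = c(3, 3 * c_shift)),
                      inputs = "x", outputs = "y")
  mal <- malmquist_pair(pd, "A", 1, 2)
  expect_equal(mal$techch, c_shift, tolerance = 1e-7)
  expect_equal(mal$effch, 1, tolerance = 1e-7)
})

test_that("summaries use geometric means and rank by mean mi", {
  res <- data.frame(unit = c("A", "A", "B", "B"),
                    from_period = c(1, 2, 1, 2), to_period = c(2, 3, 2, 3),
                    mi = c(2, 0.5, 1.2, 1.2),
                    effch = c(1, 1, 1.1, 1.1), techch = c(2, 0.5, 1.2, 1.2),
                    pech = c(1, 1, 1, 1), sech = c(1, 1, 1.1, 1.1),
                    n_infeasible = 0)
  s <- malmquist_summary(res, by = "unit")
  expect_equal(s$mi[s$unit == "A"], 1.0, tolerance = 1e-12)
  expect_equal(s$mi[s$unit == "B"], 1.2, tolerance = 1e-12)
  expect_equal(s$rank[s$unit == "B"], 1L)
  expect_equal(s$rank[s$unit == "A"], 2L)
  g <- malmquist_summary(res, by = "group",
                         grouping = c(A = "G1", B = "G2"))
  expect_equal(g$mi[g$group == "All"], exp(mean(log(res$mi))),
               tolerance = 1e-12)
  expect_error(malmquist_summary(res, by = "group",
                                 grouping = c(A = "G1")), "B")
})
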