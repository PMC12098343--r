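# Analytic fixtures: values derived by hand from the fractional programs
# (and re-checkable with the brute-force oracle in helper-oracles.R).

test_that("standard SBM matches the analytic two-unit solution", {
  pd <- two_unit_panel()
  a <- solve_sbm_standard(pd, "A", 1)
  b <- solve_sbm_standard(pd, "B", 1)
  expect_equal(a$score, 1.0, tolerance = 1e-7)
  expect_equal(b$score, 0.5, tolerance = 1e-7)
  expect_equal(a$stage, "standard")
  # score 1 comes with zero slacks, sub-unity score with positive slack
  expect_lt(max(abs(c(a$s_minus, a$s_plus))), 1e-7)
  expect_gt(sum(b$s_minus) + sum(b$s_plus), 1e-3)
})

test_that("undesirable output enters the standard score as derived", {
  pd <- panel_dataset(data.frame(unit = c("P", "Q"), period = 1L,
                                 x = c(1, 1), y = c(1, 1), b = c(1, 2)),
                      inputs = "x", outputs = "y", bads = "b")
  q <- solve_sbm_standard(pd, "Q", 1)
  expect_equal(q$score, 0.8, tolerance = 1e-7)
  expect_equal(solve_sbm_standard(pd, "P", 1)$score, 1.0, tolerance = 1e-7)
  # dropping the bad removes the penalty
  q2 <- solve_sbm_standard(pd, "Q", 1,
                           dea_options(undesirable_mode = "none"))
  expect_equal(q2$score, 1.0, tolerance = 1e-7)
})

test_that("super-efficiency matches the analytic value and edge cases", {
  pd <- two_unit_panel()
  a <- solve_sbm_super(pd, "A", 1)
  expect_equal(a$score, 2.0, tolerance = 1e-7)
  # identical DMUs: zero-slack reference exists, score 1
  pd2 <- panel_dataset(data.frame(unit = c("A", "B"), period = 1L,
                                  x = c(1, 1), y = c(1, 1)),
                       inputs = "x", outputs = "y")
  expect_equal(solve_sbm_super(pd2, "A", 1)$score, 1.0, tolerance = 1e-7)
  # single DMU: empty reference set
  pd1 <- panel_dataset(data.frame(unit = "A", period = 1L, x = 1, y = 1),
                       inputs = "x", outputs = "y")
  expect_equal(solve_sbm_super(pd1, "A", 1)$status, "infeasible")
})

test_that("two-stage protocol routes frontier units to the super stage", {
  pd <- two_unit_panel()
  a <- efficiency_score(pd, "A", 1)
  b <- efficiency_score(pd, "B", 1)
  expect_equal(a$score, 2.0, tolerance = 1e-7)
  expect_equal(a$stage, "super")
  expect_equal(b$score, 0.5, tolerance = 1e-7)
  expect_equal(b$stage, "standard")
  # all-identical units: every score 1
  pd3 <- panel_dataset(data.frame(unit = c("A", "B", "C"), period = 1L,
                                  x = 1, y = 1),
                       inputs = "x", outputs = "y")
  sc <- efficiency_batch(pd3)
  expect_equal(sc$score, rep(1, 3), tolerance = 1e-7)
})

test_that("scale decomposition matches the analytic CRS/VRS split", {
  pd <- panel_dataset(data.frame(unit = c("A", "B"), period = 1L,
                                 x = c(1, 2), y = c(1, 4)),
                      inputs = "x", outputs = "y")
  # textbook standard-stage decomposition: VRS convexity forces
  # lambda_A = 1 so vrste(A) = 1; CRS analytic value 0.5
  dec <- decompose_scale(pd, stage = "standard")
  a <- dec[dec$unit == "A", ]
  expect_equal(a$crste, 0.5, tolerance = 1e-7)
  expect_equal(a$vrste, 1.0, tolerance = 1e-6)
  expect_equal(a$scale, 0.5, tolerance = 1e-6)
  # two-stage protocol re-scores the VRS-efficient unit with the
  # super-efficiency program: sigma_VRS(A) = 2 (oracle-derived), so the
  # published-table form reports vrste above 1 for frontier units
  dec2s <- decompose_scale(pd)
  a2 <- dec2s[dec2s$unit == "A", ]
  expect_equal(a2$crste, 0.5, tolerance = 1e-7)
  expect_equal(a2$vrste, 2.0, tolerance = 1e-6)
  # doubling a frontier vertex keeps both on the CRS and VRS frontiers
  pd2 <- panel_dataset(data.frame(unit = c("A", "B"), period = 1L,
                                  x = c(2, 4), y = c(4, 8)),
                       inputs = "x", outputs = "y")
  dec2 <- decompose_scale(pd2, stage = "standard")
  expect_true(all(abs(dec2$crste - 1) < 1e-7))
  expect_true(all(abs(dec2$scale - 1) < 1e-6))
})

test_that("crste <= vrste for standard-stage records", {
  set.seed(301)
  for (rep in 1:5) {
    inst <- random_instance(n = 4, m = 2, q = 1, h = 0)
    crs <- efficiency_batch(inst$pd, dea_options(rts = "CRS"))
    vrs <- efficiency_batch(inst$pd, dea_options(rts = "VRS"))
    both_std <- crs$stage == "standard" & vrs$stage == "standard"
    expect_true(all(crs$score[both_std] <= vrs$score[both_std] + 1e-6))
  }
})

test_that("LP scores match the brute-force fractional minimizer", {
  set.seed(1234)
  n_checked <- 0
  for (rep in 1:12) {
    inst <- random_instance()
    o <- sample(inst$n, 1)
    xo <- inst$X[, o]; yo <- inst$Y[, o]
    bo <- if (inst$h > 0) inst$B[, o] else numeric(0)
    res <- solve_sbm_standard(inst$pd, paste0("u", o), 1)
    st <- numeric(inst$n); st[o] <- 1
    bf <- bf_sbm(xo, yo, bo, inst$X, inst$Y, inst$B, start = st)
    expect_equal(res$score, bf, tolerance = 1e-4)
    sup <- solve_sbm_super(inst$pd, paste0("u", o), 1)
    bfs <- bf_sbm(xo, yo, bo,
                  inst$X[, -o, drop = FALSE], inst$Y[, -o, drop = FALSE],
                  inst$B[, -o, drop = FALSE], super = TRUE)
    if (!is.na(sup$score) && !is.na(bfs)) {
      expect_equal(sup$score, bfs, tolerance = 1e-4)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 5)
})

test_that("scores are invariant to rescaling any single column", {
  set.seed(55)
  inst <- random_instance(n = 4, m = 2, q = 1, h = 1)
  base <- efficiency_batch(inst$pd)
  df <- as.data.frame(inst$pd)
  for (col in c("x2", "y1", "b1")) {
    df2 <- df
    df2[[col]] <- df2[[col]] * 1000
    pd2 <- panel_dataset(df2, inputs = c("x1", "x2"), outputs = "y1",
                         bads = "b1")
    again <- efficiency_batch(pd2)
    expect_equal(again$score, base$score, tolerance = 1e-8)
  }
})

test_that("appending a dominating DMU cannot raise a standard score", {
  set.seed(77)
  for (rep in 1:5) {
    inst <- random_instance(n = 3, m = 1, q = 1, h = 0)
    df <- as.data.frame(inst$pd)
    o <- sample(3, 1)
    before <- solve_sbm_standard(inst$pd, paste0("u", o), 1)$score
    dom <- df[df$unit == paste0("u", o), ]
    dom$unit <- "udom"
    dom$x1 <- dom$x1 * 0.8
    dom$y1 <- dom$y1 * 1.2
    pd2 <- panel_dataset(rbind(df, dom), inputs = "x1", outputs = "y1")
    after <- solve_sbm_standard(pd2, paste0("u", o), 1)$score
    expect_lte(after, before + 1e-7)
  }
})

test_that("standard score is 1 exactly when all optimal slacks vanish", {
  set.seed(91)
  for (rep in 1:6) {
    inst <- random_instance(n = 4, m = 2, q = 1, h = 0)
    for (u in paste0("u", 1:4)) {
      res <- solve_sbm_standard(inst$pd, u, 1)
      total_slack <- sum(res$s_minus) + sum(res$s_plus) +
        sum(res$s_bad)
      if (res$score == 1) {
        expect_lt(total_slack, 1e-6)
      } else {
        expect_gt(total_slack, 1e-8)
      }
    }
  }
})

test_that("standard CRS SBM never exceeds the radial CRS efficiency", {
  set.seed(131)
  for (rep in 1:6) {
    inst <- random_instance(n = 4, m = 2, q = 1, h = 0)
    for (u in paste0("u", 1:4)) {
      sbm <- solve_sbm_standard(inst$pd, u, 1)$score
      # input-oriented radial efficiency from the malmquist module
      rad <- radial_distance(inst$pd, u, 1, 1, "CRS",
                             orientation = "input")$value
      expect_lte(sbm, rad + 1e-6)
    }
  }
})

test_that("VRS lambda weights sum to one at the optimum", {
  set.seed(151)
  inst <- random_instance(n = 4, m = 2, q = 1, h = 0)
  for (u in paste0("u", 1:4)) {
    res <- solve_sbm_standard(inst$pd, u, 1, dea_options(rts = "VRS"))
    expect_equal(sum(res$lambda), 1, tolerance = 1e-6)
    expect_true(all(res$lambda >= -1e-9))
    expect_true(all(c(res$s_minus, res$s_plus) >= -1e-9))
  }
})
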