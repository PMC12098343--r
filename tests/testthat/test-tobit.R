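sim_tobit_data <- function(n, beta = c(1, 2), sigma = 1, censor_at = 0) {
  z <- rnorm(n)
  ystar <- beta[1] + beta[2] * z + rnorm(n, 0, sigma)
  y <- pmax(ystar, censor_at)
  list(y = y, X = matrix(z, ncol = 1, dimnames = list(NULL, "z")))
}

test_that("uncensored Tobit coincides with least squares", {
  set.seed(10)
  d <- sim_tobit_data(400, beta = c(5, 2), censor_at = -Inf)
  fit <- fit_tobit_pooled(d$y, d$X, censor_spec(lower = -Inf))
  ols <- lm(d$y ~ d$X)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-4)
  expect_equal(fit$n_censored, 0)
})

test_that("pooled fit agrees with the survreg censored-gaussian oracle", {
  set.seed(21)
  d <- sim_tobit_data(600, beta = c(0.5, 1.5), sigma = 1)
  fit <- fit_tobit_pooled(d$y, d$X)
  sr <- survival::survreg(
    survival::Surv(d$y, d$y > 0, type = "left") ~ d$X,
    dist = "gaussian")
  expect_equal(unname(fit$beta), unname(coef(sr)), tolerance = 1e-4)
  expect_equal(fit$sigma_e, sr$scale, tolerance = 1e-3)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(sr))[1:2])),
               tolerance = 1e-2)
  expect_gt(fit$n_censored, 0)
})

test_that("pooled MLE recovers known truth within Monte-Carlo error", {
  set.seed(33)
  d <- sim_tobit_data(2000, beta = c(1, 2), sigma = 1)
  fit <- fit_tobit_pooled(d$y, d$X)
  expect_lt(abs(fit$beta[1] - 1) / fit$se[1], 3)
  expect_lt(abs(fit$beta[2] - 2) / fit$se[2], 3)
})

test_that("degenerate all-censored input raises an estimation error", {
  expect_error(fit_tobit_pooled(rep(0, 50), matrix(rnorm(50))),
               "censored")
})

test_that("likelihood is non-decreasing over accepted iterations", {
  set.seed(44)
  d <- sim_tobit_data(300)
  fit <- fit_tobit_pooled(d$y, d$X)
  # the trace records every evaluation; the running maximum at the end
  # must equal the final loglik, and the fit must improve on the start
  expect_equal(max(fit$trace), fit$loglik, tolerance = 1e-8)
  expect_gte(fit$loglik, fit$trace[1])
})

test_that("covariate rescaling rescales beta and leaves z, p, Wald alone", {
  set.seed(55)
  d <- sim_tobit_data(500)
  f1 <- fit_tobit_pooled(d$y, d$X)
  f2 <- fit_tobit_pooled(d$y, d$X * 100)
  expect_equal(f2$beta[["z"]], f1$beta[["z"]] / 100, tolerance = 1e-6)
  expect_equal(f2$z[["z"]], f1$z[["z"]], tolerance = 1e-6)
  w1 <- wald_test(f1); w2 <- wald_test(f2)
  expect_equal(w1$chi2, w2$chi2, tolerance = 1e-6)
})

test_that("random-effects fit collapses to pooled when sigma_u = 0", {
  set.seed(66)
  n_unit <- 60; T_per <- 4
  id <- rep(seq_len(n_unit), each = T_per)
  z <- rnorm(n_unit * T_per)
  y <- pmax(0.5 + 1.0 * z + rnorm(n_unit * T_per, 0, 0.8), 0)
  X <- matrix(z, ncol = 1, dimnames = list(NULL, "z"))
  re <- fit_tobit_re(y, X, id, quad_nodes = 12)
  po <- fit_tobit_pooled(y, X)
  expect_lt(re$sigma_u, 0.05)
  expect_equal(unname(re$beta), unname(po$beta), tolerance = 1e-3)
})

test_that("random-effects fit recovers known panel truth", {
  set.seed(77)
  n_unit <- 150; T_per <- 5
  id <- rep(seq_len(n_unit), each = T_per)
  u <- rnorm(n_unit, 0, 0.3)[id]
  z <- rnorm(n_unit * T_per)
  y <- pmax(0.3 + 0.8 * z + u + rnorm(n_unit * T_per, 0, 0.5), 0)
  X <- matrix(z, ncol = 1, dimnames = list(NULL, "z"))
  fit <- fit_tobit_re(y, X, id)
  expect_lt(abs(fit$beta[["z"]] - 0.8) / fit$se[["z"]], 3)
  expect_equal(fit$sigma_u, 0.3, tolerance = 0.25)
  expect_equal(fit$sigma_e, 0.5, tolerance = 0.15)
})

test_that("single period per unit reports sigma_u as unidentified", {
  set.seed(88)
  d <- sim_tobit_data(200)
  fit <- fit_tobit_re(d$y, d$X, id = seq_along(d$y))
  expect_false(fit$sigma_u_identified)
  po <- fit_tobit_pooled(d$y, d$X)
  expect_equal(unname(fit$beta), unname(po$beta), tolerance = 5e-3)
})

test_that("doubling quadrature nodes barely moves the loglik", {
  set.seed(99)
  n_unit <- 40; T_per <- 4
  id <- rep(seq_len(n_unit), each = T_per)
  u <- rnorm(n_unit, 0, 0.2)[id]
  z <- rnorm(n_unit * T_per)
  y <- pmax(0.5 + 0.6 * z + u + rnorm(n_unit * T_per, 0, 0.4), 0)
  X <- matrix(z, ncol = 1, dimnames = list(NULL, "z"))
  f12 <- fit_tobit_re(y, X, id, quad_nodes = 12)
  f24 <- fit_tobit_re(y, X, id, quad_nodes = 24)
  expect_lt(abs(f12$loglik - f24$loglik), 1e-3)
})

test_that("Wald machinery: single slope equals z^2, df bookkeeping", {
  set.seed(111)
  z2 <- rnorm(500)
  d <- sim_tobit_data(500)
  X <- cbind(d$X, z2 = z2)
  fit <- fit_tobit_pooled(d$y, X)
  w1 <- wald_test(fit, "z")
  expect_equal(w1$chi2, fit$z[["z"]]^2, tolerance = 1e-8)
  expect_equal(w1$df, 1)
  wall <- wald_test(fit)
  expect_equal(wall$df, 2)
})

test_that("z-test keeps its nominal size on a null covariate", {
  set.seed(222)
  reps <- 60
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    null_z <- rnorm(150)
    d <- sim_tobit_data(150)
    X <- cbind(d$X, nz = null_z)
    fit <- fit_tobit_pooled(d$y, X)
    rej[i] <- fit$p[["nz"]] < 0.05
  }
  # within 3 binomial SEs of 5%
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 1e-9)
})

test_that("regression table carries stars and the joint Wald statistic", {
  set.seed(333)
  d <- sim_tobit_data(400, beta = c(1, 2))
  tab <- tobit_table(fit_tobit_pooled(d$y, d$X))
  expect_named(tab, c("variable", "coefficient", "std_error", "z", "p",
                      "signif"))
  expect_equal(tab$signif[tab$variable == "z"], "***")
  expect_true(is.finite(attr(tab, "wald_chi2")))
})
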