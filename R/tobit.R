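# Censored-normal (Tobit) likelihoods, pooled and with unit-level random
# effects integrated by Gauss-Hermite quadrature.

#' Censoring bounds for a Tobit fit
#'
#' Default: lower = 0, upper = +Inf. Efficiency scores from the
#' super-efficiency stage exceed 1, so no upper censoring is applied; the
#' lower bound reflects the non-negativity of efficiency values.
#'
#' @param lower lower censoring bound (may be `-Inf`).
#' @param upper upper censoring bound (may be `Inf`).
#' @return a list of class `censor_spec`.
#' @export
censor_spec <- function(lower = 0, upper = Inf) {
  stopifnot(lower < upper)
  structure(list(lower = lower, upper = upper), class = "censor_spec")
}

# log density/mass of one censored observation given mean mu, sd sigma
censored_loglik_obs <- function(y, mu, sigma, lower, upper) {
  ll <- numeric(length(y))
  at_low <- is.finite(lower) & y <= lower
  at_up <- is.finite(upper) & y >= upper
  mid <- !at_low & !at_up
  if (any(at_low)) {
    ll[at_low] <- stats::pnorm((lower - mu[at_low]) / sigma, log.p = TRUE)
  }
  if (any(at_up)) {
    ll[at_up] <- stats::pnorm((upper - mu[at_up]) / sigma, log.p = TRUE,
                              lower.tail = FALSE)
  }
  if (any(mid)) {
    ll[mid] <- stats::dnorm(y[mid], mu[mid], sigma, log = TRUE)
  }
  ll
}

prep_design <- function(y, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(X)) X <- matrix(numeric(0), length(y), 0)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    colnames(X) <- if (ncol(X) > 0) paste0("x", seq_len(ncol(X))) else
      character(0)
  }
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  sds <- if (ncol(X) > 0) apply(X, 2, stats::sd) else numeric(0)
  if (any(sds == 0)) {
    stop("constant covariate column supplied; the intercept is added ",
         "internally", call. = FALSE)
  }
  cbind(`_cons` = 1, X)
}

# Standardize the non-constant columns of a design (intercept first).
# Fitting on the standardized scale makes z, p and Wald statistics exactly
# invariant to covariate rescaling and conditions the optimizer; the
# Jacobian J maps standardized-scale coefficients (and their covariance)
# back: beta = J beta_std, V = J V_std J'.
std_design <- function(Xd) {
  k <- ncol(Xd)
  J <- diag(k)
  dimnames(J) <- list(colnames(Xd), colnames(Xd))
  if (k == 1) return(list(Xs = Xd, J = J))
  m <- colMeans(Xd[, -1, drop = FALSE])
  s <- apply(Xd[, -1, drop = FALSE], 2, stats::sd)
  Xs <- Xd
  Xs[, -1] <- sweep(sweep(Xd[, -1, drop = FALSE], 2, m), 2, s, `/`)
  J[1, -1] <- -m / s
  diag(J)[-1] <- 1 / s
  list(Xs = Xs, J = J)
}

tobit_fit_result <- function(beta, se, sigma_e, sigma_u, vcov, loglik,
                             n, n_censored, converged, iterations,
                             model, trace = NULL) {
  z <- ifelse(se > 0, beta / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  sigma_e <- unname(sigma_e); sigma_u <- unname(sigma_u)
  loglik <- unname(loglik)
  structure(list(beta = beta, se = se, z = z, p = p,
                 sigma_e = sigma_e, sigma_u = sigma_u, vcov = vcov,
                 loglik = loglik, n = n, n_censored = n_censored,
                 converged = converged, iterations = iterations,
                 model = model, trace = trace),
            class = "tobit_fit")
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat(sprintf("tobit_fit (%s): n = %d, %d censored, loglik = %.4f%s\n",
              x$model, x$n, x$n_censored, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(coef = x$beta, se = x$se, z = x$z, p = x$p)
  print(round(tab, 4))
  cat(sprintf("sigma_e = %.4f", x$sigma_e))
  if (x$model == "random_effects") cat(sprintf("  sigma_u = %.4f", x$sigma_u))
  cat("\n")
  invisible(x)
}

#' Pooled Tobit regression
#'
#' Maximum-likelihood fit of the censored-normal model
#' \eqn{y^* = X\beta + \varepsilon}, \eqn{\varepsilon \sim N(0,\sigma_e^2)},
#' observed as `y = min(max(y*, lower), upper)`. Censored observations
#' contribute the normal tail mass, interior observations the density.
#' Standard errors come from the inverse observed information at the
#' optimum. With no censored observations the MLE coincides with least
#' squares. An intercept (`_cons`) is added internally.
#'
#' @param y numeric response vector.
#' @param X covariate matrix or data.frame (no constant column).
#' @param censor a [censor_spec()].
#' @param control list of optimizer settings: `maxit` (500) and `reltol`
#'   (1e-10; relative log-likelihood change).
#' @return a `tobit_fit` with coefficients, `sigma_e`, standard errors,
#'   z and p values, covariance, log-likelihood, censoring count and a
#'   convergence flag.
#' @export
fit_tobit_pooled <- function(y, X, censor = censor_spec(),
                             control = list()) {
  Xraw <- prep_design(y, X)
  sd_ <- std_design(Xraw)
  Xd <- sd_$Xs
  lower <- censor$lower; upper <- censor$upper
  n_cens <- sum((is.finite(lower) & y <= lower) |
                  (is.finite(upper) & y >= upper))
  if (n_cens == length(y)) {
    stop("estimation error: every observation is censored", call. = FALSE)
  }
  maxit <- control$maxit %||% 500
  reltol <- control$reltol %||% 1e-10
  # starting values: least squares on all rows, residual SD
  ls <- stats::lm.fit(Xd, y)
  sigma0 <- max(stats::sd(ls$residuals), 1e-3)
  par0 <- c(ls$coefficients, log(sigma0))
  k <- ncol(Xd)
  trace_env <- new.env(); trace_env$ll <- numeric(0)
  negll <- function(par) {
    mu <- drop(Xd %*% par[seq_len(k)])
    sigma <- exp(par[k + 1])
    v <- -sum(censored_loglik_obs(y, mu, sigma, lower, upper))
    if (!is.finite(v)) v <- 1e10
    trace_env$ll <- c(trace_env$ll, -v)
    v
  }
  neggrad <- function(par) {
    mu <- drop(Xd %*% par[seq_len(k)])
    sigma <- exp(par[k + 1])
    gmu <- gls <- numeric(length(y))
    at_low <- is.finite(lower) & y <= lower
    at_up <- is.finite(upper) & y >= upper
    mid <- !at_low & !at_up
    if (any(mid)) {
      r <- (y[mid] - mu[mid]) / sigma
      gmu[mid] <- r / sigma
      gls[mid] <- r^2 - 1
    }
    if (any(at_low)) {
      a <- (lower - mu[at_low]) / sigma
      mills <- exp(stats::dnorm(a, log = TRUE) -
                     stats::pnorm(a, log.p = TRUE))
      gmu[at_low] <- -mills / sigma
      gls[at_low] <- -a * mills
    }
    if (any(at_up)) {
      b <- (upper - mu[at_up]) / sigma
      mills <- exp(stats::dnorm(b, log = TRUE) -
                     stats::pnorm(b, log.p = TRUE, lower.tail = FALSE))
      gmu[at_up] <- mills / sigma
      gls[at_up] <- b * mills
    }
    -c(drop(crossprod(Xd, gmu)), sum(gls))
  }
  opt <- stats::optim(par0, negll, neggrad, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol),
                      hessian = TRUE)
  beta_s <- opt$par[seq_len(k)]
  beta <- drop(sd_$J %*% beta_s)
  names(beta) <- colnames(Xd)
  sigma_e <- exp(opt$par[k + 1])
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(vc)) {
    se <- rep(NA_real_, k); vcb <- matrix(NA_real_, k, k)
  } else {
    vcb <- sd_$J %*% vc[seq_len(k), seq_len(k), drop = FALSE] %*% t(sd_$J)
    se <- sqrt(pmax(diag(vcb), 0))
  }
  names(se) <- colnames(Xd)
  dimnames(vcb) <- list(colnames(Xd), colnames(Xd))
  tobit_fit_result(beta, se, sigma_e, 0, vcb, -opt$value,
                   length(y), n_cens, opt$convergence == 0,
                   opt$counts[1], "pooled", trace_env$ll)
}

#' Random-effects panel Tobit regression
#'
#' Adds a unit-level normal random effect: \eqn{y_{it}^* = x_{it}'\beta +
#' u_i + \varepsilon_{it}}, \eqn{u_i \sim N(0, \sigma_u^2)}. The per-unit
#' likelihood integrates the random effect with Gauss-Hermite quadrature
#' (`quad_nodes` points); the model reduces to the pooled fit as
#' \eqn{\sigma_u \to 0}, and with a single period per unit \eqn{\sigma_u}
#' is unidentified (reported, with slopes matching the pooled fit).
#'
#' @inheritParams fit_tobit_pooled
#' @param id unit identifier vector (length of `y`).
#' @param quad_nodes number of quadrature nodes (>= 4; default 12).
#' @return a `tobit_fit` with `model = "random_effects"` and a `sigma_u`
#'   estimate.
#' @export
fit_tobit_re <- function(y, X, id, censor = censor_spec(),
                         quad_nodes = 12, control = list()) {
  stopifnot(quad_nodes >= 4, length(id) == length(y))
  Xraw <- prep_design(y, X)
  sd_ <- std_design(Xraw)
  Xd <- sd_$Xs
  lower <- censor$lower; upper <- censor$upper
  n_cens <- sum((is.finite(lower) & y <= lower) |
                  (is.finite(upper) & y >= upper))
  if (n_cens == length(y)) {
    stop("estimation error: every observation is censored", call. = FALSE)
  }
  id <- as.character(id)
  uid <- unique(id)
  idx <- match(id, uid)
  gq <- statmod::gauss.quad(quad_nodes, kind = "hermite")
  maxit <- control$maxit %||% 500
  reltol <- control$reltol %||% 1e-10
  k <- ncol(Xd)
  ls <- stats::lm.fit(Xd, y)
  sigma0 <- max(stats::sd(ls$residuals), 1e-3)
  par0 <- c(ls$coefficients, log(sigma0), log(0.1 * sigma0))
  trace_env <- new.env(); trace_env$ll <- numeric(0)
  logw <- log(gq$weights) - 0.5 * log(pi)
  negll <- function(par) {
    mu <- drop(Xd %*% par[seq_len(k)])
    sigma_e <- exp(par[k + 1]); sigma_u <- exp(par[k + 2])
    # nodes matrix: units x quad points, via per-observation loglik sums
    lmat <- vapply(seq_len(quad_nodes), function(j) {
      u <- sqrt(2) * sigma_u * gq$nodes[j]
      ll <- censored_loglik_obs(y, mu + u, sigma_e, lower, upper)
      as.numeric(rowsum(ll, idx, reorder = FALSE))
    }, numeric(length(uid)))
    lmat <- sweep(lmat, 2, logw, `+`)
    mx <- apply(lmat, 1, max)
    if (any(!is.finite(mx))) return(1e10)
    v <- -sum(mx + log(rowSums(exp(lmat - mx))))
    if (!is.finite(v)) v <- 1e10
    trace_env$ll <- c(trace_env$ll, -v)
    v
  }
  opt <- stats::optim(par0, negll, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol),
                      hessian = TRUE)
  beta_s <- opt$par[seq_len(k)]
  beta <- drop(sd_$J %*% beta_s)
  names(beta) <- colnames(Xd)
  sigma_e <- exp(opt$par[k + 1])
  sigma_u <- exp(opt$par[k + 2])
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(vc)) {
    se <- rep(NA_real_, k); vcb <- matrix(NA_real_, k, k)
  } else {
    vcb <- sd_$J %*% vc[seq_len(k), seq_len(k), drop = FALSE] %*% t(sd_$J)
    se <- sqrt(pmax(diag(vcb), 0))
  }
  names(se) <- colnames(Xd)
  dimnames(vcb) <- list(colnames(Xd), colnames(Xd))
  fit <- tobit_fit_result(beta, se, sigma_e, sigma_u, vcb, -opt$value,
                          length(y), n_cens, opt$convergence == 0,
                          opt$counts[1], "random_effects", trace_env$ll)
  fit$sigma_u_identified <- any(duplicated(id))
  fit
}

#' Wald test of joint slope significance
#'
#' Computes \eqn{\chi^2 = b' V^{-1} b} over the selected coefficients,
#' compared to a chi-square reference with df equal to the number of
#' restrictions. Restricting a single slope gives exactly the square of
#' its z statistic. By default all slopes (everything except the
#' intercept) are tested, mirroring the usual joint regression test.
#'
#' @param fit a `tobit_fit`.
#' @param restriction character vector of coefficient names, or integer
#'   indices into `fit$beta`; default all non-intercept coefficients.
#' @return a list with `chi2`, `df`, `p`.
#' @export
wald_test <- function(fit, restriction = NULL) {
  stopifnot(inherits(fit, "tobit_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  nm <- names(fit$beta)
  if (is.null(restriction)) restriction <- setdiff(nm, "_cons")
  if (is.numeric(restriction)) restriction <- nm[restriction]
  stopifnot(all(restriction %in% nm))
  b <- fit$beta[restriction]
  V <- fit$vcov[restriction, restriction, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e) {
    stop("singular covariance in Wald test", call. = FALSE)
  })
  chi2 <- drop(t(b) %*% Vi %*% b)
  df <- length(restriction)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Regression table in the conventional published layout
#'
#' @param fit a `tobit_fit`.
#' @return a data.frame with variable, coefficient, standard error, z, p
#'   and significance stars (* p<0.1, ** p<0.05, *** p<0.01), with the
#'   joint Wald chi-square and its p-value as attributes.
#' @export
tobit_table <- function(fit) {
  stopifnot(inherits(fit, "tobit_fit"))
  stars <- cut(fit$p, c(-Inf, 0.01, 0.05, 0.1, Inf),
               labels = c("***", "**", "*", ""))
  out <- data.frame(variable = names(fit$beta),
                    coefficient = unname(fit$beta),
                    std_error = unname(fit$se),
                    z = unname(fit$z), p = unname(fit$p),
                    signif = as.character(stars),
                    stringsAsFactors = FALSE)
  w <- tryCatch(wald_test(fit), error = function(e) NULL)
  attr(out, "wald_chi2") <- if (is.null(w)) NA_real_ else w$chi2
  attr(out, "wald_df") <- if (is.null(w)) NA_integer_ else w$df
  attr(out, "wald_p") <- if (is.null(w)) NA_real_ else w$p
  out
}
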