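# Independent brute-force oracles for the LP-based models: dense random
# search over reference weights with local refinement, fully vectorized.
# These never touch the package's simplex path.

# Objective value of the (standard or super) SBM fractional program at a
# matrix of candidate weights L (rows = candidates). Infeasible rows -> NA.
sbm_obj_at <- function(L, xo, yo, bo, X, Y, B, super, vrs) {
  m <- length(xo); q <- length(yo); h <- length(bo)
  if (vrs) {
    rs <- rowSums(L)
    keep <- rs > 1e-12
    L[keep, ] <- L[keep, , drop = FALSE] / rs[keep]
    L[!keep, 1] <- NA
  }
  XR <- L %*% t(X); YR <- L %*% t(Y)
  BR <- if (h > 0) L %*% t(B) else NULL
  if (!super) {
    sm <- sweep(-XR, 2, xo, `+`)           # x_o - X lambda
    sp <- sweep(YR, 2, yo, `-`)            # Y lambda - y_o
    feas <- rowSums(sm < -1e-9) == 0 & rowSums(sp < -1e-9) == 0
    if (h > 0) {
      sb <- sweep(-BR, 2, bo, `+`)
      feas <- feas & rowSums(sb < -1e-9) == 0
    }
    num <- 1 - rowMeans(sweep(pmax(sm, 0), 2, xo, `/`))
    den <- 1 + rowSums(sweep(pmax(sp, 0), 2, yo, `/`)) / (q + h)
    if (h > 0) {
      den <- den + rowSums(sweep(pmax(sb, 0), 2, bo, `/`)) / (q + h)
    }
    val <- num / den
    val[!feas] <- NA
  } else {
    sm <- sweep(XR, 2, xo, `-`)            # X lambda - x_o
    sp <- sweep(-YR, 2, yo, `+`)           # y_o - Y lambda
    num <- 1 + rowMeans(sweep(pmax(sm, 0), 2, xo, `/`))
    den <- 1 - rowSums(sweep(pmax(sp, 0), 2, yo, `/`)) / (q + h)
    if (h > 0) {
      sb <- sweep(BR, 2, bo, `-`)
      den <- den - rowSums(sweep(pmax(sb, 0), 2, bo, `/`)) / (q + h)
    }
    val <- num / den
    val[den <= 1e-9] <- NA
  }
  val
}

# Brute-force minimizer of the SBM fractional program over lambda >= 0.
bf_sbm <- function(xo, yo, bo, X, Y, B, super = FALSE, vrs = FALSE,
                   start = NULL, n_grid = 20000, n_refine = 35) {
  n <- ncol(X)
  pts <- matrix(stats::runif(n_grid * n, 0, 3), ncol = n)
  if (!is.null(start)) pts <- rbind(matrix(start, 1), pts)
  vals <- sbm_obj_at(pts, xo, yo, bo, X, Y, B, super, vrs)
  if (all(is.na(vals))) return(NA_real_)
  best <- min(vals, na.rm = TRUE)
  bl <- pts[which.min(vals), ]
  for (rep in seq_len(n_refine)) {
    w <- 3 * 0.6^rep
    cand <- matrix(stats::rnorm(3000 * n, rep(bl, each = 3000), w),
                   ncol = n)
    cand[cand < 0] <- 0
    vals <- sbm_obj_at(cand, xo, yo, bo, X, Y, B, super, vrs)
    if (all(is.na(vals))) next
    i <- which.min(vals)
    if (vals[i] < best) { best <- vals[i]; bl <- cand[i, ] }
  }
  best
}

# Brute-force Farrell output-expansion factor: maximize over lambda >= 0
# the largest phi with X lambda <= x_o and Y lambda >= phi * y_o.
bf_phi <- function(xo, yo, X, Y, vrs = FALSE, n_grid = 20000,
                   n_refine = 35) {
  n <- ncol(X)
  phi_at <- function(L) {
    if (vrs) {
      rs <- rowSums(L); keep <- rs > 1e-12
      L[keep, ] <- L[keep, , drop = FALSE] / rs[keep]
      L[!keep, 1] <- NA
    }
    XR <- L %*% t(X); YR <- L %*% t(Y)
    feas <- rowSums(sweep(XR, 2, xo, `-`) > 1e-9) == 0
    phi <- apply(sweep(YR, 2, yo, `/`), 1, min)
    phi[!feas] <- NA
    phi
  }
  pts <- rbind(diag(n) * 0 + 0, matrix(stats::runif(n_grid * n, 0, 3),
                                       ncol = n))
  vals <- phi_at(pts)
  if (all(is.na(vals))) return(NA_real_)
  best <- max(vals, na.rm = TRUE)
  bl <- pts[which.max(vals), ]
  for (rep in seq_len(n_refine)) {
    w <- 3 * 0.6^rep
    cand <- matrix(stats::rnorm(3000 * n, rep(bl, each = 3000), w),
                   ncol = n)
    cand[cand < 0] <- 0
    vals <- phi_at(cand)
    if (all(is.na(vals))) next
    i <- which.max(vals)
    if (vals[i] > best) { best <- vals[i]; bl <- cand[i, ] }
  }
  best
}

# Random small DEA instance as a one-period panel_dataset plus matrices.
random_instance <- function(n = NULL, m = NULL, q = NULL, h = NULL) {
  n <- n %||% sample(2:4, 1)
  m <- m %||% sample(1:2, 1)
  q <- q %||% sample(1:2, 1)
  h <- h %||% sample(0:max(0, 3 - m - q), 1)
  X <- matrix(stats::runif(m * n, 0.5, 3), m)
  Y <- matrix(stats::runif(q * n, 0.5, 3), q)
  B <- if (h > 0) matrix(stats::runif(h * n, 0.5, 3), h) else
    matrix(0, 0, n)
  df <- data.frame(unit = paste0("u", seq_len(n)), period = 1L)
  for (i in seq_len(m)) df[[paste0("x", i)]] <- X[i, ]
  for (r in seq_len(q)) df[[paste0("y", r)]] <- Y[r, ]
  if (h > 0) for (k in seq_len(h)) df[[paste0("b", k)]] <- B[k, ]
  pd <- panel_dataset(df, inputs = paste0("x", seq_len(m)),
                      outputs = paste0("y", seq_len(q)),
                      bads = if (h > 0) paste0("b", seq_len(h)) else
                        character())
  list(pd = pd, X = X, Y = Y, B = B, n = n, m = m, q = q, h = h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny two-unit one-input/one-output panel used by several analytic cases:
# A(x=2, y=4) has the best ratio; B(x=4, y=4) is dominated.
two_unit_panel <- function() {
  panel_dataset(data.frame(unit = c("A", "B"), period = 1L,
                           x = c(2, 4), y = c(4, 4)),
                inputs = "x", outputs = "y")
}
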