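#' Options for the SBM efficiency models
#'
#' @param rts returns-to-scale assumption: `"CRS"` (constant) or `"VRS"`
#'   (variable; adds the convexity constraint sum(lambda) = 1).
#' @param frontier_scope `"contemporaneous"` (reference set = same-period
#'   DMUs; the default, so each year has its own frontier) or `"global"`
#'   (all unit-periods pooled into one frontier).
#' @param undesirable_mode `"eq1"` treats declared undesirable outputs with
#'   the bad-output slack constraints of the model; `"none"` drops them
#'   (sensitivity runs).
#' @param denominator_floor lower bound on the (linearized) fractional
#'   denominator, guarding against division blow-up in the super-efficiency
#'   program.
#' @param solver_tolerance tolerance used to snap scores to 1 (stabilizes
#'   the standard/super two-stage switch) and to check slack feasibility.
#' @return a list of class `dea_options`.
#' @export
dea_options <- function(rts = c("CRS", "VRS"),
                        frontier_scope = c("contemporaneous", "global"),
                        undesirable_mode = c("eq1", "none"),
                        denominator_floor = 1e-9,
                        solver_tolerance = 1e-6) {
  stopifnot(denominator_floor > 0, solver_tolerance > 0)
  structure(list(rts = match.arg(rts),
                 frontier_scope = match.arg(frontier_scope),
                 undesirable_mode = match.arg(undesirable_mode),
                 denominator_floor = denominator_floor,
                 solver_tolerance = solver_tolerance),
            class = "dea_options")
}

# Reference-set rows for an evaluated (unit, period).
reference_rows <- function(pd, unit, period, opts, exclude_self = FALSE) {
  r <- roles(pd)
  rows <- if (opts$frontier_scope == "contemporaneous") {
    which(pd[[r$period]] == period)
  } else {
    seq_len(nrow(pd))
  }
  if (exclude_self) {
    rows <- rows[!(pd[[r$unit]][rows] == unit & pd[[r$period]][rows] == period)]
  }
  rows
}

row_of <- function(pd, unit, period) {
  r <- roles(pd)
  i <- which(pd[[r$unit]] == unit & pd[[r$period]] == period)
  if (length(i) != 1) {
    stop("unit '", unit, "' not observed in period ", period, call. = FALSE)
  }
  i
}

# Solve min/max a'v subject to A1 v <= b1, A2 v >= b2, A3 v = b3, v >= 0,
# via the package's two-phase simplex (lp.R).
solve_lp <- function(obj, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                     A3 = NULL, b3 = NULL, maxi = FALSE) {
  out <- lp_simplex(obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                    A3 = A3, b3 = b3, maxi = maxi)
  list(value = out$value, soln = out$x,
       solved = if (out$status == "optimal") 1 else -1)
}

# Column scaling: SBM and the radial models are invariant to rescaling any
# input/output column; scaling by reference-set means conditions the LP.
scale_cols <- function(M, f) if (nrow(M) > 0) M / f else M
col_factors <- function(M) if (nrow(M) > 0) rowMeans(M) else numeric(0)

# Assemble and solve the standard SBM program (Charnes-Cooper linearized).
# Variables: t, Lambda (n_ref), S- (m), S+ (q), Sb (h); all >= 0.
# rho = t - (1/m) sum S-/x_o   with
#   t + 1/(q+h) (sum S+/y_o + sum Sb/b_o) = 1
#   x_o t = X Lambda + S-,  y_o t = Y Lambda - S+,  b_o t = B Lambda + Sb
#   VRS: sum Lambda = t
sbm_standard_lp <- function(xo, yo, bo, X, Y, B, vrs) {
  m <- length(xo); q <- length(yo); h <- length(bo); n <- ncol(X)
  nv <- 1 + n + m + q + h
  it <- 1; iL <- 1 + seq_len(n); iSm <- 1 + n + seq_len(m)
  iSp <- 1 + n + m + seq_len(q); iSb <- 1 + n + m + q + seq_len(h)
  obj <- numeric(nv); obj[it] <- 1; obj[iSm] <- -1 / (m * xo)
  A3 <- matrix(0, 1 + m + q + h + vrs, nv); b3 <- numeric(nrow(A3))
  A3[1, it] <- 1
  A3[1, iSp] <- 1 / ((q + h) * yo)
  if (h > 0) A3[1, iSb] <- 1 / ((q + h) * bo)
  b3[1] <- 1
  for (i in seq_len(m)) {
    A3[1 + i, it] <- xo[i]; A3[1 + i, iL] <- -X[i, ]; A3[1 + i, iSm[i]] <- -1
  }
  for (s in seq_len(q)) {
    A3[1 + m + s, it] <- yo[s]; A3[1 + m + s, iL] <- -Y[s, ]
    A3[1 + m + s, iSp[s]] <- 1
  }
  for (k in seq_len(h)) {
    A3[1 + m + q + k, it] <- bo[k]; A3[1 + m + q + k, iL] <- -B[k, ]
    A3[1 + m + q + k, iSb[k]] <- -1
  }
  if (vrs) {
    A3[nrow(A3), iL] <- 1; A3[nrow(A3), it] <- -1
  }
  out <- solve_lp(obj, A3 = A3, b3 = b3)
  tval <- out$soln[it]
  list(value = out$value, solved = out$solved, t = tval,
       lambda = out$soln[iL] / max(tval, .Machine$double.eps),
       s_minus = out$soln[iSm] / max(tval, .Machine$double.eps),
       s_plus = out$soln[iSp] / max(tval, .Machine$double.eps),
       s_bad = out$soln[iSb] / max(tval, .Machine$double.eps))
}

# Super-efficiency SBM program (evaluated DMU excluded from columns of
# X, Y, B). sigma = t + (1/m) sum S-/x_o with
#   t - 1/(q+h)(sum S+/y_o + sum Sb/b_o) = 1
#   X Lambda - S- <= x_o t,  y_o t <= Y Lambda + S+,  B Lambda - Sb <= b_o t
#   t <= 1/denominator_floor;  VRS: sum Lambda = t
sbm_super_lp <- function(xo, yo, bo, X, Y, B, vrs, tmax) {
  m <- length(xo); q <- length(yo); h <- length(bo); n <- ncol(X)
  nv <- 1 + n + m + q + h
  it <- 1; iL <- 1 + seq_len(n); iSm <- 1 + n + seq_len(m)
  iSp <- 1 + n + m + seq_len(q); iSb <- 1 + n + m + q + seq_len(h)
  obj <- numeric(nv); obj[it] <- 1; obj[iSm] <- 1 / (m * xo)
  norm <- numeric(nv); norm[it] <- 1
  norm[iSp] <- -1 / ((q + h) * yo)
  if (h > 0) norm[iSb] <- -1 / ((q + h) * bo)
  A3 <- rbind(norm); b3 <- 1
  if (vrs) {
    r <- numeric(nv); r[iL] <- 1; r[it] <- -1
    A3 <- rbind(A3, r); b3 <- c(b3, 0)
  }
  A1 <- matrix(0, m + q + h + 1, nv); b1 <- numeric(nrow(A1))
  for (i in seq_len(m)) {
    A1[i, iL] <- X[i, ]; A1[i, iSm[i]] <- -1; A1[i, it] <- -xo[i]
  }
  for (s in seq_len(q)) {
    A1[m + s, it] <- yo[s]; A1[m + s, iL] <- -Y[s, ]; A1[m + s, iSp[s]] <- -1
  }
  for (k in seq_len(h)) {
    A1[m + q + k, iL] <- B[k, ]; A1[m + q + k, iSb[k]] <- -1
    A1[m + q + k, it] <- -bo[k]
  }
  A1[m + q + h + 1, it] <- 1; b1[m + q + h + 1] <- tmax
  out <- solve_lp(obj, A1 = A1, b1 = b1, A3 = A3, b3 = b3)
  tval <- out$soln[it]
  list(value = out$value, solved = out$solved, t = tval,
       lambda = out$soln[iL] / max(tval, .Machine$double.eps),
       s_minus = out$soln[iSm] / max(tval, .Machine$double.eps),
       s_plus = out$soln[iSp] / max(tval, .Machine$double.eps),
       s_bad = out$soln[iSb] / max(tval, .Machine$double.eps))
}

efficiency_result <- function(unit, period, score, s_minus, s_plus, s_bad,
                              lambda, lambda_units, lambda_periods,
                              status, stage) {
  structure(list(unit = unit, period = period, score = score,
                 s_minus = s_minus, s_plus = s_plus, s_bad = s_bad,
                 lambda = lambda, lambda_units = lambda_units,
                 lambda_periods = lambda_periods,
                 status = status, stage = stage),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("efficiency_result: %s @ %d  score = %s  [%s, %s]\n",
              x$unit, x$period,
              if (is.na(x$score)) "NA" else formatC(x$score, digits = 4,
                                                    format = "f"),
              x$stage, x$status))
  invisible(x)
}

sbm_solve_one <- function(pd, unit, period, opts, super) {
  o <- row_of(pd, unit, period)
  ref <- reference_rows(pd, unit, period, opts, exclude_self = super)
  mo <- panel_matrices(pd, o)
  if (length(ref) == 0) {
    return(efficiency_result(unit, period, NA_real_,
                             rep(NA_real_, nrow(mo$X)),
                             rep(NA_real_, nrow(mo$Y)),
                             rep(NA_real_, nrow(mo$B)),
                             numeric(0), character(0), integer(0),
                             "infeasible", if (super) "super" else "standard"))
  }
  mr <- panel_matrices(pd, ref)
  use_bads <- opts$undesirable_mode == "eq1" && nrow(mr$B) > 0
  X <- mr$X; Y <- mr$Y; B <- if (use_bads) mr$B else matrix(0, 0, ncol(mr$X))
  xo <- drop(mo$X); yo <- drop(mo$Y)
  bo <- if (use_bads) drop(mo$B) else numeric(0)
  xo <- as.numeric(xo); yo <- as.numeric(yo); bo <- as.numeric(bo)
  # scale columns (units invariance holds exactly; this conditions the LP)
  fx <- col_factors(X); fy <- col_factors(Y); fb <- col_factors(B)
  Xs <- scale_cols(X, fx); Ys <- scale_cols(Y, fy); Bs <- scale_cols(B, fb)
  xos <- xo / fx; yos <- yo / fy
  bos <- if (length(bo) > 0) bo / fb else bo
  vrs <- opts$rts == "VRS"
  fit <- if (super) {
    sbm_super_lp(xos, yos, bos, Xs, Ys, Bs, vrs, 1 / opts$denominator_floor)
  } else {
    sbm_standard_lp(xos, yos, bos, Xs, Ys, Bs, vrs)
  }
  if (fit$solved != 1 || !is.finite(fit$value)) {
    return(efficiency_result(unit, period, NA_real_,
                             rep(NA_real_, length(xo)),
                             rep(NA_real_, length(yo)),
                             rep(NA_real_, length(bo)),
                             numeric(0), character(0), integer(0),
                             "infeasible", if (super) "super" else "standard"))
  }
  score <- fit$value
  tol <- opts$solver_tolerance
  if (abs(score - 1) < tol) score <- 1
  status <- if (fit$t <= opts$denominator_floor) "degenerate" else "optimal"
  # slacks back on the original data scale
  efficiency_result(unit, period, score,
                    fit$s_minus * fx, fit$s_plus * fy,
                    if (length(bo) > 0) fit$s_bad * fb else numeric(0),
                    fit$lambda, mr$unit, mr$period, status,
                    if (super) "super" else "standard")
}

#' Standard SBM efficiency with undesirable outputs
#'
#' Solves the non-oriented slacks-based-measure program for one evaluated
#' DMU against its reference set (which includes the DMU itself):
#' \deqn{\rho = \min \frac{1 - \frac1m \sum_i s_i^-/x_{io}}
#'   {1 + \frac{1}{q+h}(\sum_r s_r^+/y_{ro} + \sum_k s_k^b/b_{ko})}}
#' subject to \eqn{x_o = X\lambda + s^-}, \eqn{y_o = Y\lambda - s^+},
#' \eqn{b_o = B\lambda + s^b}, all slacks and weights nonnegative (plus
#' \eqn{\sum\lambda = 1} under VRS). The fractional program is linearized by
#' the Charnes-Cooper transformation and solved as an LP. The score lies in
#' (0, 1]; it equals 1 exactly when a zero-slack solution exists.
#'
#' @param data a [panel_dataset()].
#' @param unit,period the evaluated DMU.
#' @param opts a [dea_options()] list.
#' @return an `efficiency_result` with the score, optimal slacks, reference
#'   weights `lambda` and solver status.
#' @export
solve_sbm_standard <- function(data, unit, period, opts = dea_options()) {
  sbm_solve_one(data, unit, period, opts, super = FALSE)
}

#' Super-efficiency SBM with undesirable outputs
#'
#' Excludes the evaluated DMU from the reference set so that units on the
#' frontier receive discriminating scores greater than or equal to 1:
#' \deqn{\sigma^* = \min \frac{1 + \frac1m \sum_i s_i^-/x_{io}}
#'   {1 - \frac{1}{q+h}(\sum_r s_r^+/y_{ro} + \sum_k s_k^-/b_{ko})}}
#' subject to \eqn{x_o \ge X\lambda - s^-}, \eqn{y_o \le Y\lambda + s^+},
#' \eqn{b_o \ge B\lambda - s^-_b} over the remaining DMUs. The denominator
#' is kept above `denominator_floor`; an empty reference set (single DMU)
#' or an unsatisfiable program yields `status = "infeasible"` with an
#' undefined score, reported rather than imputed.
#'
#' @inheritParams solve_sbm_standard
#' @return an `efficiency_result` with `stage = "super"`.
#' @export
solve_sbm_super <- function(data, unit, period, opts = dea_options()) {
  sbm_solve_one(data, unit, period, opts, super = TRUE)
}

#' Two-stage comprehensive efficiency score
#'
#' The production protocol behind the reported "comprehensive efficiency
#' values": run the standard SBM first; DMUs strictly inside the frontier
#' keep their sub-unity standard score, while frontier DMUs (standard score
#' 1 within tolerance) are re-evaluated with the super-efficiency program so
#' that efficient units can be ranked above 1. The standard stage is needed
#' because the super-efficiency program alone scores every dominated DMU at
#' 1 and cannot produce sub-unity values.
#'
#' @inheritParams solve_sbm_standard
#' @return an `efficiency_result`; `stage` records which program produced
#'   the score.
#' @export
efficiency_score <- function(data, unit, period, opts = dea_options()) {
  std <- solve_sbm_standard(data, unit, period, opts)
  if (std$status != "optimal") return(std)
  if (std$score < 1) return(std)
  solve_sbm_super(data, unit, period, opts)
}

#' Batch comprehensive efficiency scores
#'
#' Runs [efficiency_score()] for every unit-period record and returns a
#' tidy table.
#'
#' @inheritParams solve_sbm_standard
#' @return a data.frame with columns `unit`, `period`, `score`, `stage`,
#'   `status`, and the total input/output/bad slack per record.
#' @export
efficiency_batch <- function(data, opts = dea_options()) {
  r <- roles(data)
  res <- lapply(seq_len(nrow(data)), function(i) {
    er <- efficiency_score(data, data[[r$unit]][i], data[[r$period]][i], opts)
    data.frame(unit = er$unit, period = er$period, score = er$score,
               stage = er$stage, status = er$status,
               slack_input = sum(er$s_minus), slack_output = sum(er$s_plus),
               slack_bad = if (length(er$s_bad) > 0) sum(er$s_bad) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' CRS/VRS scale-efficiency decomposition
#'
#' Computes the comprehensive (CRS) score `crste`, the pure technical (VRS)
#' score `vrste`, and scale efficiency `scale = crste / vrste` for every
#' record, under both returns-to-scale assumptions. With
#' `stage = "two_stage"` (default) each score comes from the two-stage
#' protocol of [efficiency_score()], so frontier units can exceed 1 (the
#' form published benchmarking tables report). With `stage = "standard"`
#' only the standard SBM is run, scores are capped at 1, and
#' `scale` is guaranteed to lie in (0, 1] — the textbook decomposition,
#' since super-efficiency values distort the crste/vrste ratio for
#' frontier units. Records whose VRS super-efficiency program is
#' infeasible get `NA` for `vrste` and `scale` and are flagged.
#'
#' @param data a [panel_dataset()].
#' @param opts a [dea_options()]; its `rts` field is ignored (both are run).
#' @param stage `"two_stage"` or `"standard"` (see Details).
#' @return a data.frame with columns `unit`, `period`, `crste`, `vrste`,
#'   `scale`, `flag`.
#' @export
decompose_scale <- function(data, opts = dea_options(),
                            stage = c("two_stage", "standard")) {
  stage <- match.arg(stage)
  batch <- function(o) {
    if (stage == "two_stage") return(efficiency_batch(data, o))
    r <- roles(data)
    res <- lapply(seq_len(nrow(data)), function(i) {
      er <- solve_sbm_standard(data, data[[r$unit]][i],
                               data[[r$period]][i], o)
      data.frame(unit = er$unit, period = er$period, score = er$score,
                 stage = er$stage, status = er$status,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  crs <- batch(utils::modifyList(opts, list(rts = "CRS")))
  vrs <- batch(utils::modifyList(opts, list(rts = "VRS")))
  out <- data.frame(unit = crs$unit, period = crs$period,
                    crste = crs$score, vrste = vrs$score,
                    scale = crs$score / vrs$score,
                    flag = ifelse(crs$status != "optimal" |
                                    vrs$status != "optimal",
                                  "infeasible_component", ""),
                    stringsAsFactors = FALSE)
  out$scale[out$flag != ""] <- NA_real_
  out
}
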