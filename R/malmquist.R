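#' Radial (Shephard) distance to a period frontier
#'
#' Output-oriented distance of one unit's bundle, observed in
#' `data_period`, from the technology defined by all DMUs observed in
#' `frontier_period`. The Farrell expansion factor \eqn{\varphi^*} solves
#' \deqn{\max \varphi \;\; s.t.\;\; X\lambda \le x_o,\;
#'   Y\lambda \ge \varphi y_o,\; \lambda \ge 0}
#' (plus \eqn{\sum\lambda = 1} under VRS), and the Shephard output distance
#' is \eqn{D = 1/\varphi^*}: at most 1 inside the frontier, above 1 for
#' points beyond it. Undesirable outputs enter the input constraints when
#' `bad_mode = "as_input"` (default) and are dropped when `"ignore"`. With
#' `orientation = "input"` the Farrell input contraction \eqn{\theta^*} is
#' solved instead and \eqn{D = \theta^*} is returned (same inside-frontier
#' reading). Cross-period VRS programs can be genuinely infeasible; this is
#' reported, never imputed.
#'
#' @param data a [panel_dataset()].
#' @param unit evaluated unit.
#' @param data_period period of the evaluated bundle.
#' @param frontier_period period whose DMUs define the technology.
#' @param rts `"CRS"` or `"VRS"`.
#' @param bad_mode `"as_input"` or `"ignore"`.
#' @param orientation `"output"` (default) or `"input"`.
#' @return a list of class `distance_value` with fields `unit`,
#'   `data_period`, `frontier_period`, `rts`, `value`, `status`.
#' @export
radial_distance <- function(data, unit, data_period, frontier_period,
                            rts = c("CRS", "VRS"),
                            bad_mode = c("as_input", "ignore"),
                            orientation = c("output", "input")) {
  rts <- match.arg(rts); bad_mode <- match.arg(bad_mode)
  orientation <- match.arg(orientation)
  r <- roles(data)
  o <- row_of(data, unit, data_period)
  ref <- which(data[[r$period]] == frontier_period)
  if (length(ref) == 0) stop("no DMUs in frontier period ", frontier_period,
                             call. = FALSE)
  mo <- panel_matrices(data, o); mr <- panel_matrices(data, ref)
  xo <- as.numeric(drop(mo$X)); yo <- as.numeric(drop(mo$Y))
  X <- mr$X; Y <- mr$Y
  if (bad_mode == "as_input" && nrow(mr$B) > 0) {
    X <- rbind(X, mr$B); xo <- c(xo, as.numeric(drop(mo$B)))
  }
  fx <- col_factors(X); fy <- col_factors(Y)
  X <- scale_cols(X, fx); Y <- scale_cols(Y, fy)
  xo <- xo / fx; yo <- yo / fy
  m <- length(xo); q <- length(yo); n <- ncol(X)
  vrs <- rts == "VRS"
  # vars: phi (or theta), lambda_1..n
  nv <- 1 + n
  if (orientation == "output") {
    obj <- c(1, numeric(n))
    A1 <- matrix(0, m + q, nv); b1 <- numeric(m + q)
    A1[seq_len(m), 1 + seq_len(n)] <- X
    b1[seq_len(m)] <- xo
    A1[m + seq_len(q), 1] <- yo
    A1[m + seq_len(q), 1 + seq_len(n)] <- -Y
    A3 <- NULL; b3 <- NULL
    if (vrs) {
      A3 <- matrix(c(0, rep(1, n)), 1); b3 <- 1
    }
    out <- solve_lp(obj, A1 = A1, b1 = b1, A3 = A3, b3 = b3, maxi = TRUE)
    ok <- out$solved == 1 && is.finite(out$value) && out$value > 0
    val <- if (ok) 1 / out$value else NA_real_
  } else {
    obj <- c(1, numeric(n))
    # X lambda <= theta x_o ; Y lambda >= y_o
    A1 <- matrix(0, m, nv); b1 <- numeric(m)
    A1[, 1] <- -xo
    A1[, 1 + seq_len(n)] <- X
    A2 <- matrix(0, q, nv); b2 <- yo
    A2[, 1 + seq_len(n)] <- Y
    A3 <- NULL; b3 <- NULL
    if (vrs) { A3 <- matrix(c(0, rep(1, n)), 1); b3 <- 1 }
    out <- solve_lp(obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                    A3 = A3, b3 = b3, maxi = FALSE)
    ok <- out$solved == 1 && is.finite(out$value)
    val <- if (ok) out$value else NA_real_
  }
  structure(list(unit = unit, data_period = data_period,
                 frontier_period = frontier_period, rts = rts,
                 value = val, status = if (ok) "optimal" else "infeasible"),
            class = "distance_value")
}

#' Malmquist index between two consecutive periods for one unit
#'
#' Total-factor-productivity change from period `t` to `t_plus_1`:
#' \deqn{M_i = \sqrt{\frac{D^t(x^{t+1},y^{t+1})}{D^t(x^t,y^t)} \cdot
#'   \frac{D^{t+1}(x^{t+1},y^{t+1})}{D^{t+1}(x^t,y^t)}}}
#' decomposed as `mi = effch * techch` with
#' `effch = D^{t+1}(x^{t+1},y^{t+1}) / D^t(x^t,y^t)` (CRS), technological
#' change `techch = mi / effch`, pure efficiency change `pech` (the VRS
#' analogue of `effch`) and scale-efficiency change `sech = effch / pech`.
#' Both identities hold exactly by construction. `mi > 1` signals a
#' productivity gain. Four CRS and two VRS distance programs are solved;
#' any infeasible component leaves the affected entries `NA` and increments
#' `n_infeasible`.
#'
#' @inheritParams radial_distance
#' @param t,t_plus_1 the two periods (the unit must be observed in both).
#' @return a one-row data.frame: `unit`, `from_period`, `to_period`, `mi`,
#'   `effch`, `techch`, `pech`, `sech`, `n_infeasible`.
#' @export
malmquist_pair <- function(data, unit, t, t_plus_1,
                           bad_mode = c("as_input", "ignore"),
                           orientation = c("output", "input")) {
  bad_mode <- match.arg(bad_mode); orientation <- match.arg(orientation)
  dv <- function(dp, fp, rts) {
    radial_distance(data, unit, dp, fp, rts, bad_mode, orientation)
  }
  d_t_t <- dv(t, t, "CRS")
  d_t_t1 <- dv(t_plus_1, t, "CRS")
  d_t1_t <- dv(t, t_plus_1, "CRS")
  d_t1_t1 <- dv(t_plus_1, t_plus_1, "CRS")
  v_t_t <- dv(t, t, "VRS")
  v_t1_t1 <- dv(t_plus_1, t_plus_1, "VRS")
  comps <- list(d_t_t, d_t_t1, d_t1_t, d_t1_t1, v_t_t, v_t1_t1)
  n_inf <- sum(vapply(comps, function(d) d$status != "optimal", logical(1)))
  mi <- effch <- techch <- pech <- sech <- NA_real_
  if (d_t_t$status == "optimal" && d_t_t1$status == "optimal" &&
      d_t1_t$status == "optimal" && d_t1_t1$status == "optimal") {
    mi <- sqrt((d_t_t1$value / d_t_t$value) *
                 (d_t1_t1$value / d_t1_t$value))
    effch <- d_t1_t1$value / d_t_t$value
    techch <- mi / effch
  }
  if (v_t_t$status == "optimal" && v_t1_t1$status == "optimal") {
    pech <- v_t1_t1$value / v_t_t$value
    if (!is.na(effch)) sech <- effch / pech
  }
  data.frame(unit = unit, from_period = t, to_period = t_plus_1,
             mi = mi, effch = effch, techch = techch, pech = pech,
             sech = sech, n_infeasible = n_inf, stringsAsFactors = FALSE)
}

#' Malmquist indices for every unit and consecutive period pair
#'
#' @inheritParams malmquist_pair
#' @return a data.frame with one row per unit and consecutive period pair
#'   in which the unit is observed (columns as in [malmquist_pair()]).
#' @export
malmquist <- function(data, bad_mode = c("as_input", "ignore"),
                      orientation = c("output", "input")) {
  bad_mode <- match.arg(bad_mode); orientation <- match.arg(orientation)
  r <- roles(data)
  pers <- periods_of(data)
  if (length(pers) < 2) stop("need at least two periods", call. = FALSE)
  rows <- list()
  for (i in seq_len(length(pers) - 1)) {
    t0 <- pers[i]; t1 <- pers[i + 1]
    u0 <- data[[r$unit]][data[[r$period]] == t0]
    u1 <- data[[r$unit]][data[[r$period]] == t1]
    for (u in intersect(u0, u1)) {
      rows[[length(rows) + 1]] <-
        malmquist_pair(data, u, t0, t1, bad_mode, orientation)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

geomean <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  exp(mean(log(v)))
}

#' Summaries of Malmquist results
#'
#' Index numbers are averaged geometrically. Three layouts:
#' `by = "unit"` gives the per-city mean of each component over period
#' pairs plus a rank by mean `mi` (rank 1 = largest); `by = "period"`
#' gives per period-pair means over units (optionally within groups);
#' `by = "group"` gives per-group means over all unit-pairs, with an
#' all-units row labeled `"All"`. Undefined (infeasible) components are
#' excluded and counted in `n_excluded`.
#'
#' @param results the output of [malmquist()].
#' @param by one of `"unit"`, `"period"`, `"group"`.
#' @param grouping optional named character vector mapping unit to group
#'   (required for `by = "group"`, used for `by = "period"` if given).
#' @return a data.frame summary table.
#' @export
malmquist_summary <- function(results, by = c("unit", "period", "group"),
                              grouping = NULL) {
  by <- match.arg(by)
  stopifnot(is.data.frame(results), nrow(results) > 0)
  comp <- c("effch", "techch", "pech", "sech", "mi")
  agg <- function(split_f, label) {
    parts <- split(results, split_f)
    out <- do.call(rbind, lapply(names(parts), function(k) {
      p <- parts[[k]]
      row <- as.data.frame(lapply(p[comp], geomean))
      row <- cbind(stats::setNames(data.frame(k, stringsAsFactors = FALSE),
                                   label), row)
      row$n_excluded <- sum(is.na(p[comp]))
      row
    }))
    rownames(out) <- NULL
    out
  }
  if (by == "unit") {
    out <- agg(results$unit, "unit")
    out$rank <- NA_integer_
    ok <- !is.na(out$mi)
    out$rank[ok] <- rank(-out$mi[ok], ties.method = "first")
    return(out)
  }
  if (by == "period") {
    f <- paste(results$from_period, results$to_period, sep = "-")
    if (!is.null(grouping)) {
      res2 <- results; res2$group <- grouping[res2$unit]
      out <- agg(paste(res2$group, f, sep = " "), "group_period")
      all_row <- agg(f, "group_period")
      all_row$group_period <- paste("All", all_row$group_period)
      out <- rbind(out, all_row)
      return(out)
    }
    return(agg(f, "period_pair"))
  }
  if (is.null(grouping)) stop("grouping required for by = 'group'",
                              call. = FALSE)
  unmapped <- setdiff(unique(results$unit), names(grouping))
  if (length(unmapped) > 0) {
    stop("unit(s) not mapped to a group: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  out <- agg(grouping[results$unit], "group")
  all_row <- as.data.frame(lapply(results[comp], geomean))
  all_row <- cbind(data.frame(group = "All", stringsAsFactors = FALSE),
                   all_row)
  all_row$n_excluded <- sum(is.na(results[comp]))
  rbind(out, all_row)
}
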