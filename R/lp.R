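# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# The DEA programs solved here are small (tens of variables, around ten
# constraints), so a careful dense implementation is both fast enough and
# fully controllable numerically. Solves
#   min/max  c'x   s.t.  A1 x <= b1,  A2 x >= b2,  A3 x = b3,  x >= 0.
# Returns list(status = "optimal" | "infeasible" | "unbounded",
#              value, x).

lp_simplex <- function(obj, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                       A3 = NULL, b3 = NULL, maxi = FALSE, tol = 1e-9) {
  n <- length(obj)
  rows <- list(); rhs <- numeric(0); sense <- character(0)
  add <- function(A, b, s) {
    if (!is.null(A)) {
      A <- matrix(A, ncol = n)
      for (i in seq_len(nrow(A))) {
        rows[[length(rows) + 1]] <<- A[i, ]
        rhs[length(rhs) + 1] <<- b[i]
        sense[length(sense) + 1] <<- s
      }
    }
  }
  add(A1, b1, "<="); add(A2, b2, ">="); add(A3, b3, "=")
  m <- length(rows)
  A <- do.call(rbind, rows)
  b <- rhs
  # normalize to b >= 0
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    sense[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[sense[neg]]
  }
  # slack / surplus columns
  n_slack <- sum(sense != "=")
  S <- matrix(0, m, n_slack)
  j <- 0
  slack_basic <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      j <- j + 1; S[i, j] <- 1; slack_basic[i] <- n + j
    } else if (sense[i] == ">=") {
      j <- j + 1; S[i, j] <- -1
    }
  }
  # artificials for rows without an initial basic column
  need_art <- is.na(slack_basic)
  n_art <- sum(need_art)
  Aa <- matrix(0, m, n_art)
  art_cols <- integer(0)
  j <- 0
  basis <- slack_basic
  for (i in which(need_art)) {
    j <- j + 1; Aa[i, j] <- 1
    basis[i] <- n + n_slack + j
    art_cols <- c(art_cols, n + n_slack + j)
  }
  Tab <- cbind(A, S, Aa, b)
  ncols <- ncol(Tab) - 1
  cost <- numeric(ncols)
  cost[seq_len(n)] <- if (maxi) -obj else obj

  pivot <- function(pr, pc) {
    Tab[pr, ] <<- Tab[pr, ] / Tab[pr, pc]
    other <- setdiff(seq_len(nrow(Tab)), pr)
    f <- Tab[other, pc]
    nz <- which(abs(f) > 0)
    if (length(nz) > 0) {
      o <- other[nz]
      Tab[o, ] <<- Tab[o, ] - outer(f[nz], Tab[pr, ])
      Tab[o, pc] <<- 0
    }
    basis[pr] <<- pc
  }

  run_phase <- function(cvec, allowed) {
    repeat {
      cb <- cvec[basis]
      # reduced costs: c_j - cb' B^{-1} A_j ; tableau already holds B^{-1}A
      red <- cvec[allowed] - drop(cb %*% Tab[, allowed, drop = FALSE])
      ent_rel <- which(red < -max(tol, 1e-11))
      if (length(ent_rel) == 0) return("optimal")
      pc <- allowed[min(ent_rel)]  # Bland: smallest index
      col <- Tab[, pc]
      pos <- which(col > tol)
      if (length(pos) == 0) return("unbounded")
      ratio <- Tab[pos, ncols + 1] / col[pos]
      mn <- min(ratio)
      cand <- pos[ratio <= mn + tol]
      pr <- cand[which.min(basis[cand])]  # Bland tie-break
      pivot(pr, pc)
    }
  }

  if (n_art > 0) {
    c1 <- numeric(ncols); c1[art_cols] <- 1
    # price out artificials that start basic
    st <- run_phase(c1, seq_len(ncols))
    ph1 <- sum(c1[basis] * Tab[, ncols + 1])
    if (st != "optimal" || ph1 > 1e-7) {
      return(list(status = "infeasible", value = NA_real_,
                  x = rep(NA_real_, n)))
    }
    # drive remaining zero-level artificials out of the basis; a row whose
    # non-artificial coefficients all vanish is redundant and is dropped
    drop_rows <- integer(0)
    for (i in which(basis %in% art_cols)) {
      cand <- setdiff(which(abs(Tab[i, seq_len(ncols)]) > tol), art_cols)
      if (length(cand) > 0) {
        pivot(i, min(cand))
      } else {
        drop_rows <- c(drop_rows, i)
      }
    }
    if (length(drop_rows) > 0) {
      Tab <- Tab[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
    }
  }
  allowed <- setdiff(seq_len(ncols), art_cols)
  st <- run_phase(cost, allowed)
  if (st != "optimal") {
    return(list(status = st, value = NA_real_, x = rep(NA_real_, n)))
  }
  x <- numeric(ncols)
  x[basis] <- Tab[, ncols + 1]
  val <- sum(cost[seq_len(n)] * x[seq_len(n)])
  list(status = "optimal", value = if (maxi) -val else val,
       x = x[seq_len(n)])
}
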