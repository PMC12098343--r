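# Synthetic city-by-year panels with a known production frontier, so that
# every pipeline stage (SBM, Malmquist, Tobit) can be validated against a
# known truth without external yearbook data.

#' Generate a synthetic efficiency panel with known truth
#'
#' Simulates a city-by-year panel from a Cobb-Douglas frontier with
#' multiplicative inefficiency:
#' * inputs `x` are log-normal;
#' * latent efficiency is \eqn{\theta_{it} =
#'   \mathrm{logistic}(\alpha_0 + z_{it}'\beta + u_i + \epsilon_{it})} with
#'   \eqn{u_i \sim N(0, \sigma_u^2)} and
#'   \eqn{\epsilon_{it} \sim N(0, \sigma_e^2)}; when `anchor_frontier` is
#'   set, \eqn{\theta} is divided by its per-period maximum so each period
#'   contains a unit with \eqn{\theta = 1} (keeping \eqn{\theta \in (0,1]});
#' * desirable outputs are \eqn{y_{rit} = \gamma_r \cdot
#'   \mathrm{drift}_t \cdot \prod_j x_j^{a_j} \cdot \theta_{it} \cdot
#'   e^{\nu}} with small multiplicative noise \eqn{\nu};
#' * the undesirable output rises with the first desirable output,
#'   \eqn{b = 0.1\, y_1\, e^{\nu_b}};
#' * covariates `z` are standard normal.
#'
#' A single integer seed governs all draws through one generator stream;
#' regeneration with the same configuration is bit-identical.
#'
#' @param n_units number of units (default 41, the study's city count).
#' @param n_periods number of periods (default 6 years).
#' @param m,q,h,p numbers of inputs, desirable outputs, undesirable
#'   outputs and covariates (defaults 3, 2, 1, 8, mirroring the indicator
#'   system).
#' @param beta_true covariate coefficients on the latent-efficiency scale
#'   (recycled/truncated to length `p`; default 0.5, -0.5, 0.3, then 0).
#' @param sigma_u,sigma_e random-effect and idiosyncratic SDs of the
#'   latent efficiency (defaults 0.2 and 0.15).
#' @param tech_drift per-period frontier multipliers (length `n_periods`;
#'   default a 3 percent annual rise).
#' @param frontier_exponents Cobb-Douglas exponents, length `m`, positive;
#'   default equal shares summing to `rts_degree`.
#' @param rts_degree returns-to-scale degree the exponents sum to
#'   (default 1, constant returns).
#' @param output_noise_sd SD of the log-normal output noise (default 0.05).
#' @param anchor_frontier if `TRUE` (default), rescale so each period has
#'   a fully efficient unit.
#' @param seed integer seed.
#' @return a list with `panel` (a [panel_dataset()] with covariates and a
#'   4-level `group` label) and `truth` (a `synthetic_truth` list holding
#'   the frontier exponents, the true efficiency matrix, the drift, the
#'   true coefficients and variance components, and the seed).
#' @export
generate_panel <- function(n_units = 41, n_periods = 6, m = 3, q = 2,
                           h = 1, p = 8,
                           beta_true = c(0.5, -0.5, 0.3, rep(0, 5)),
                           sigma_u = 0.2, sigma_e = 0.15,
                           tech_drift = 1.03^(seq_len(n_periods) - 1),
                           frontier_exponents = NULL, rts_degree = 1,
                           output_noise_sd = 0.05,
                           anchor_frontier = TRUE, seed = 1L) {
  stopifnot(n_units >= 2, n_periods >= 1, m >= 1, q >= 1, h >= 0, p >= 0,
            length(tech_drift) == n_periods, all(tech_drift > 0),
            sigma_u >= 0, sigma_e >= 0, output_noise_sd >= 0)
  if (is.null(frontier_exponents)) {
    frontier_exponents <- rep(rts_degree / m, m)
  }
  stopifnot(length(frontier_exponents) == m, all(frontier_exponents > 0))
  beta_true <- rep_len(beta_true, p)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))

  units <- sprintf("city%02d", seq_len(n_units))
  periods <- seq_len(n_periods)
  grid <- expand.grid(unit = units, period = periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$unit, grid$period), ]
  N <- nrow(grid)

  X <- matrix(stats::rlnorm(N * m, rep(meanlog_inputs(m), each = N), 0.3),
              N, m)
  Z <- if (p > 0) matrix(stats::rnorm(N * p), N, p) else
    matrix(numeric(0), N, 0)
  u <- stats::rnorm(n_units, 0, sigma_u)
  names(u) <- units
  eps <- stats::rnorm(N, 0, sigma_e)
  lin <- 1 + (if (p > 0) drop(Z %*% beta_true) else 0) +
    u[grid$unit] + eps
  theta <- stats::plogis(lin)
  # grid rows are unit-major (unit 1 periods 1..T, unit 2 ...), so fill by row
  theta_mat <- matrix(theta, nrow = n_units, ncol = n_periods, byrow = TRUE,
                      dimnames = list(units, periods))
  if (anchor_frontier) {
    mx <- apply(theta_mat, 2, max)
    theta_mat <- sweep(theta_mat, 2, mx, `/`)
  }
  theta_vec <- as.numeric(t(theta_mat))  # back to grid order

  drift <- tech_drift[grid$period]
  frontier <- exp(log(X) %*% frontier_exponents)
  gamma <- 1 + (seq_len(q) - 1)  # output-specific scale 1, 2, ...
  Y <- sapply(seq_len(q), function(r) {
    gamma[r] * drift * frontier * theta_vec *
      exp(stats::rnorm(N, 0, output_noise_sd))
  })
  Y <- matrix(Y, N, q)
  B <- if (h > 0) {
    sapply(seq_len(h), function(k) {
      0.1 * Y[, 1] * exp(stats::rnorm(N, 0, 0.1))
    })
  } else matrix(numeric(0), N, 0)
  B <- matrix(B, N, h)

  df <- data.frame(unit = grid$unit, period = grid$period,
                   stringsAsFactors = FALSE)
  in_names <- paste0("input", seq_len(m))
  out_names <- paste0("output", seq_len(q))
  bad_names <- if (h > 0) paste0("bad", seq_len(h)) else character(0)
  cov_names <- if (p > 0) paste0("z", seq_len(p)) else character(0)
  df[in_names] <- as.data.frame(X)
  df[out_names] <- as.data.frame(Y)
  if (h > 0) df[bad_names] <- as.data.frame(B)
  if (p > 0) df[cov_names] <- as.data.frame(Z)
  # four groups sized like the study region (16/13/11/1) when n = 41,
  # otherwise round proportional blocks
  sizes <- if (n_units == 41) c(16, 13, 11, 1) else {
    s <- diff(round(seq(0, n_units, length.out = 5))); pmax(s, 1)
  }
  sizes[length(sizes)] <- n_units - sum(sizes[-length(sizes)])
  glab <- rep(paste0("G", seq_along(sizes)), times = sizes)
  names(glab) <- units
  df$group <- glab[df$unit]

  panel <- panel_dataset(df, unit = "unit", period = "period",
                         inputs = in_names, outputs = out_names,
                         bads = bad_names, covariates = cov_names,
                         group = "group")
  truth <- structure(list(frontier_exponents = frontier_exponents,
                          true_efficiency = theta_mat,
                          tech_drift = tech_drift,
                          beta_true = beta_true,
                          sigma_u_true = sigma_u, sigma_e_true = sigma_e,
                          gamma = gamma, seed = as.integer(seed),
                          anchor_frontier = anchor_frontier),
                     class = "synthetic_truth")
  list(panel = panel, truth = truth)
}

meanlog_inputs <- function(m) log(10) + 0.2 * (seq_len(m) - 1)

#' Printed comprehensive-efficiency fixture (41 cities x 6 years)
#'
#' Transcription of the published comprehensive efficiency values of
#' medical and health resource allocation for the 41 cities of the Yangtze
#' River Delta urban agglomeration, 2015-2020, together with the published
#' per-city averages and ranks and the published per-year region averages.
#' The two city-name collisions (Suzhou, Taizhou) are disambiguated with
#' their province in parentheses. The packaged CSV is integrity-checked
#' against a stored MD5 checksum.
#'
#' @return a list with `scores` (41-row data.frame: `unit`, `province`,
#'   year columns `y2015`..`y2020`, `printed_average`, `printed_rank`) and
#'   `region_average` (named numeric vector of the published per-year
#'   all-city means plus overall).
#' @export
table4_fixture <- function() {
  path <- system.file("extdata", "table4_efficiency.csv",
                      package = "medeff", mustWork = TRUE)
  expected_md5 <- "b1137780ccdf98cb74e7dd5ca3241622"
  md5 <- unname(tools::md5sum(path))
  if (!is.na(expected_md5) && md5 != expected_md5) {
    stop("fixture checksum mismatch: ", md5, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  all_row <- df[df$unit == "All", ]
  scores <- df[df$unit != "All", ]
  rownames(scores) <- NULL
  yr <- paste0("y", 2015:2020)
  region <- c(as.numeric(all_row[1, yr]), all_row$printed_average[1])
  names(region) <- c(yr, "overall")
  list(scores = scores, region_average = region)
}
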