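#' Panel dataset of decision-making units
#'
#' A `panel_dataset` holds a long-format panel of decision-making units
#' (DMUs, e.g. cities) observed over integer periods (years), together with
#' the role each numeric column plays in the efficiency analysis: inputs
#' `x`, desirable outputs `y`, undesirable outputs `b`, and optional
#' covariates `z` for the second-stage regression. All downstream models
#' (SBM, Malmquist, Tobit) consume this class only.
#'
#' Invariants enforced by the validator:
#' * every (unit, period) pair is unique;
#' * all input and output values are strictly positive, and all undesirable
#'   output values are strictly positive when any are declared;
#' * the numbers of inputs/outputs/bads/covariates are identical across
#'   records (they are column roles, so this holds by construction);
#' * at least two distinct units are required before any DEA computation.
#'
#' @param data a data.frame in long format, one row per unit-period.
#' @param unit,period names of the identifier columns. Periods must be
#'   coercible to integers (plain years; no date parsing).
#' @param inputs,outputs character vectors of column names for inputs and
#'   desirable outputs (each at least one column).
#' @param bads character vector of undesirable-output columns (may be empty).
#' @param covariates character vector of covariate columns (may be empty).
#' @param group optional name of a column with a group label per unit
#'   (e.g. province); must be constant within unit.
#' @return an object of class `panel_dataset`: the normalized data.frame
#'   (sorted by unit then period) with the role map stored in attributes.
#' @examples
#' df <- data.frame(city = c("A", "B"), year = 2015,
#'                  beds = c(2, 4), visits = c(4, 4))
#' pd <- panel_dataset(df, unit = "city", period = "year",
#'                     inputs = "beds", outputs = "visits")
#' n_units(pd)
#' @export
panel_dataset <- function(data, unit = "unit", period = "period",
                          inputs, outputs, bads = character(),
                          covariates = character(), group = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  roles <- list(unit = unit, period = period, inputs = inputs,
                outputs = outputs, bads = bads, covariates = covariates,
                group = group)
  needed <- unlist(roles, use.names = FALSE)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("schema error: column(s) not present in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(inputs) < 1 || length(outputs) < 1) {
    stop("schema error: at least one input and one output column required",
         call. = FALSE)
  }
  data[[unit]] <- as.character(data[[unit]])
  per <- data[[period]]
  per_int <- suppressWarnings(as.integer(per))
  if (anyNA(per_int) || any(abs(as.numeric(per) - per_int) > 0)) {
    stop("validation error: period column must contain plain integers",
         call. = FALSE)
  }
  data[[period]] <- per_int

  key <- paste(data[[unit]], data[[period]], sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("integrity error: duplicate (unit, period) pair: ",
         gsub("\r", ", ", dup), call. = FALSE)
  }
  for (col in c(inputs, outputs, bads)) {
    v <- data[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("validation error: column '", col, "' must be numeric without NA",
           call. = FALSE)
    }
    bad_rows <- which(v <= 0)
    if (length(bad_rows) > 0) {
      i <- bad_rows[1]
      stop(sprintf(
        "validation error: nonpositive value in column '%s' at unit '%s', period %d",
        col, data[[unit]][i], data[[period]][i]), call. = FALSE)
    }
  }
  for (col in covariates) {
    v <- data[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("validation error: covariate '", col, "' must be finite numeric",
           call. = FALSE)
    }
  }
  if (!is.null(group)) {
    per_unit <- tapply(data[[group]], data[[unit]],
                       function(g) length(unique(g)))
    if (any(per_unit > 1)) {
      stop("validation error: group label must be constant within unit",
           call. = FALSE)
    }
  }
  data <- data[order(data[[unit]], data[[period]]), , drop = FALSE]
  rownames(data) <- NULL
  structure(data, roles = roles, class = c("panel_dataset", "data.frame"))
}

#' @export
print.panel_dataset <- function(x, ...) {
  r <- attr(x, "roles")
  cat(sprintf(
    "panel_dataset: %d units x %d periods (%d records)\n",
    n_units(x), n_periods(x), nrow(x)))
  cat("  inputs (m=", length(r$inputs), "): ",
      paste(r$inputs, collapse = ", "), "\n", sep = "")
  cat("  outputs (q=", length(r$outputs), "): ",
      paste(r$outputs, collapse = ", "), "\n", sep = "")
  cat("  undesirable (h=", length(r$bads), "): ",
      paste(r$bads, collapse = ", "), "\n", sep = "")
  if (length(r$covariates) > 0) {
    cat("  covariates (p=", length(r$covariates), "): ",
        paste(r$covariates, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

roles <- function(pd) attr(pd, "roles")

#' @rdname panel_dataset
#' @param pd a `panel_dataset`.
#' @export
n_units <- function(pd) length(unique(pd[[roles(pd)$unit]]))

#' @rdname panel_dataset
#' @export
n_periods <- function(pd) length(unique(pd[[roles(pd)$period]]))

#' @rdname panel_dataset
#' @export
units_of <- function(pd) sort(unique(pd[[roles(pd)$unit]]))

#' @rdname panel_dataset
#' @export
periods_of <- function(pd) sort(unique(pd[[roles(pd)$period]]))

# Extract role matrices for a subset of rows (reference set assembly).
# Returns list with unit, period, X (m x n), Y (q x n), B (h x n), Z, group.
panel_matrices <- function(pd, rows = seq_len(nrow(pd))) {
  r <- roles(pd)
  sub <- pd[rows, , drop = FALSE]
  list(
    unit = sub[[r$unit]],
    period = sub[[r$period]],
    X = t(as.matrix(sub[, r$inputs, drop = FALSE])),
    Y = t(as.matrix(sub[, r$outputs, drop = FALSE])),
    B = if (length(r$bads) > 0) t(as.matrix(sub[, r$bads, drop = FALSE]))
        else matrix(0, 0, nrow(sub)),
    Z = if (length(r$covariates) > 0)
          as.matrix(sub[, r$covariates, drop = FALSE]) else NULL,
    group = if (!is.null(r$group)) sub[[r$group]] else NULL
  )
}

#' Read a long-format panel CSV into a panel_dataset
#'
#' @param path path to a CSV file with one row per unit-period.
#' @param schema a named list mapping roles to column names, with entries
#'   `unit`, `period`, `inputs`, `outputs` and optionally `bads`,
#'   `covariates`, `group`; or the path to a YAML file with those keys.
#' @return a validated [panel_dataset()]; rows are normalized to
#'   (unit, period) order.
#' @export
read_panel <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1) {
    schema <- yaml::read_yaml(schema)
  }
  stopifnot(is.list(schema))
  for (k in c("unit", "period", "inputs", "outputs")) {
    if (is.null(schema[[k]])) {
      stop("schema error: missing role '", k, "'", call. = FALSE)
    }
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  panel_dataset(df,
                unit = schema$unit, period = schema$period,
                inputs = schema$inputs, outputs = schema$outputs,
                bads = schema$bads %||% character(),
                covariates = schema$covariates %||% character(),
                group = schema$group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tabular result to CSV
#'
#' Deterministic column order (as stored); a round-trip read recovers the
#' values to full stored precision (15 significant digits).
#'
#' @param result a non-empty data.frame (any tabular stage output).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_table <- function(result, path) {
  if (!is.data.frame(result)) result <- as.data.frame(result)
  if (nrow(result) == 0) {
    stop("refusing to write an empty result table", call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("IO error: directory does not exist: ", dir, call. = FALSE)
  }
  out <- result
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct the efficiency-analysis indicator panel from raw city records
#'
#' Turns raw administrative quantities (institution counts, beds, visits,
#' expenditure aggregates, personnel counts) into the indicator ratios used
#' throughout the analysis: three inputs (institutions, beds per thousand
#' residents, health technicians per thousand residents), two desirable
#' outputs (outpatient/emergency visits, bed utilization rate), one
#' undesirable output (medical-expense share of household consumption, in
#' percent), and eight covariates (urbanization rate %, per-capita GDP,
#' urban/rural income ratio, health-expenditure share of the public budget
#' %, fiscal autonomy %, physician/nurse ratio %, share of physicians and
#' nurses among health technical personnel %, average length of stay).
#' Percentages are stored on the 0-100 scale.
#'
#' @param raw a data.frame with columns `unit`, `period` and the raw
#'   quantities: `institutions`, `beds`, `population`, `technicians`,
#'   `visits`, `bed_days_used`, `bed_days_open`, `medical_expense`,
#'   `total_consumption`; optionally `urban_population`, `gdp`,
#'   `urban_income`, `rural_income`, `health_expenditure`,
#'   `budget_expenditure`, `budget_revenue`, `physicians`, `nurses`,
#'   `health_technical_personnel`, `inpatient_days`, `discharged_patients`
#'   (all required for the covariate block), and `group`.
#' @return a [panel_dataset()] with m = 3 inputs, q = 2 outputs, h = 1
#'   undesirable output and, when the covariate columns are supplied,
#'   p = 8 covariates.
#' @export
build_indicators <- function(raw) {
  stopifnot(is.data.frame(raw))
  need <- c("unit", "period", "institutions", "beds", "population",
            "technicians", "visits", "bed_days_used", "bed_days_open",
            "medical_expense", "total_consumption")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("schema error: missing raw column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cov_need <- c("urban_population", "gdp", "urban_income", "rural_income",
                "health_expenditure", "budget_expenditure", "budget_revenue",
                "physicians", "nurses", "health_technical_personnel",
                "inpatient_days", "discharged_patients")
  have_cov <- all(cov_need %in% names(raw))

  denom_cols <- c("population", "bed_days_open", "total_consumption")
  if (have_cov) {
    denom_cols <- c(denom_cols, "rural_income", "budget_expenditure",
                    "nurses", "health_technical_personnel",
                    "discharged_patients")
  }
  for (col in denom_cols) {
    if (any(raw[[col]] <= 0)) {
      stop("validation error: nonpositive denominator in '", col, "'",
           call. = FALSE)
    }
  }
  out <- data.frame(
    unit = as.character(raw$unit),
    period = raw$period,
    institutions = raw$institutions,
    beds_per_thousand = raw$beds / raw$population * 1000,
    technicians_per_thousand = raw$technicians / raw$population * 1000,
    visits = raw$visits,
    bed_utilization = raw$bed_days_used / raw$bed_days_open,
    medical_expense_share = raw$medical_expense / raw$total_consumption * 100,
    stringsAsFactors = FALSE
  )
  covs <- character()
  if (have_cov) {
    out$urbanization <- raw$urban_population / raw$population * 100
    out$gdp_per_capita <- raw$gdp / raw$population
    out$income_gap <- raw$urban_income / raw$rural_income
    out$health_fiscal_share <-
      raw$health_expenditure / raw$budget_expenditure * 100
    out$fiscal_autonomy <- raw$budget_revenue / raw$budget_expenditure * 100
    out$doctor_nurse_ratio <- raw$physicians / raw$nurses * 100
    out$staff_technician_ratio <-
      (raw$physicians + raw$nurses) / raw$health_technical_personnel * 100
    out$avg_length_of_stay <- raw$inpatient_days / raw$discharged_patients
    covs <- c("urbanization", "gdp_per_capita", "income_gap",
              "health_fiscal_share", "fiscal_autonomy", "doctor_nurse_ratio",
              "staff_technician_ratio", "avg_length_of_stay")
  }
  grp <- NULL
  if ("group" %in% names(raw)) {
    out$group <- raw$group
    grp <- "group"
  }
  panel_dataset(out, unit = "unit", period = "period",
                inputs = c("institutions", "beds_per_thousand",
                           "technicians_per_thousand"),
                outputs = c("visits", "bed_utilization"),
                bads = "medical_expense_share",
                covariates = covs, group = grp)
}
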