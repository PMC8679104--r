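#' @importFrom rlang .data
NULL

share_cols <- c("share_no_facility", "share_limited", "share_basic")
split_cols <- c("limited_soap_only", "limited_water_only", "limited_both")

quantity_schema <- function(base_year = 2021L, horizon = 10L) {
  years <- seq(base_year, base_year + horizon - 1L)
  c("country_code", "setting", "household_size",
    paste0("pop_", years),
    share_cols, split_cols,
    "piped_share", "piped_unit_cost", "nonpiped_unit_cost", "provenance")
}

pop_cols <- function(table) {
  grep("^pop_\\d{4}$", names(table), value = TRUE)
}

pop_years <- function(table) {
  as.integer(sub("^pop_", "", pop_cols(table)))
}

#' Build a hygiene service breakdown
#'
#' A country-stratum's split of households across hygiene service levels
#' ("no facility" / "limited" / "basic"), together with the split of the
#' limited group by limiting factor (soap missing, water missing, both
#' missing). Both triples must sum to 1.
#'
#' @param no_facility,limited,basic Proportions of households at each
#'   service level.
#' @param limited_soap_only,limited_water_only,limited_both Proportions of
#'   the limited group by limiting factor.
#' @return A named numeric vector of the six proportions.
#' @export
service_breakdown <- function(no_facility, limited, basic,
                              limited_soap_only = 0.47,
                              limited_water_only = 0.10,
                              limited_both = 0.43) {
  sb <- c(share_no_facility = no_facility, share_limited = limited,
          share_basic = basic, limited_soap_only = limited_soap_only,
          limited_water_only = limited_water_only, limited_both = limited_both)
  if (any(sb < 0 | sb > 1)) {
    rlang::abort("all proportions must lie in [0, 1].",
                 class = "hygienecost_validation_error")
  }
  if (abs(sum(sb[1:3]) - 1) > 1e-9) {
    rlang::abort("service shares must sum to 1.",
                 class = "hygienecost_validation_error")
  }
  if (abs(sum(sb[4:6]) - 1) > 1e-9) {
    rlang::abort("limited-factor split must sum to 1.",
                 class = "hygienecost_validation_error")
  }
  sb
}

#' Validate a country quantity table
#'
#' Checks the row-level invariants: positive populations, household sizes in
#' a plausible range, proportions in `[0, 1]`, both share triples summing to
#' 1, and at most one row per country x setting. Rows with missing service
#' shares (to be filled by [impute_missing()]) are tolerated when
#' `allow_missing_service = TRUE`.
#'
#' @param table A quantity table (tibble).
#' @param allow_missing_service Tolerate rows whose service shares are all
#'   `NA` (pending imputation).
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_quantity_table <- function(table, allow_missing_service = FALSE) {
  missing_cols <- setdiff(quantity_schema(), names(table))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "hygienecost_schema_error"
    )
  }
  if (!all(table$setting %in% c("urban", "rural"))) {
    rlang::abort("`setting` must be 'urban' or 'rural'.",
                 class = "hygienecost_validation_error")
  }
  dup <- duplicated(table[c("country_code", "setting")])
  if (any(dup)) {
    rlang::abort(paste0("duplicate country x setting rows: ",
                        paste(which(dup), collapse = ", ")),
                 class = "hygienecost_validation_error")
  }

  row_id <- paste0(table$country_code, "/", table$setting, " (row ",
                   seq_len(nrow(table)), ")")
  fail <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rlang::abort(paste0(what, ": ", paste(row_id[which(bad)], collapse = "; ")),
                   class = "hygienecost_validation_error")
    }
  }

  pops <- as.matrix(table[pop_cols(table)])
  fail(apply(pops <= 0 | is.na(pops), 1, any), "non-positive or missing population")
  fail(table$household_size <= 1 | table$household_size >= 15,
       "household_size outside (1, 15)")
  fail(table$piped_share < 0 | table$piped_share > 1, "piped_share outside [0, 1]")
  fail(table$piped_unit_cost < 0 | table$nonpiped_unit_cost < 0,
       "negative water unit cost")

  svc <- as.matrix(table[c(share_cols, split_cols)])
  has_service <- stats::complete.cases(svc)
  if (!allow_missing_service) {
    fail(!has_service, "missing service shares")
  } else {
    partially <- !has_service & apply(!is.na(svc), 1, any)
    fail(partially, "partially missing service shares (all-or-none expected)")
  }
  sv <- svc[has_service, , drop = FALSE]
  idx <- which(has_service)
  bad_range <- apply(sv < 0 | sv > 1, 1, any)
  bad_sum1 <- abs(rowSums(sv[, share_cols, drop = FALSE]) - 1) > 1e-9
  bad_sum2 <- abs(rowSums(sv[, split_cols, drop = FALSE]) - 1) > 1e-9
  fail_at <- function(bad, what) {
    if (any(bad)) {
      rlang::abort(paste0(what, ": ", paste(row_id[idx[which(bad)]], collapse = "; ")),
                   class = "hygienecost_validation_error")
    }
  }
  fail_at(bad_range, "service proportions outside [0, 1]")
  fail_at(bad_sum1, "service shares do not sum to 1")
  fail_at(bad_sum2, "limited-factor split does not sum to 1")
  invisible(table)
}

#' Load a country quantity table from CSV
#'
#' One row per country x setting with household size, population projections
#' `pop_2021`..`pop_2030`, hygiene service shares, the limited-service split
#' by limiting factor, and water-supply attributes.
#'
#' @param path CSV file path.
#' @param allow_missing_service Accept rows with all service shares missing
#'   (fill them with [impute_missing()]).
#' @return A validated quantity table (tibble).
#' @export
load_country_table <- function(path, allow_missing_service = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "hygienecost_schema_error")
  }
  table <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_quantity_table(table, allow_missing_service = allow_missing_service)
  table
}

#' Fill missing service breakdowns
#'
#' Rows whose service shares are missing are filled from an earlier-year
#' observation where one exists, and otherwise from the LDC average
#' breakdown; the `provenance` column records which policy applied. Fully
#' observed rows are returned untouched, so the operation is idempotent.
#'
#' @param table Quantity table, possibly with rows whose six service-share
#'   columns are all `NA`.
#' @param ldc_average A [service_breakdown()] used when no data exist.
#' @param earlier Optional tibble of earlier-year observations with columns
#'   `country_code`, `setting` and the six share columns.
#' @return The completed, validated quantity table.
#' @export
impute_missing <- function(table, ldc_average, earlier = NULL) {
  ldc_average <- service_breakdown(
    ldc_average[["share_no_facility"]], ldc_average[["share_limited"]],
    ldc_average[["share_basic"]], ldc_average[["limited_soap_only"]],
    ldc_average[["limited_water_only"]], ldc_average[["limited_both"]]
  )
  validate_quantity_table(table, allow_missing_service = TRUE)
  cols <- c(share_cols, split_cols)
  needs <- !stats::complete.cases(table[cols])
  for (i in which(needs)) {
    filled <- FALSE
    if (!is.null(earlier)) {
      j <- which(earlier$country_code == table$country_code[i] &
                   earlier$setting == table$setting[i])
      if (length(j) == 1 && all(!is.na(earlier[j, cols]))) {
        table[i, cols] <- earlier[j, cols]
        table$provenance[i] <- "earlier_year"
        filled <- TRUE
      }
    }
    if (!filled) {
      table[i, cols] <- as.list(ldc_average[cols])
      table$provenance[i] <- "ldc_average"
    }
  }
  validate_quantity_table(table)
  table
}

stratum_population <- function(cs, year) {
  col <- paste0("pop_", year)
  if (!col %in% names(cs)) {
    rlang::abort(paste0("year ", year, " outside the population projections."),
                 class = "hygienecost_validation_error")
  }
  cs[[col]]
}

#' Households without a handwashing facility
#'
#' Number of households to be targeted in a country stratum: the year's
#' projected population divided by the average household size, times the
#' share with no hygiene facility. Fractional households are kept (rounding
#' happens only at reporting).
#'
#' @param cs One row of a quantity table.
#' @param year Calendar year within the projection range.
#' @return Household count (non-negative real).
#' @export
unserved_households <- function(cs, year) {
  stratum_population(cs, year) / cs$household_size * cs$share_no_facility
}

#' Limited-service households by limiting factor
#'
#' Splits the stratum's "limited" households (facility present but soap
#' and/or water missing) into the three limiting-factor groups.
#'
#' @inheritParams unserved_households
#' @return Named vector `c(soap_only, water_only, both_missing)`.
#' @export
limited_households_by_factor <- function(cs, year) {
  hh <- stratum_population(cs, year) / cs$household_size * cs$share_limited
  c(soap_only = hh * cs$limited_soap_only,
    water_only = hh * cs$limited_water_only,
    both_missing = hh * cs$limited_both)
}

#' Newly served households in an implementation year
#'
#' Under the cohort scale-up, the cumulative served fraction after year `t`
#' is `t / horizon` applied to that year's unserved household stock (from
#' year-`t` population projections); the year-`t` cohort is the successive
#' difference. Under constant population this is exactly `1 / horizon` of
#' the stock per year, and the increments always telescope to the final
#' year's unserved stock.
#'
#' @param cs One row of a quantity table.
#' @param year_index Implementation year, `1..horizon`.
#' @param params A [cost_parameters()] object.
#' @return Newly served household count.
#' @export
cohort_increment <- function(cs, year_index, params) {
  h <- params$horizon
  if (year_index < 1 || year_index > h) {
    rlang::abort(paste0("year_index must be in 1..", h),
                 class = "hygienecost_validation_error")
  }
  served <- function(t) {
    if (t == 0) return(0)
    unserved_households(cs, params$base_year + t - 1) * t / h
  }
  served(year_index) - served(year_index - 1)
}

# All-years increment vector for an arbitrary household stock (stock(year)
# returns the year's stock); shared by the cost engine for no-facility,
# whole-population and limited-service scale-ups.
increment_schedule <- function(stock_by_year, params) {
  h <- params$horizon
  years <- params$base_year + seq_len(h) - 1L
  served <- vapply(seq_len(h), function(t) stock_by_year(years[t]) * t / h, numeric(1))
  diff(c(0, served))
}
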