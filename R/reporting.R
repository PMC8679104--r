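#' Write the report files for a model run
#'
#' Produces the presentation surfaces of a run: `summary.json` (category
#' totals with shares and, when a Monte Carlo result is supplied, 95%
#' uncertainty intervals; the headline block with the 10-year total,
#' promotion-only and facilities-and-supplies totals, capital/recurrent
#' split, per-head and per-household figures), `by_year.csv` (the
#' discounted year-by-category cost matrix) and, when streams are
#' available, `streams.csv` (the long cost stream). Rendering is a pure
#' function of the already-computed objects — nothing is recomputed.
#'
#' @param model A `hygienecost_model` from [evaluate_model()], or a bare
#'   `cost_summary`.
#' @param mc Optional `mc_result` from [run_monte_carlo()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
render_summary <- function(model, mc = NULL, dir) {
  if (inherits(model, "hygienecost_model")) {
    summary <- model$summary
    streams <- model$streams
  } else {
    summary <- model
    streams <- NULL
  }
  if (is.null(summary$totals)) {
    rlang::abort("aggregation incomplete: no category totals to render.",
                 class = "hygienecost_validation_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  blocks <- list(
    currency = "usd_2019",
    horizon_years = summary$horizon,
    headline = summary$report,
    totals_usd_2019 = as.list(summary$totals),
    grand_total_usd_2019 = summary$grand_total,
    shares_pct = as.list(summary$shares_pct),
    capital_recurrent = list(
      capital_usd_2019 = summary$capital_total,
      recurrent_usd_2019 = summary$recurrent_total,
      capital_share_pct = summary$capital_share_pct
    ),
    promotion_only_usd_2019 = summary$promotion_only_total,
    facilities_supplies_usd_2019 = summary$facilities_supplies_total
  )
  if (!is.null(summary$per_head)) blocks$per_head <- summary$per_head
  if (!is.null(summary$per_household)) blocks$per_household <- summary$per_household
  if (!is.null(mc)) {
    blocks$uncertainty = list(
      n_draws = mc$config$n_draws,
      seed = mc$seed_used,
      interval_pct = mc$config$interval,
      total_usd_2019 = list(point = mc$point_estimates$total,
                            lower = mc$intervals$total[1],
                            upper = mc$intervals$total[2]),
      promotion_only_usd_2019 = list(point = mc$point_estimates$promotion_only,
                                     lower = mc$intervals$promotion_only[1],
                                     upper = mc$intervals$promotion_only[2]),
      facilities_supplies_usd_2019 = list(
        point = mc$point_estimates$facilities_supplies,
        lower = mc$intervals$facilities_supplies[1],
        upper = mc$intervals$facilities_supplies[2])
    )
  }

  paths <- c(summary = file.path(dir, "summary.json"))
  jsonlite::write_json(blocks, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (!is.null(summary$by_year)) {
    by_year <- tibble::as_tibble(summary$by_year, rownames = "category")
    names(by_year)[-1] <- paste0("year_", names(by_year)[-1])
    paths[["by_year"]] <- file.path(dir, "by_year.csv")
    readr::write_csv(by_year, paths[["by_year"]])
  }
  if (!is.null(streams)) {
    paths[["streams"]] <- file.path(dir, "streams.csv")
    readr::write_csv(streams, paths[["streams"]])
  }
  if (!is.null(mc)) {
    paths[["draws"]] <- file.path(dir, "draws.csv")
    readr::write_csv(mc$draws, paths[["draws"]])
  }
  invisible(paths)
}

#' @export
print.cost_summary <- function(x, ...) {
  r <- x$report
  cat("Cost summary (2019 US$, discounted, ", x$horizon, "-year horizon)\n",
      sep = "")
  cat(sprintf("  Total:                 US$%.1f billion\n", r$total_usd_billion))
  cat(sprintf("  Promotion only:        US$%.1f billion\n",
              r$promotion_only_usd_billion))
  cat(sprintf("  Facilities & supplies: US$%.1f billion\n",
              r$facilities_supplies_usd_billion))
  cat(sprintf("  Capital share:         %d%%\n", r$capital_share_pct))
  cat("  Average annual cost by category (US$ million):\n")
  for (nm in names(r$average_annual_usd_million)) {
    cat(sprintf("    %-10s %8.4g  (%d%%)\n", nm,
                r$average_annual_usd_million[[nm]], x$shares_pct[[nm]]))
  }
  invisible(x)
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo result: %d draws (seed %d)\n  total: US$%.2f billion (%g%%-%g%% interval: %.2f-%.2f)\n",
    x$config$n_draws, x$seed_used, x$point_estimate / 1e9,
    x$config$interval[1], x$config$interval[2],
    x$ci_lower / 1e9, x$ci_upper / 1e9))
  invisible(x)
}
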