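stream_categories <- c("formative", "promotion", "hwf", "topup", "soap", "water")
capital_categories <- c("formative", "promotion", "hwf")
recurrent_categories <- c("topup", "soap", "water")

#' Cumulative served fraction per implementation year
#'
#' The scale-up serves equal cohorts of the unserved stock each year:
#' `1/h, 2/h, ..., 1` over an `h`-year horizon.
#'
#' @param horizon Scale-up horizon in years (>= 1).
#' @return Numeric vector of cumulative served fractions.
#' @export
service_schedule <- function(horizon) {
  if (horizon < 1) {
    rlang::abort("`horizon` must be >= 1.", class = "hygienecost_validation_error")
  }
  seq_len(horizon) / horizon
}

#' Per-household cost multipliers for one cohort
#'
#' For a cohort first served in year `service_year`, returns the multiplier
#' applied to the category's per-household price in each year of the
#' horizon:
#' \itemize{
#'   \item `promotion` and `hwf`: 1 in the service year and at every
#'     repeat purchase (end of useful life) within the horizon;
#'   \item `topup`: `topup_fraction` in every later year that is not a full
#'     promotion repeat year (top-up and a full repeat in the same year
#'     would double-count);
#'   \item `soap` and `water`: 1 in every year from the service year on.
#' }
#' Formative research is a one-off country-level investment and is not a
#' per-cohort cost.
#'
#' @param category One of `"promotion"`, `"topup"`, `"hwf"`, `"soap"`,
#'   `"water"`.
#' @param service_year Year the cohort is first served, `1..horizon`.
#' @param params A [cost_parameters()] object.
#' @return Numeric vector of length `horizon`.
#' @export
cohort_cost_profile <- function(category, service_year, params) {
  h <- params$horizon
  if (service_year < 1 || service_year > h) {
    rlang::abort(paste0("service_year must be in 1..", h),
                 class = "hygienecost_validation_error")
  }
  years <- seq_len(h)
  promo_years <- seq(service_year, h, by = params$promo_life)
  switch(category,
    promotion = as.numeric(years %in% promo_years),
    hwf = as.numeric(years %in% seq(service_year, h, by = params$hwf_life)),
    topup = params$topup_fraction *
      as.numeric(years > service_year & !(years %in% promo_years)),
    soap = ,
    water = as.numeric(years >= service_year),
    rlang::abort(paste0("unknown category '", category,
                        "' (formative research is costed at country level)."),
                 class = "hygienecost_validation_error")
  )
}

# Effective priced household-events per year: q(t) = sum_s inc[s] * M[s, t].
cohort_quantity <- function(increments, category, params) {
  h <- params$horizon
  q <- numeric(h)
  for (s in seq_len(h)) {
    if (increments[s] != 0) {
      q <- q + increments[s] * cohort_cost_profile(category, s, params)
    }
  }
  q
}

#' Undiscounted cost streams for one country stratum
#'
#' Applies the cohort scale-up to the stratum's unserved stock and prices
#' each category's purchase events. Promotion and top-up may instead target
#' all households (`promotion_target = "whole_population"`), and
#' limited-service households' soap/water needs can be added per their
#' limiting factor (soap missing, water missing, or both). Under the
#' economies-of-scale scenario, promotion (and top-up), HWF and soap prices
#' fall with the implementation year per [apply_scale_economies()].
#'
#' @param cs One row of a quantity table.
#' @param prices Named vector of this country's 2019 US$ unit prices:
#'   `promotion` (per household campaign cost), `hwf`, `soap` (annual).
#' @param params A [cost_parameters()] object.
#' @param scenario A [scenario_spec()] object.
#' @param water_price Annual household water price for this stratum
#'   (2019 US$); computed with [annual_water_price()] when omitted.
#' @return Long tibble `country_code, setting, category, year, cost_usd2019`.
#' @export
country_cost_stream <- function(cs, prices, params, scenario = scenario_spec(),
                                water_price = NULL) {
  for (nm in c("promotion", "hwf", "soap")) {
    if (is.na(prices[nm])) {
      rlang::abort(paste0("missing price for required category '", nm, "'."),
                   class = "hygienecost_validation_error")
    }
  }
  if (is.null(water_price)) water_price <- annual_water_price(cs, params)
  h <- params$horizon

  inc_nf <- increment_schedule(function(y) unserved_households(cs, y), params)
  inc_promo <- if (scenario$promotion_target == "whole_population") {
    increment_schedule(function(y) stratum_population(cs, y) / cs$household_size,
                       params)
  } else {
    inc_nf
  }

  q_soap <- cohort_quantity(inc_nf, "soap", params)
  q_water <- cohort_quantity(inc_nf, "water", params)
  if (scenario$include_limited_supplies) {
    lim_soap <- increment_schedule(function(y) {
      lf <- limited_households_by_factor(cs, y)
      lf[["soap_only"]] + lf[["both_missing"]]
    }, params)
    lim_water <- increment_schedule(function(y) {
      lf <- limited_households_by_factor(cs, y)
      lf[["water_only"]] + lf[["both_missing"]]
    }, params)
    q_soap <- q_soap + cohort_quantity(lim_soap, "soap", params)
    q_water <- q_water + cohort_quantity(lim_water, "water", params)
  }

  scale_mult <- if (scenario$economies_of_scale) {
    vapply(seq_len(h), function(t) apply_scale_economies(1, t), numeric(1))
  } else {
    rep(1, h)
  }

  costs <- list(
    promotion = prices[["promotion"]] * cohort_quantity(inc_promo, "promotion", params) * scale_mult,
    topup = prices[["promotion"]] * cohort_quantity(inc_promo, "topup", params) * scale_mult,
    hwf = prices[["hwf"]] * cohort_quantity(inc_nf, "hwf", params) * scale_mult,
    soap = prices[["soap"]] * q_soap * scale_mult,
    water = water_price * q_water
  )
  purrr::imap_dfr(costs, function(v, cat) {
    tibble::tibble(country_code = cs$country_code, setting = cs$setting,
                   category = cat, year = seq_len(h), cost_usd2019 = v)
  })
}

#' Cost streams for a whole quantity table
#'
#' Runs [country_cost_stream()] for every stratum and adds each country's
#' one-off formative-research investment (booked nationally in year 1).
#'
#' @param quantities Quantity table.
#' @param local_prices Tibble `country_code, category, usd_2019` from
#'   [localize_prices()]; the promotion price follows
#'   `scenario$promotion_mode`.
#' @param params A [cost_parameters()] object.
#' @param scenario A [scenario_spec()] object.
#' @return Long tibble of undiscounted streams.
#' @export
build_cost_streams <- function(quantities, local_prices, params,
                               scenario = scenario_spec()) {
  promo_cat <- if (scenario$promotion_mode == "alternative") {
    "promotion_alternative"
  } else {
    "promotion_base"
  }
  wide <- local_prices |>
    tidyr::pivot_wider(names_from = "category", values_from = "usd_2019")
  for (nm in c(promo_cat, "hwf", "soap_annual", "formative_research")) {
    if (!nm %in% names(wide)) {
      rlang::abort(paste0("missing price for required category '", nm, "'."),
                   class = "hygienecost_validation_error")
    }
  }

  strata <- purrr::map_dfr(seq_len(nrow(quantities)), function(i) {
    cs <- quantities[i, ]
    w <- wide[wide$country_code == cs$country_code, ]
    if (nrow(w) != 1) {
      rlang::abort(paste0("no localised prices for ", cs$country_code),
                   class = "hygienecost_validation_error")
    }
    country_cost_stream(
      cs,
      prices = c(promotion = w[[promo_cat]], hwf = w[["hwf"]],
                 soap = w[["soap_annual"]]),
      params = params, scenario = scenario
    )
  })

  formative <- wide |>
    dplyr::filter(.data$country_code %in% unique(quantities$country_code)) |>
    dplyr::transmute(.data$country_code, setting = "national",
                     category = "formative", year = 1L,
                     cost_usd2019 = .data$formative_research)
  formative <- tidyr::complete(
    formative,
    country_code = unique(quantities$country_code),
    setting = "national", category = "formative",
    year = seq_len(params$horizon), fill = list(cost_usd2019 = 0)
  )
  dplyr::bind_rows(strata, formative)
}

#' Discount a cost stream to year 1
#'
#' `discounted(t) = cost(t) / (1 + rate)^(t - 1)`: year-1 costs are
#' undiscounted (start-of-year accrual).
#'
#' @param streams Long stream tibble with `year` and `cost_usd2019`.
#' @param rate Annual discount rate (>= 0).
#' @return `streams` with an added `discounted_usd2019` column.
#' @export
discount_stream <- function(streams, rate) {
  if (rate < 0) {
    rlang::abort("`rate` must be >= 0.", class = "hygienecost_validation_error")
  }
  streams$discounted_usd2019 <- streams$cost_usd2019 / (1 + rate)^(streams$year - 1)
  streams
}

#' Summarise 10-year discounted totals from category totals
#'
#' The headline aggregation: grand total; per-category averages and integer
#' percentage shares; the capital/recurrent split (capital: formative
#' research, initial promotion, HWF purchases; recurrent: top-up promotion,
#' soap, water); the promotion-only total (formative + initial + top-up) and
#' the facilities-and-supplies total (HWF + soap + water); and optional
#' per-head figures. A `report` block applies the reporting conventions:
#' billions to 1 decimal, shares to the nearest integer percent, millions to
#' 3 significant figures.
#'
#' @param category_totals Named vector of discounted 10-year totals (US$)
#'   for the six categories `formative, promotion, hwf, topup, soap, water`
#'   (missing categories count as zero).
#' @param horizon Horizon in years (for annual averages).
#' @param population Optional population denominator for per-head figures.
#' @return A `cost_summary` list.
#' @export
summarize_costs <- function(category_totals, horizon = 10, population = NULL) {
  if (length(category_totals) == 0) {
    rlang::abort("no cost categories to summarise.",
                 class = "hygienecost_validation_error")
  }
  totals <- stats::setNames(numeric(length(stream_categories)), stream_categories)
  totals[names(category_totals)] <- category_totals
  grand <- sum(totals)
  if (grand <= 0) {
    rlang::abort("grand total must be positive.",
                 class = "hygienecost_validation_error")
  }
  shares_pct <- round(100 * totals / grand)
  capital <- sum(totals[capital_categories])
  recurrent <- sum(totals[recurrent_categories])
  promotion_only <- totals[["formative"]] + totals[["promotion"]] + totals[["topup"]]
  facilities_supplies <- totals[["hwf"]] + totals[["soap"]] + totals[["water"]]

  out <- list(
    totals = totals,
    grand_total = grand,
    average_annual = totals / horizon,
    average_annual_total = grand / horizon,
    shares_pct = shares_pct,
    capital_total = capital,
    recurrent_total = recurrent,
    capital_share_pct = round(100 * capital / grand),
    promotion_only_total = promotion_only,
    facilities_supplies_total = facilities_supplies,
    horizon = horizon
  )
  if (!is.null(population)) {
    out$per_head <- list(
      population = population,
      promotion_annual_usd = promotion_only / horizon / population,
      facilities_supplies_annual_usd = facilities_supplies / horizon / population,
      total_annual_usd = grand / horizon / population
    )
  }
  out$report <- list(
    total_usd_billion = round(grand / 1e9, 1),
    promotion_only_usd_billion = round(promotion_only / 1e9, 1),
    facilities_supplies_usd_billion = round(facilities_supplies / 1e9, 1),
    capital_share_pct = out$capital_share_pct,
    shares_pct = shares_pct,
    average_annual_usd_million = signif(totals / horizon / 1e6, 3)
  )
  structure(out, class = "cost_summary")
}

#' Aggregate cost streams into the headline summary
#'
#' @param streams Discounted stream tibble from [discount_stream()].
#' @param params A [cost_parameters()] object.
#' @param population Optional per-head denominator.
#' @return A `cost_summary` list with an added `by_year` matrix
#'   (category x year, discounted US$) and `by_year_undiscounted`.
#' @export
aggregate_total <- function(streams, params, population = NULL) {
  if (is.null(streams) || nrow(streams) == 0) {
    rlang::abort("empty stream set.", class = "hygienecost_validation_error")
  }
  totals <- streams |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(total = sum(.data$discounted_usd2019), .groups = "drop")
  summary <- summarize_costs(stats::setNames(totals$total, totals$category),
                             horizon = params$horizon, population = population)
  by_year <- function(col) {
    m <- streams |>
      dplyr::group_by(.data$category, .data$year) |>
      dplyr::summarise(v = sum(.data[[col]]), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "year", values_from = "v", values_fill = 0)
    cats <- m$category
    m <- as.matrix(m[-1])
    rownames(m) <- cats
    m[intersect(stream_categories, cats), order(as.integer(colnames(m))), drop = FALSE]
  }
  summary$by_year <- by_year("discounted_usd2019")
  summary$by_year_undiscounted <- by_year("cost_usd2019")
  summary
}

#' Annual soap and water cost for limited-service households
#'
#' The full-stock annual requirement (no scale-up): soap for households
#' missing soap only or both, water for households missing water only or
#' both, priced at each country's soap price and each stratum's water price.
#'
#' @param quantities Quantity table.
#' @param local_prices Localised price tibble (needs `soap_annual`).
#' @param params A [cost_parameters()] object.
#' @param year Calendar year of the stock (default base year).
#' @return List with `total`, `soap`, `water` (US$/year) and `soap_share`.
#' @export
limited_supplies_annual_cost <- function(quantities, local_prices, params,
                                         year = params$base_year) {
  soap_prices <- local_prices |>
    dplyr::filter(.data$category == "soap_annual")
  per_stratum <- purrr::map_dfr(seq_len(nrow(quantities)), function(i) {
    cs <- quantities[i, ]
    lf <- limited_households_by_factor(cs, year)
    sp <- soap_prices$usd_2019[soap_prices$country_code == cs$country_code]
    tibble::tibble(
      soap = (lf[["soap_only"]] + lf[["both_missing"]]) * sp,
      water = (lf[["water_only"]] + lf[["both_missing"]]) * annual_water_price(cs, params)
    )
  })
  soap <- sum(per_stratum$soap)
  water <- sum(per_stratum$water)
  list(total = soap + water, soap = soap, water = water,
       soap_share = soap / (soap + water))
}

#' Evaluate the deterministic costing model
#'
#' Localises pooled category prices to each country, constructs per-stratum
#' water prices, builds and discounts the cost streams, and aggregates to
#' the headline summary. The returned object carries everything the Monte
#' Carlo and scenario layers need to re-price the model.
#'
#' @param quantities Quantity table.
#' @param dists Price distribution tibble (pooled I$ means / SEs).
#' @param factors Economic factor table.
#' @param params A [cost_parameters()] object.
#' @param scenario A [scenario_spec()] object.
#' @return A `hygienecost_model` list: `summary`, `streams`, `dists`,
#'   `local_prices`, `per_household` medians, `population`, plus the inputs.
#' @export
evaluate_model <- function(quantities, dists, factors,
                           params = cost_parameters(),
                           scenario = scenario_spec()) {
  local_prices <- localize_prices(dists, factors)
  streams <- build_cost_streams(quantities, local_prices, params, scenario)
  streams <- discount_stream(streams, params$discount_rate)

  years <- params$base_year + seq_len(params$horizon) - 1L
  pop <- mean(vapply(years, function(y) sum(quantities[[paste0("pop_", y)]]),
                     numeric(1)))
  summary <- aggregate_total(streams, params, population = pop)

  med <- function(cat) {
    stats::median(local_prices$usd_2019[local_prices$category == cat])
  }
  water_prices <- vapply(seq_len(nrow(quantities)),
                         function(i) annual_water_price(quantities[i, ], params),
                         numeric(1))
  summary$per_household <- list(
    hwf_usd_median = med("hwf"),
    soap_annual_usd_median = med("soap_annual"),
    promotion_usd_median = med(if (scenario$promotion_mode == "alternative")
      "promotion_alternative" else "promotion_base"),
    water_annual_usd_median = stats::median(water_prices)
  )

  structure(
    list(summary = summary, streams = streams, dists = dists,
         local_prices = local_prices, factors = factors,
         quantities = quantities, params = params, scenario = scenario,
         population = pop),
    class = "hygienecost_model"
  )
}

#' Run the base-case model on a fixture
#'
#' Standardises the raw price datapoints, pools them into gamma-prior
#' category distributions, and evaluates the deterministic model.
#'
#' @param fixture List with `quantities`, `prices` (raw datapoints) and
#'   `factors`, e.g. from [reference_fixture()].
#' @param params A [cost_parameters()] object.
#' @param scenario A [scenario_spec()] object.
#' @param fallback_cv Passed to [pool_price_table()].
#' @return A `hygienecost_model` list (see [evaluate_model()]).
#' @export
run_base_case <- function(fixture, params = cost_parameters(),
                          scenario = scenario_spec(), fallback_cv = NULL) {
  std <- standardize_prices(fixture$prices, fixture$factors)
  dists <- pool_price_table(std, fallback_cv = fallback_cv)
  evaluate_model(fixture$quantities, dists, fixture$factors, params, scenario)
}
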