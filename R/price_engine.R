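price_categories <- c("promotion_base", "promotion_alternative", "hwf",
                      "hwf_homemade", "soap_annual", "formative_research")

#' Load a price datapoint table from CSV
#'
#' Columns: `category, amount, currency, price_year, country_code, scope,
#' source_id`. Amounts are in the original currency of the source study;
#' `currency = "USD"` marks datapoints reported in US dollars, anything
#' else is read as the study country's local currency unit.
#'
#' @param path CSV file path.
#' @return A tibble of price points.
#' @export
load_price_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "hygienecost_schema_error")
  }
  points <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("category", "amount", "currency", "price_year", "country_code", "scope")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("missing required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "hygienecost_schema_error")
  }
  bad <- setdiff(unique(points$category), price_categories)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown price categories: ", paste(bad, collapse = ", ")),
                 class = "hygienecost_validation_error")
  }
  if (any(points$amount <= 0)) {
    rlang::abort("price amounts must be > 0.", class = "hygienecost_validation_error")
  }
  if (any(points$price_year < 1990 | points$price_year > 2030)) {
    rlang::abort("price_year outside [1990, 2030].",
                 class = "hygienecost_validation_error")
  }
  points
}

#' Load an economic factor table from CSV
#'
#' Long format: `country_code, year, deflator, ppp_lcu_per_int_dollar,
#' fx_lcu_per_usd`. The GDP deflator is indexed to 2019 = 100; purchasing
#' power parity (PPP) and market exchange-rate factors are local currency
#' units per international dollar and per US dollar respectively.
#'
#' @param path CSV file path.
#' @return A tibble of economic factors.
#' @export
load_factor_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "hygienecost_schema_error")
  }
  factors <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("country_code", "year", "deflator", "ppp_lcu_per_int_dollar",
                "fx_lcu_per_usd")
  missing_cols <- setdiff(required, names(factors))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("missing required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "hygienecost_schema_error")
  }
  if (any(factors$deflator <= 0 | factors$ppp_lcu_per_int_dollar <= 0 |
            factors$fx_lcu_per_usd <= 0)) {
    rlang::abort("economic factors must be strictly positive.",
                 class = "hygienecost_validation_error")
  }
  factors
}

factor_at <- function(factors, country_code, year, what) {
  i <- which(factors$country_code == country_code & factors$year == year)
  if (length(i) != 1) {
    rlang::abort(paste0("no ", what, " for ", country_code, " in ", year),
                 class = "hygienecost_validation_error")
  }
  factors[[what]][i]
}

#' Standardise one price datapoint to 2019 international dollars
#'
#' The datapoint is first expressed in the study country's local currency
#' (datapoints reported in US dollars are converted at the price-year
#' exchange rate), then inflated to 2019 prices with the country's GDP
#' deflator, then converted to international dollars (I$) at the 2019 PPP
#' factor. Pooling across countries happens on this common I$ scale because
#' a US$ mean would be biased by purchasing-power differences.
#'
#' @param amount Price in the original currency.
#' @param currency Currency code; `"USD"` triggers conversion to local
#'   currency at the price-year exchange rate, anything else is taken to be
#'   the country's local currency unit.
#' @param price_year Calendar year of the price.
#' @param country_code Study country.
#' @param factors Economic factor table from [load_factor_table()] or
#'   [generate_economic_factors()].
#' @return The amount in 2019 I$.
#' @export
standardize_price <- function(amount, currency, price_year, country_code, factors) {
  if (amount <= 0) {
    rlang::abort("amount must be > 0.", class = "hygienecost_validation_error")
  }
  lcu <- if (identical(currency, "USD")) {
    amount * factor_at(factors, country_code, price_year, "fx_lcu_per_usd")
  } else {
    amount
  }
  defl_then <- factor_at(factors, country_code, price_year, "deflator")
  defl_2019 <- factor_at(factors, country_code, 2019L, "deflator")
  lcu_2019 <- lcu * defl_2019 / defl_then
  lcu_2019 / factor_at(factors, country_code, 2019L, "ppp_lcu_per_int_dollar")
}

#' Standardise a whole price table
#'
#' @param points Price point tibble (see [load_price_table()]).
#' @param factors Economic factor table.
#' @return `points` with an added `i2019` column (2019 I$).
#' @export
standardize_prices <- function(points, factors) {
  points$i2019 <- purrr::pmap_dbl(
    points[c("amount", "currency", "price_year", "country_code")],
    function(amount, currency, price_year, country_code) {
      standardize_price(amount, currency, price_year, country_code, factors)
    }
  )
  points
}

#' Moment-matched gamma parameters
#'
#' Shape `(mean/se)^2` and scale `se^2/mean`, so that the gamma's mean and
#' standard deviation reproduce the inputs exactly. Price data are
#' right-skewed, so pooled category means are given gamma priors.
#'
#' @param mean,se Positive mean and standard error.
#' @return Named vector `c(shape, scale)`.
#' @export
gamma_from_moments <- function(mean, se) {
  if (any(mean <= 0) || any(se <= 0)) {
    rlang::abort("`mean` and `se` must be > 0.", class = "hygienecost_validation_error")
  }
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Pool standardised prices into a category distribution
#'
#' The pooled estimate is the sample mean of the I$-standardised datapoints
#' with standard error `sd / sqrt(n)`; a gamma prior is moment-matched to
#' `(mean, se)`. For a single datapoint the SE is imputed as
#' `mean * fallback_cv` and the result is flagged.
#'
#' @param values Standardised amounts (2019 I$).
#' @param category Cost category label.
#' @param fallback_cv Coefficient of variation used to impute an SE when
#'   only one datapoint exists (see [pool_price_table()] for the pooled-CV
#'   default).
#' @return One-row tibble: `category, i_mean, i_se, gamma_shape,
#'   gamma_scale, n_points, se_imputed`.
#' @export
pool_prices <- function(values, category, fallback_cv = NULL) {
  if (length(values) < 1) {
    rlang::abort("at least one datapoint is required.",
                 class = "hygienecost_validation_error")
  }
  i_mean <- mean(values)
  imputed <- FALSE
  if (length(values) == 1) {
    if (is.null(fallback_cv) || fallback_cv <= 0) {
      rlang::abort(paste0("category '", category, "' has a single datapoint; ",
                          "supply a positive `fallback_cv` to impute its SE."),
                   class = "hygienecost_validation_error")
    }
    i_se <- i_mean * fallback_cv
    imputed <- TRUE
  } else {
    i_se <- stats::sd(values) / sqrt(length(values))
  }
  if (i_se <= 0) {
    rlang::abort(paste0("category '", category, "' has zero price dispersion; ",
                        "a gamma prior is degenerate. Apply a minimum-SE floor ",
                        "to the inputs or supply more varied datapoints."),
                 class = "hygienecost_validation_error")
  }
  g <- gamma_from_moments(i_mean, i_se)
  tibble::tibble(
    category = category, i_mean = i_mean, i_se = i_se,
    gamma_shape = g[["shape"]], gamma_scale = g[["scale"]],
    n_points = length(values), se_imputed = imputed
  )
}

#' Pool every category in a standardised price table
#'
#' Applies [pool_prices()] per category. When `fallback_cv` is `NULL`, the
#' fallback for single-datapoint categories is the median coefficient of
#' variation (sd/mean of datapoints) across categories with two or more
#' datapoints — an explicit, conservative prior for sparse categories.
#'
#' @param std_points Output of [standardize_prices()].
#' @param fallback_cv Optional override for the single-datapoint SE rule.
#' @return Tibble of per-category price distributions.
#' @export
pool_price_table <- function(std_points, fallback_cv = NULL) {
  if (is.null(fallback_cv)) {
    cvs <- std_points |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(n = dplyr::n(),
                       cv = stats::sd(.data$i2019) / mean(.data$i2019),
                       .groups = "drop") |>
      dplyr::filter(.data$n >= 2)
    if (nrow(cvs) > 0) fallback_cv <- stats::median(cvs$cv)
  }
  std_points |>
    dplyr::group_by(.data$category) |>
    dplyr::group_map(~ pool_prices(.x$i2019, .y$category, fallback_cv = fallback_cv)) |>
    dplyr::bind_rows()
}

#' Construct a price distribution from stated moments
#'
#' Convenience constructor used for user-supplied or degenerate (zero-SE)
#' distributions; `i_se = 0` yields a point mass (no gamma parameters).
#'
#' @param category Cost category label.
#' @param i_mean Pooled mean, 2019 I$.
#' @param i_se Standard error of the mean, 2019 I$ (>= 0).
#' @param n_points Number of underlying datapoints (informational).
#' @return One-row distribution tibble as in [pool_prices()].
#' @export
make_price_distribution <- function(category, i_mean, i_se, n_points = NA_integer_) {
  if (i_mean <= 0 || i_se < 0) {
    rlang::abort("`i_mean` must be > 0 and `i_se` >= 0.",
                 class = "hygienecost_validation_error")
  }
  if (i_se == 0) {
    g <- c(shape = NA_real_, scale = NA_real_)
  } else {
    g <- gamma_from_moments(i_mean, i_se)
  }
  tibble::tibble(category = category, i_mean = i_mean, i_se = i_se,
                 gamma_shape = g[["shape"]], gamma_scale = g[["scale"]],
                 n_points = n_points, se_imputed = FALSE)
}

#' Re-localise a pooled I$ price to a country's 2019 US$
#'
#' `usd_2019 = i_mean * ppp / fx` with 2019 factors: the same basket of
#' goods costs fewer US dollars where the price level (PPP/market-rate
#' ratio) is low.
#'
#' @param i_mean Pooled price in 2019 I$.
#' @param country_code Country to localise to.
#' @param factors Economic factor table.
#' @return Price in 2019 US$.
#' @export
localize_price <- function(i_mean, country_code, factors) {
  ppp <- factor_at(factors, country_code, 2019L, "ppp_lcu_per_int_dollar")
  fx <- factor_at(factors, country_code, 2019L, "fx_lcu_per_usd")
  i_mean * ppp / fx
}

#' Localise every pooled category price to every country
#'
#' @param dists Distribution tibble from [pool_price_table()].
#' @param factors Economic factor table.
#' @return Tibble `country_code, category, usd_2019`.
#' @export
localize_prices <- function(dists, factors) {
  f19 <- factors |> dplyr::filter(.data$year == 2019L)
  tidyr::crossing(country_code = unique(f19$country_code),
                  category = dists$category) |>
    dplyr::left_join(dists[c("category", "i_mean")], by = "category") |>
    dplyr::left_join(f19[c("country_code", "ppp_lcu_per_int_dollar", "fx_lcu_per_usd")],
                     by = "country_code") |>
    dplyr::mutate(usd_2019 = .data$i_mean * .data$ppp_lcu_per_int_dollar /
                    .data$fx_lcu_per_usd) |>
    dplyr::select("country_code", "category", "usd_2019")
}

#' Annual household water price for handwashing
#'
#' Water for handwashing is assumed to average `water_lpd` litres per person
#' per day. The annual household volume is priced at a weighted unit cost
#' over piped and non-piped supplies, reflecting the share of the stratum's
#' population using piped improved water. Unit costs are 2019 US$ per cubic
#' metre, so no currency conversion is applied.
#'
#' @param cs One row of a quantity table.
#' @param params A [cost_parameters()] object.
#' @return 2019 US$ per household per year.
#' @export
annual_water_price <- function(cs, params) {
  if (any(cs$piped_unit_cost < 0) || any(cs$nonpiped_unit_cost < 0)) {
    rlang::abort("water unit costs must be >= 0.",
                 class = "hygienecost_validation_error")
  }
  volume_m3 <- params$water_lpd * cs$household_size * 365 / 1000
  volume_m3 * (cs$piped_share * cs$piped_unit_cost +
                 (1 - cs$piped_share) * cs$nonpiped_unit_cost)
}
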