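#' Configuration for the synthetic data generator
#'
#' Defines the study conditions the generator emulates: 46 LDC-like
#' countries split into urban/rural strata, household sizes smaller in
#' urban areas, exponential population growth, hygiene service breakdowns
#' with a rural skew towards "no facility", limited-service splits centred
#' on the observed 47/10/43 soap-only/water-only/both-missing averages,
#' right-skewed price datapoints whose localised medians track the
#' published per-household anchors, and economic factors with LDC-like
#' price levels (PPP/exchange-rate ratio well below 1).
#'
#' @param n_countries Number of countries (>= 1).
#' @param seed Integer seed; all generator output is deterministic in it.
#' @param urban_share_range Urban population share interval.
#' @param household_size_urban,household_size_rural Household size intervals
#'   (persons); urban below rural.
#' @param growth_rate_range Annual population growth interval.
#' @param coverage_concentration Dirichlet-style concentration of the
#'   service breakdown (higher = less spread).
#' @param price_anchor_medians Named US$ per-household anchors for the
#'   localised price medians.
#' @param formative_anchor_mean Localised mean anchor for formative
#'   research (US$ per country).
#' @param price_cv Coefficient of variation of the price-generating gammas.
#' @param price_counts Datapoints per category.
#' @param deflator_inflation_range Annual inflation interval behind the GDP
#'   deflator series.
#' @param ppp_fx_ratio_range Interval for the PPP/exchange-rate ratio
#'   (price level; < 1 in low-income economies).
#' @param mean_country_population Mean 2021 country population.
#' @param n_missing_service Number of countries generated with missing
#'   service shares (to exercise imputation); 0 by default.
#' @param base_year,horizon Projection window.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_countries = 46L,
                             seed = 4646L,
                             urban_share_range = c(0.15, 0.50),
                             household_size_urban = c(3.5, 5.5),
                             household_size_rural = c(4.5, 7.5),
                             growth_rate_range = c(0.01, 0.03),
                             coverage_concentration = 8,
                             price_anchor_medians = c(promotion_base = 33.9,
                                                      promotion_alternative = 19.4,
                                                      hwf = 14.8,
                                                      soap_annual = 14.8,
                                                      hwf_homemade = 1.2),
                             formative_anchor_mean = 1e5,
                             price_cv = 0.5,
                             price_counts = c(promotion_base = 14L,
                                              promotion_alternative = 8L,
                                              hwf = 16L,
                                              hwf_homemade = 5L,
                                              soap_annual = 10L,
                                              formative_research = 5L),
                             deflator_inflation_range = c(0.02, 0.10),
                             ppp_fx_ratio_range = c(0.24, 0.43),
                             mean_country_population = 24e6,
                             n_missing_service = 0L,
                             base_year = 2021L,
                             horizon = 10L) {
  check_interval <- function(x, nm) {
    if (length(x) != 2 || x[1] > x[2]) {
      rlang::abort(paste0("`", nm, "` must be an ordered interval."),
                   class = "hygienecost_validation_error")
    }
  }
  if (n_countries < 1) {
    rlang::abort("`n_countries` must be >= 1.",
                 class = "hygienecost_validation_error")
  }
  check_interval(urban_share_range, "urban_share_range")
  check_interval(household_size_urban, "household_size_urban")
  check_interval(household_size_rural, "household_size_rural")
  check_interval(growth_rate_range, "growth_rate_range")
  check_interval(deflator_inflation_range, "deflator_inflation_range")
  check_interval(ppp_fx_ratio_range, "ppp_fx_ratio_range")
  if (any(price_anchor_medians <= 0) || formative_anchor_mean <= 0 ||
      price_cv <= 0) {
    rlang::abort("price anchors and `price_cv` must be positive.",
                 class = "hygienecost_validation_error")
  }
  structure(
    list(n_countries = as.integer(n_countries), seed = as.integer(seed),
         urban_share_range = urban_share_range,
         household_size_urban = household_size_urban,
         household_size_rural = household_size_rural,
         growth_rate_range = growth_rate_range,
         coverage_concentration = coverage_concentration,
         price_anchor_medians = price_anchor_medians,
         formative_anchor_mean = formative_anchor_mean,
         price_cv = price_cv, price_counts = price_counts,
         deflator_inflation_range = deflator_inflation_range,
         ppp_fx_ratio_range = ppp_fx_ratio_range,
         mean_country_population = mean_country_population,
         n_missing_service = as.integer(n_missing_service),
         base_year = as.integer(base_year), horizon = as.integer(horizon)),
    class = "synthetic_config"
  )
}

make_country_codes <- function(n) {
  grid <- expand.grid(b = LETTERS, a = LETTERS)
  paste0("Z", grid$a, grid$b)[seq_len(n)]
}

rdirichlet1 <- function(alpha) {
  v <- stats::rgamma(length(alpha), shape = alpha)
  v <- v / sum(v)
  v[length(v)] <- 1 - sum(v[-length(v)])
  v
}

#' Generate a synthetic country quantity table
#'
#' @param config A [synthetic_config()] object.
#' @return A validated quantity table with `2 * n_countries` strata.
#' @export
generate_country_table <- function(config = synthetic_config()) {
  set.seed(config$seed)
  n <- config$n_countries
  codes <- make_country_codes(n)
  years <- config$base_year + seq_len(config$horizon) - 1L

  rows <- purrr::map_dfr(seq_len(n), function(i) {
    pop_2021 <- stats::rlnorm(1, log(config$mean_country_population) - 0.605,
                              sdlog = 1.1)
    urban_share <- stats::runif(1, config$urban_share_range[1],
                                config$urban_share_range[2])
    g_rural <- stats::runif(1, config$growth_rate_range[1],
                            config$growth_rate_range[2])
    g_urban <- g_rural + stats::runif(1, 0, 0.01)

    purrr::map_dfr(c("urban", "rural"), function(setting) {
      urban <- setting == "urban"
      hh_range <- if (urban) config$household_size_urban else config$household_size_rural
      base_props <- if (urban) c(0.25, 0.30, 0.45) else c(0.45, 0.30, 0.25)
      svc <- rdirichlet1(config$coverage_concentration * base_props)
      split <- rdirichlet1(20 * c(0.47, 0.10, 0.43))
      g <- if (urban) g_urban else g_rural
      pop0 <- pop_2021 * (if (urban) urban_share else 1 - urban_share)
      pops <- stats::setNames(as.list(pop0 * (1 + g)^(years - config$base_year)),
                              paste0("pop_", years))
      tibble::tibble(
        country_code = codes[i], setting = setting,
        household_size = stats::runif(1, hh_range[1], hh_range[2]),
        !!!pops,
        share_no_facility = svc[1], share_limited = svc[2], share_basic = svc[3],
        limited_soap_only = split[1], limited_water_only = split[2],
        limited_both = split[3],
        piped_share = if (urban) stats::runif(1, 0.30, 0.70) else stats::runif(1, 0.02, 0.20),
        piped_unit_cost = stats::runif(1, 0.6, 1.4),
        nonpiped_unit_cost = stats::runif(1, 1.2, 2.5),
        provenance = "observed"
      )
    })
  })

  if (config$n_missing_service > 0) {
    blank <- utils::tail(codes, config$n_missing_service)
    idx <- rows$country_code %in% blank
    rows[idx, c(share_cols, split_cols)] <- NA_real_
    rows$provenance[idx] <- NA_character_
  }
  validate_quantity_table(rows,
                          allow_missing_service = config$n_missing_service > 0)
  rows
}

#' Generate synthetic economic factor series
#'
#' Per country: a smooth GDP deflator series (base 2019 = 100) implied by a
#' constant inflation rate, and PPP/exchange-rate factors whose 2019 ratio
#' (the price level) falls in the configured interval; nominal factors
#' drift with the deflator (relative purchasing-power parity).
#'
#' @param config A [synthetic_config()] object.
#' @param years Years to tabulate.
#' @return An economic factor tibble (see [load_factor_table()]).
#' @export
generate_economic_factors <- function(config = synthetic_config(),
                                      years = 2000:2021) {
  set.seed(config$seed + 1L)
  codes <- make_country_codes(config$n_countries)
  purrr::map_dfr(codes, function(code) {
    infl <- stats::runif(1, config$deflator_inflation_range[1],
                         config$deflator_inflation_range[2])
    fx19 <- stats::rlnorm(1, log(500), 1)
    ratio <- stats::runif(1, config$ppp_fx_ratio_range[1],
                          config$ppp_fx_ratio_range[2])
    defl <- 100 * (1 + infl)^(years - 2019)
    tibble::tibble(
      country_code = code, year = years, deflator = defl,
      ppp_lcu_per_int_dollar = ratio * fx19 * defl / 100,
      fx_lcu_per_usd = fx19 * defl / 100
    )
  })
}

#' Generate synthetic price datapoints
#'
#' Per category, datapoints are drawn from a right-skewed gamma on the
#' 2019 I$ scale and then disguised in heterogeneous currencies and price
#' years (local currency of a random country, deflated back to the price
#' year; about a third re-expressed in US dollars at that year's exchange
#' rate) so the standardisation path is fully exercised. The I$ gamma is
#' anchored so that, after pooling and re-localisation, the cross-country
#' median price tracks the configured US$ anchor: its median is
#' `anchor / ratio_mid` where `ratio_mid` is the midpoint of the
#' configured PPP/exchange-rate ratio interval. Formative research is
#' anchored on the localised mean instead (its anchor is stated as a mean).
#'
#' @param config A [synthetic_config()] object.
#' @param factors Economic factor table; generated from `config` when
#'   omitted.
#' @return A price point tibble (see [load_price_table()]).
#' @export
generate_price_points <- function(config = synthetic_config(), factors = NULL) {
  if (is.null(factors)) factors <- generate_economic_factors(config)
  set.seed(config$seed + 2L)
  codes <- unique(factors$country_code)
  ratio_mid <- mean(config$ppp_fx_ratio_range)
  shape <- 1 / config$price_cv^2

  purrr::imap_dfr(as.list(config$price_counts), function(n_pts, category) {
    if (category == "formative_research") {
      target_mean <- config$formative_anchor_mean / ratio_mid
      scale <- target_mean / shape
    } else {
      anchor <- config$price_anchor_medians[[category]]
      target_median <- anchor / ratio_mid
      scale <- target_median / stats::qgamma(0.5, shape = shape, scale = 1)
    }
    i2019 <- stats::rgamma(n_pts, shape = shape, scale = scale)
    # calibrate the sample so its mean sits on the generating gamma's mean:
    # the pooled mean (what the pipeline localises) then tracks the anchor
    # regardless of how few datapoints the category has
    i2019 <- i2019 * (shape * scale) / mean(i2019)
    country <- sample(codes, n_pts, replace = TRUE)
    price_year <- sample(2010:2019, n_pts, replace = TRUE)
    in_usd <- stats::runif(n_pts) < 1 / 3

    purrr::map_dfr(seq_len(n_pts), function(j) {
      ppp19 <- factor_at(factors, country[j], 2019L, "ppp_lcu_per_int_dollar")
      defl_y <- factor_at(factors, country[j], price_year[j], "deflator")
      lcu_y <- i2019[j] * ppp19 * defl_y / 100
      amount <- if (in_usd[j]) {
        lcu_y / factor_at(factors, country[j], price_year[j], "fx_lcu_per_usd")
      } else {
        lcu_y
      }
      tibble::tibble(
        category = category, amount = amount,
        currency = if (in_usd[j]) "USD" else country[j],
        price_year = price_year[j], country_code = country[j],
        scope = if (category == "formative_research") "per_intervention" else "per_household",
        source_id = paste0(category, "_", j)
      )
    })
  })
}

#' The canonical reference fixture ("reference-46")
#'
#' 46 synthetic countries with a fixed seed, used by the tests, the
#' analysis scripts and the acceptance checks so every consumer sees
#' identical inputs without any download.
#'
#' @param seed Fixture seed (fixed by convention).
#' @param n_countries Number of countries.
#' @return List `quantities`, `factors`, `prices`, `config`.
#' @export
reference_fixture <- function(seed = 4646L, n_countries = 46L) {
  config <- synthetic_config(n_countries = n_countries, seed = seed)
  factors <- generate_economic_factors(config)
  list(
    quantities = generate_country_table(config),
    factors = factors,
    prices = generate_price_points(config, factors),
    config = config
  )
}

#' Write a fixture's three CSV tables
#'
#' @param fixture List from [reference_fixture()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_fixture_csvs <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    country = file.path(dir, "country_table.csv"),
    prices = file.path(dir, "price_points.csv"),
    factors = file.path(dir, "economic_factors.csv")
  )
  readr::write_csv(fixture$quantities, paths[["country"]])
  readr::write_csv(fixture$prices, paths[["prices"]])
  readr::write_csv(fixture$factors, paths[["factors"]])
  invisible(paths)
}
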