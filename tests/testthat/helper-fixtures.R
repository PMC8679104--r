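# One-row quantity table with explicit arithmetic-friendly values.
make_stratum <- function(country_code = "ZAA", setting = "rural",
                         household_size = 5, pop = 1e6, growth = 0,
                         no_facility = 0.5, limited = 0.3,
                         basic = 1 - no_facility - limited,
                         soap_only = 0.47, water_only = 0.10, both = 0.43,
                         piped_share = 0.5, piped = 1, nonpiped = 2,
                         base_year = 2021, horizon = 10) {
  years <- base_year + seq_len(horizon) - 1
  pops <- stats::setNames(as.list(pop * (1 + growth)^(years - base_year)),
                          paste0("pop_", years))
  tibble::tibble(
    country_code = country_code, setting = setting,
    household_size = household_size, !!!pops,
    share_no_facility = no_facility, share_limited = limited,
    share_basic = basic, limited_soap_only = soap_only,
    limited_water_only = water_only, limited_both = both,
    piped_share = piped_share, piped_unit_cost = piped,
    nonpiped_unit_cost = nonpiped, provenance = "observed"
  )
}

# Flat economic factors: constant inflation, fixed ppp/fx ratio.
make_factors <- function(codes, ratio = 0.4, fx = 100, infl = 0.05,
                         years = 2000:2021) {
  purrr::map_dfr(codes, function(code) {
    defl <- 100 * (1 + infl)^(years - 2019)
    tibble::tibble(country_code = code, year = years, deflator = defl,
                   ppp_lcu_per_int_dollar = ratio * fx * defl / 100,
                   fx_lcu_per_usd = fx * defl / 100)
  })
}

# Independent brute-force oracle: enumerates every cohort x year purchase
# with explicit modular-arithmetic rules, never calling the engine's
# profile/quantity machinery.
brute_force_streams <- function(quantities, local_prices, params, scenario) {
  h <- params$horizon
  scale_mult <- c(1, 0.90, 0.82, 0.76, 0.72, rep(0.70, max(h - 5, 1)))[seq_len(h)]
  if (!scenario$economies_of_scale) scale_mult <- rep(1, h)
  promo_cat <- if (scenario$promotion_mode == "alternative") {
    "promotion_alternative"
  } else {
    "promotion_base"
  }
  price_of <- function(code, cat) {
    local_prices$usd_2019[local_prices$country_code == code &
                            local_prices$category == cat]
  }
  out <- list()
  for (i in seq_len(nrow(quantities))) {
    cs <- quantities[i, ]
    pops <- sapply(seq_len(h), function(t) cs[[paste0("pop_", params$base_year + t - 1)]])
    U <- pops / cs$household_size * cs$share_no_facility
    inc <- diff(c(0, U * seq_len(h) / h))
    stock_all <- pops / cs$household_size
    inc_all <- diff(c(0, stock_all * seq_len(h) / h))
    inc_p <- if (scenario$promotion_target == "whole_population") inc_all else inc
    lim_soap_stock <- pops / cs$household_size * cs$share_limited *
      (cs$limited_soap_only + cs$limited_both)
    lim_water_stock <- pops / cs$household_size * cs$share_limited *
      (cs$limited_water_only + cs$limited_both)
    inc_lsoap <- diff(c(0, lim_soap_stock * seq_len(h) / h))
    inc_lwater <- diff(c(0, lim_water_stock * seq_len(h) / h))

    p_promo <- price_of(cs$country_code, promo_cat)
    p_hwf <- price_of(cs$country_code, "hwf")
    p_soap <- price_of(cs$country_code, "soap_annual")
    p_water <- annual_water_price(cs, params)

    cost <- matrix(0, nrow = 5, ncol = h,
                   dimnames = list(c("promotion", "topup", "hwf", "soap", "water")))
    for (s in seq_len(h)) {
      for (t in s:h) {
        age <- t - s
        if (age %% params$promo_life == 0) {
          cost["promotion", t] <- cost["promotion", t] +
            inc_p[s] * p_promo * scale_mult[t]
        } else if (t > s) {
          cost["topup", t] <- cost["topup", t] +
            inc_p[s] * p_promo * params$topup_fraction * scale_mult[t]
        }
        if (age %% params$hwf_life == 0) {
          cost["hwf", t] <- cost["hwf", t] + inc[s] * p_hwf * scale_mult[t]
        }
        cost["soap", t] <- cost["soap", t] + inc[s] * p_soap * scale_mult[t]
        cost["water", t] <- cost["water", t] + inc[s] * p_water
        if (scenario$include_limited_supplies) {
          cost["soap", t] <- cost["soap", t] + inc_lsoap[s] * p_soap * scale_mult[t]
          cost["water", t] <- cost["water", t] + inc_lwater[s] * p_water
        }
      }
    }
    for (cat in rownames(cost)) {
      out[[length(out) + 1]] <- tibble::tibble(
        country_code = cs$country_code, setting = cs$setting, category = cat,
        year = seq_len(h), cost_usd2019 = cost[cat, ]
      )
    }
  }
  for (code in unique(quantities$country_code)) {
    out[[length(out) + 1]] <- tibble::tibble(
      country_code = code, setting = "national", category = "formative",
      year = seq_len(h),
      cost_usd2019 = c(price_of(code, "formative_research"), rep(0, h - 1))
    )
  }
  streams <- dplyr::bind_rows(out)
  streams$discounted_usd2019 <- streams$cost_usd2019 /
    (1 + params$discount_rate)^(streams$year - 1)
  streams
}

# Small fixture shared across test files (3 countries keeps everything fast).
tiny_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) {
      fx <<- reference_fixture(seed = 101L, n_countries = 3L)
    }
    fx
  }
})
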