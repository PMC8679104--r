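test_that("service schedule is linear in the horizon", {
  expect_equal(service_schedule(10), seq(0.1, 1, by = 0.1))
  expect_equal(service_schedule(1), 1)
  expect_equal(service_schedule(4), c(0.25, 0.5, 0.75, 1))
  expect_error(service_schedule(0), class = "hygienecost_validation_error")
})

test_that("cohort cost profiles follow the purchase cycles", {
  params <- cost_parameters()
  promo <- cohort_cost_profile("promotion", 3, params)
  expect_equal(which(promo == 1), c(3, 8))
  topup <- cohort_cost_profile("topup", 3, params)
  expect_equal(which(topup > 0), c(4, 5, 6, 7, 9, 10))
  expect_true(all(topup[topup > 0] == 0.25))
  soap <- cohort_cost_profile("soap", 9, params)
  expect_equal(which(soap == 1), c(9, 10))
  hwf <- cohort_cost_profile("hwf", 1, cost_parameters(hwf_life = 3))
  expect_equal(which(hwf == 1), c(1, 4, 7, 10))
  expect_error(cohort_cost_profile("formative", 1, params),
               class = "hygienecost_validation_error")
  expect_error(cohort_cost_profile("promotion", 11, params),
               class = "hygienecost_validation_error")
})

test_that("single-cohort streams book purchases at the expected years", {
  params <- cost_parameters()
  # horizon-1 stock served entirely in year 1, then spread over 10 years via
  # a constant-population stratum whose whole stock is one cohort
  cs <- make_stratum(pop = 5e4, household_size = 5, no_facility = 0.1,
                     limited = 0, basic = 0.9)
  # 1000 unserved households; force one cohort by making the increments all
  # land in year 1 (horizon 1 then rebuild by hand for 10 years):
  prices <- c(promotion = 30, hwf = 12, soap = 17)
  stream <- country_cost_stream(cs, prices, params,
                                water_price = 5)
  promo <- stream$cost_usd2019[stream$category == "promotion"]
  # 100 households/year: year 1 cohort repeats in year 6
  expect_equal(promo[1], 3000)
  expect_equal(promo[6], 3000 + 3000) # year-6 new cohort + year-1 repeat
  soap <- stream$cost_usd2019[stream$category == "soap"]
  expect_equal(soap, 17 * 100 * 1:10)
})

test_that("engine totals match brute-force per-cohort enumeration", {
  fx <- tiny_fixture()
  std <- standardize_prices(fx$prices, fx$factors)
  dists <- pool_price_table(std)
  local <- localize_prices(dists, fx$factors)
  params <- cost_parameters()

  scenarios <- list(
    scenario_spec(),
    scenario_spec(promotion_mode = "alternative"),
    scenario_spec(promotion_target = "whole_population"),
    scenario_spec(include_limited_supplies = TRUE),
    scenario_spec(economies_of_scale = TRUE)
  )
  for (sc in scenarios) {
    engine <- build_cost_streams(fx$quantities, local, params, sc) |>
      discount_stream(params$discount_rate)
    oracle <- brute_force_streams(fx$quantities, local, params, sc)
    eng_tot <- engine |>
      dplyr::group_by(category, year) |>
      dplyr::summarise(v = sum(discounted_usd2019), .groups = "drop") |>
      dplyr::arrange(category, year)
    ora_tot <- oracle |>
      dplyr::group_by(category, year) |>
      dplyr::summarise(v = sum(discounted_usd2019), .groups = "drop") |>
      dplyr::arrange(category, year)
    expect_equal(eng_tot$v, ora_tot$v, tolerance = 1e-9)
  }
})

test_that("limited-service supplies add soap and water per limiting factor", {
  params <- cost_parameters(horizon = 1)
  # 10,000 limited households, no unserved stock, split 47/10/43
  cs <- make_stratum(pop = 1e5, household_size = 5, no_facility = 0,
                     limited = 0.5, basic = 0.5,
                     piped_share = 1, piped = 5 / 2.7375)
  prices <- c(promotion = 30, hwf = 12, soap = 17)
  base <- country_cost_stream(cs, prices, params,
                              scenario = scenario_spec(), water_price = 5)
  expect_equal(sum(base$cost_usd2019[base$category %in% c("soap", "water")]), 0)

  lim <- country_cost_stream(cs, prices, params,
                             scenario = scenario_spec(include_limited_supplies = TRUE),
                             water_price = 5)
  expect_equal(sum(lim$cost_usd2019[lim$category == "soap"]),
               17 * (4700 + 4300))
  expect_equal(sum(lim$cost_usd2019[lim$category == "water"]),
               5 * (1000 + 4300))
})

test_that("discounting divides by (1+r)^(t-1) with year 1 undiscounted", {
  streams <- tibble::tibble(country_code = "ZAA", setting = "rural",
                            category = "soap", year = 1:10, cost_usd2019 = 1)
  no_disc <- discount_stream(streams, 0)
  expect_equal(no_disc$discounted_usd2019, no_disc$cost_usd2019)

  disc <- discount_stream(streams, 0.03)
  expect_equal(disc$discounted_usd2019[1], 1)
  expect_equal(disc$discounted_usd2019[2] * 1.03, 1)
  # annuity-due closed form for a constant unit stream
  expect_equal(sum(disc$discounted_usd2019),
               (1 - 1.03^-10) / 0.03 * 1.03, tolerance = 1e-12)
  expect_equal(round(sum(disc$discounted_usd2019), 3), 8.786)
  expect_error(discount_stream(streams, -0.01),
               class = "hygienecost_validation_error")
})

test_that("aggregation reproduces printed-style shares and splits", {
  totals <- c(formative = 5e6, promotion = 3340e6, topup = 2330e6,
              hwf = 1740e6, soap = 4970e6, water = 1270e6)
  s <- summarize_costs(totals, horizon = 10)
  expect_equal(s$report$total_usd_billion, 13.7)
  expect_equal(s$report$capital_share_pct, 37)
  expect_equal(unname(s$shares_pct["soap"]), 36)

  single <- summarize_costs(c(soap = 1e9), horizon = 10)
  expect_equal(unname(single$shares_pct["soap"]), 100)
  expect_error(summarize_costs(numeric(0)), class = "hygienecost_validation_error")
})

test_that("cost streams satisfy the structural invariants", {
  fx <- tiny_fixture()
  m <- run_base_case(fx)
  streams <- m$streams

  # conservation across partitions
  by_cat <- sum(m$summary$totals)
  by_country <- streams |>
    dplyr::group_by(country_code) |>
    dplyr::summarise(v = sum(discounted_usd2019)) |>
    dplyr::pull(v) |> sum()
  expect_equal(m$summary$grand_total, by_cat, tolerance = 1e-9)
  expect_equal(m$summary$grand_total, by_country, tolerance = 1e-9)

  # discounted never exceeds undiscounted; equal at year 1
  expect_true(all(streams$discounted_usd2019 <= streams$cost_usd2019 + 1e-12))
  y1 <- streams[streams$year == 1, ]
  expect_equal(y1$discounted_usd2019, y1$cost_usd2019)

  # recurrent undiscounted costs are non-decreasing over years
  rec <- colSums(m$summary$by_year_undiscounted[c("topup", "soap", "water"), ])
  expect_true(all(diff(rec) > -1e-6))
})

test_that("capital costs are flat under constant population and no discounting", {
  params <- cost_parameters(discount_rate = 0)
  cs <- make_stratum(pop = 1e6, growth = 0)
  stream <- country_cost_stream(cs, c(promotion = 30, hwf = 12, soap = 17),
                                params, water_price = 5)
  hwf <- stream$cost_usd2019[stream$category == "hwf"]
  expect_equal(hwf[1:5], rep(hwf[1], 5))
  # years 6-10 add repeat purchases for cohorts 1-5
  expect_equal(hwf[6:10], rep(2 * hwf[1], 5))
})

test_that("scenario totals are ordered as expected", {
  fx <- tiny_fixture()
  base <- run_base_case(fx)
  whole <- run_base_case(fx, scenario = scenario_spec(promotion_target = "whole_population"))
  alt <- run_base_case(fx, scenario = scenario_spec(promotion_mode = "alternative"))
  scale <- run_base_case(fx, scenario = scenario_spec(economies_of_scale = TRUE))
  limited <- run_base_case(fx, scenario = scenario_spec(include_limited_supplies = TRUE))

  expect_gte(whole$summary$totals[["promotion"]], base$summary$totals[["promotion"]])
  # the alternative price distribution has the lower pooled mean here
  alt_mean <- alt$dists$i_mean[alt$dists$category == "promotion_alternative"]
  base_mean <- base$dists$i_mean[base$dists$category == "promotion_base"]
  expect_lt(alt_mean, base_mean)
  expect_lte(alt$summary$totals[["promotion"]], base$summary$totals[["promotion"]])
  expect_lt(scale$summary$grand_total, base$summary$grand_total)
  expect_gt(limited$summary$grand_total, base$summary$grand_total)
})

test_that("annuitisation matches the closed-form equivalent annual cost", {
  expect_equal(annuitize(1000, 5, 0), 200)
  eac <- annuitize(1000, 5, 0.03)
  expect_equal(sum(eac / 1.03^(1:5)), 1000, tolerance = 1e-9)
})

test_that("limited-supplies full-stock annual cost matches direct arithmetic", {
  fx <- tiny_fixture()
  m <- run_base_case(fx)
  res <- limited_supplies_annual_cost(fx$quantities, m$local_prices, m$params)
  expect_gt(res$total, 0)
  expect_equal(res$total, res$soap + res$water)
  # soap dominates under the 47/10/43 split and soap-vs-water price gap
  expect_gt(res$soap_share, 0.5)
})
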