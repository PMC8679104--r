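test_that("standardisation deflates in local currency then converts at PPP", {
  factors <- tibble::tibble(
    country_code = "ZAA", year = c(2015L, 2019L), deflator = c(80, 100),
    ppp_lcu_per_int_dollar = c(1.6, 2), fx_lcu_per_usd = c(4, 5)
  )
  # no inflation step when already in 2019 prices
  expect_equal(standardize_price(100, "ZAA", 2019L, "ZAA", factors), 50)
  # 100 LCU in 2015 -> 125 LCU in 2019 -> I$62.5
  expect_equal(standardize_price(100, "ZAA", 2015L, "ZAA", factors), 62.5)
  # US$ sources convert to LCU at the price-year exchange rate first
  expect_equal(standardize_price(25, "USD", 2015L, "ZAA", factors),
               25 * 4 * 100 / 80 / 2)
  expect_error(standardize_price(10, "ZAA", 2010L, "ZAA", factors),
               class = "hygienecost_validation_error")
})

test_that("identical prices expressed in different currencies pool identically", {
  factors <- make_factors(c("ZAA", "ZAB"), ratio = 0.3, fx = 250, infl = 0.07)
  # the same I$40 value, disguised three ways
  i_target <- 40
  lcu_2019 <- i_target * 0.3 * 250
  defl_2014 <- 100 * 1.07^(2014 - 2019)
  points <- tibble::tibble(
    category = "soap_annual",
    amount = c(lcu_2019,
               lcu_2019 * defl_2014 / 100,
               lcu_2019 * defl_2014 / 100 / (250 * defl_2014 / 100)),
    currency = c("ZAA", "ZAB", "USD"),
    price_year = c(2019L, 2014L, 2014L),
    country_code = c("ZAA", "ZAB", "ZAB"),
    scope = "per_household", source_id = c("a", "b", "c")
  )
  std <- standardize_prices(points, factors)
  expect_equal(std$i2019, rep(i_target, 3), tolerance = 1e-12)
  # pooling is invariant to datapoint order
  d1 <- pool_prices(c(30, 40, 50), "soap_annual")
  d2 <- pool_prices(c(50, 30, 40), "soap_annual")
  expect_equal(d2$i_mean, d1$i_mean)
  expect_equal(d2$i_se, d1$i_se)
})

test_that("pooling gives mean, SE of the mean, and a moment-matched gamma", {
  d <- pool_prices(c(30, 40, 50), "hwf")
  expect_equal(d$i_mean, 40)
  expect_equal(d$i_se, 10 / sqrt(3))
  expect_equal(d$gamma_shape * d$gamma_scale, d$i_mean, tolerance = 1e-9)
  expect_equal(d$gamma_shape * d$gamma_scale^2, d$i_se^2, tolerance = 1e-9)

  single <- pool_prices(25, "hwf", fallback_cv = 0.25)
  expect_equal(single$i_mean, 25)
  expect_equal(single$i_se, 6.25)
  expect_true(single$se_imputed)
  expect_error(pool_prices(25, "hwf"), "single datapoint",
               class = "hygienecost_validation_error")
  expect_error(pool_prices(c(20, 20, 20), "hwf"), "minimum-SE floor",
               class = "hygienecost_validation_error")
})

test_that("single-datapoint categories borrow the median CV of the others", {
  std <- tibble::tibble(
    category = c("hwf", "hwf", "soap_annual", "soap_annual", "formative_research"),
    i2019 = c(10, 20, 30, 50, 100)
  )
  dists <- pool_price_table(std)
  cv_hwf <- sd(c(10, 20)) / 15
  cv_soap <- sd(c(30, 50)) / 40
  expected_cv <- median(c(cv_hwf, cv_soap))
  form <- dists[dists$category == "formative_research", ]
  expect_equal(form$i_se, 100 * expected_cv)
  expect_true(form$se_imputed)
})

test_that("gamma moment matching round-trips and matches simulation", {
  expect_equal(unname(gamma_from_moments(4, 2)), c(4, 1))
  expect_equal(unname(gamma_from_moments(10, 1)), c(100, 0.1))
  for (m in c(0.5, 7, 120)) {
    for (s in c(0.1 * m, 0.6 * m)) {
      g <- gamma_from_moments(m, s)
      expect_equal(unname(g[["shape"]] * g[["scale"]]), m, tolerance = 1e-10)
      expect_equal(unname(sqrt(g[["shape"]]) * g[["scale"]]), s, tolerance = 1e-10)
    }
  }
  expect_error(gamma_from_moments(10, 0), class = "hygienecost_validation_error")

  set.seed(7)
  g <- gamma_from_moments(40, 6)
  draws <- rgamma(1e5, shape = g[["shape"]], scale = g[["scale"]])
  expect_lt(abs(mean(draws) - 40), 4 * 6 / sqrt(1e5))
})

test_that("localisation follows the PPP/exchange-rate ratio", {
  factors <- tibble::tibble(
    country_code = c("AFG", "NER", "PAR"), year = 2019L, deflator = 100,
    ppp_lcu_per_int_dollar = c(10, 18, 5), fx_lcu_per_usd = c(42, 42, 5)
  )
  # I$42 pooled mean lands at US$10 or US$18 depending on price level
  expect_equal(localize_price(42, "AFG", factors), 10)
  expect_equal(localize_price(42, "NER", factors), 18)
  # parity case: ppp == fx
  expect_equal(localize_price(42, "PAR", factors), 42)

  dists <- make_price_distribution("soap_annual", 42, 4)
  local <- localize_prices(dists, factors)
  expect_equal(sort(local$usd_2019), c(10, 18, 42))
  # monotone in i_mean
  local2 <- localize_prices(make_price_distribution("soap_annual", 84, 4), factors)
  expect_true(all(local2$usd_2019 > local$usd_2019))
})

test_that("annual water price combines volume and weighted unit cost", {
  params <- cost_parameters()
  piped <- make_stratum(household_size = 5, piped_share = 1, piped = 1)
  expect_equal(annual_water_price(piped, params), 2.7375)
  hauled <- make_stratum(household_size = 5, piped_share = 0, nonpiped = 2)
  expect_equal(annual_water_price(hauled, params), 5.475)
  expect_equal(annual_water_price(piped, cost_parameters(water_lpd = 0)), 0)
  expect_error(annual_water_price(make_stratum(piped = -1), params),
               class = "hygienecost_validation_error")
})
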