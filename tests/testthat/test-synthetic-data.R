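test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_countries = 4, seed = 7)
  expect_identical(generate_country_table(cfg), generate_country_table(cfg))
  expect_identical(generate_economic_factors(cfg), generate_economic_factors(cfg))
  expect_identical(generate_price_points(cfg), generate_price_points(cfg))
  fx1 <- reference_fixture(seed = 7, n_countries = 4)
  fx2 <- reference_fixture(seed = 7, n_countries = 4)
  expect_identical(fx1, fx2)
})

test_that("generated tables satisfy every row invariant", {
  cfg <- synthetic_config(n_countries = 8, seed = 12)
  tab <- generate_country_table(cfg)
  expect_equal(nrow(tab), 16)
  expect_silent(validate_quantity_table(tab))
  expect_true(all(abs(tab$share_no_facility + tab$share_limited +
                        tab$share_basic - 1) < 1e-9))
  # urban household sizes below rural within each country
  wide <- tidyr::pivot_wider(tab[c("country_code", "setting", "household_size")],
                             names_from = "setting",
                             values_from = "household_size")
  expect_true(all(wide$urban < wide$rural))
})

test_that("economic factors are normalised to 2019 with LDC-like price levels", {
  cfg <- synthetic_config(n_countries = 6, seed = 9)
  f <- generate_economic_factors(cfg)
  f19 <- f[f$year == 2019, ]
  expect_equal(f19$deflator, rep(100, 6))
  ratio <- f19$ppp_lcu_per_int_dollar / f19$fx_lcu_per_usd
  expect_true(all(ratio >= 0.24 & ratio <= 0.43))
  expect_true(all(f$deflator > 0 & f$ppp_lcu_per_int_dollar > 0 &
                    f$fx_lcu_per_usd > 0))
})

test_that("an I$42 soap mean localises to roughly the US$10-18 range", {
  cfg <- synthetic_config(n_countries = 40, seed = 33,
                          ppp_fx_ratio_range = c(0.24, 0.43))
  f <- generate_economic_factors(cfg)
  local <- localize_prices(make_price_distribution("soap_annual", 42, 4), f)
  expect_gt(min(local$usd_2019), 9)
  expect_lt(max(local$usd_2019), 19)
})

test_that("price points carry heterogeneous currencies and hit their anchors", {
  cfg <- synthetic_config(n_countries = 20, seed = 10)
  pts <- generate_price_points(cfg)
  expect_equal(sum(pts$category == "promotion_base"), 14)
  expect_equal(sum(pts$category == "hwf"), 16)
  expect_equal(sum(pts$category == "soap_annual"), 10)
  expect_equal(sum(pts$category == "formative_research"), 5)
  expect_gt(length(unique(pts$currency)), 2)
  expect_true(any(pts$currency == "USD"))
  expect_true(all(pts$amount > 0))

  # large-n: standardised sample median within 10% of the I$-scale target
  cfg_big <- synthetic_config(n_countries = 20, seed = 10,
                              price_counts = c(soap_annual = 4000L))
  f <- generate_economic_factors(cfg_big)
  big <- generate_price_points(cfg_big, f)
  std <- standardize_prices(big, f)
  target <- 14.8 / mean(cfg_big$ppp_fx_ratio_range)
  expect_equal(median(std$i2019), target, tolerance = 0.1)
})

test_that("tiny price dispersion collapses points onto the anchor", {
  cfg <- synthetic_config(n_countries = 5, seed = 2, price_cv = 1e-4,
                          price_counts = c(hwf = 12L))
  f <- generate_economic_factors(cfg)
  std <- standardize_prices(generate_price_points(cfg, f), f)
  target <- 14.8 / mean(cfg$ppp_fx_ratio_range)
  expect_equal(std$i2019, rep(target, 12), tolerance = 1e-2)
})

test_that("pooled synthetic prices recover their generating gamma at n = 1e4", {
  cfg <- synthetic_config(n_countries = 10, seed = 5,
                          price_counts = c(hwf = 10000L), price_cv = 0.5)
  f <- generate_economic_factors(cfg)
  std <- standardize_prices(generate_price_points(cfg, f), f)
  vals <- std$i2019
  shape_true <- 1 / 0.5^2
  scale_true <- (14.8 / mean(cfg$ppp_fx_ratio_range)) /
    qgamma(0.5, shape = shape_true, scale = 1)
  fit <- gamma_from_moments(mean(vals), sd(vals))
  expect_equal(unname(fit[["shape"]]), shape_true, tolerance = 0.05)
  expect_equal(unname(fit[["scale"]]), scale_true, tolerance = 0.05)
})

test_that("the default-scale fixture lands near the LDC no-facility stock", {
  fx <- reference_fixture()
  q <- fx$quantities
  nf <- sum(q[["pop_2021"]] / q$household_size * q$share_no_facility)
  expect_gt(nf, 61e6 / 5)
  expect_lt(nf, 61e6 * 5)
})

test_that("the localised price medians track the published anchors within 15%", {
  fx <- reference_fixture()
  std <- standardize_prices(fx$prices, fx$factors)
  dists <- pool_price_table(std)
  local <- localize_prices(dists, fx$factors)
  anchors <- c(promotion_base = 33.9, hwf = 14.8, soap_annual = 14.8,
               promotion_alternative = 19.4, hwf_homemade = 1.2)
  for (cat in names(anchors)) {
    med <- median(local$usd_2019[local$category == cat])
    expect_lt(abs(med - anchors[[cat]]) / anchors[[cat]], 0.15)
  }
})

test_that("fixture CSVs round-trip through the loaders", {
  fx <- reference_fixture(seed = 3, n_countries = 3)
  dir <- withr::local_tempdir()
  paths <- write_fixture_csvs(fx, dir)
  q <- load_country_table(paths[["country"]])
  p <- load_price_table(paths[["prices"]])
  f <- load_factor_table(paths[["factors"]])
  expect_equal(q$household_size, fx$quantities$household_size)
  expect_equal(p$amount, fx$prices$amount)
  expect_equal(f$deflator, fx$factors$deflator)
  # a re-run of the pipeline from the files matches the in-memory fixture
  m1 <- run_base_case(fx)
  m2 <- run_base_case(list(quantities = q, prices = p, factors = f))
  expect_equal(m2$summary$grand_total, m1$summary$grand_total, tolerance = 1e-9)
})
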