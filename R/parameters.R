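#' Model constants for the costing engine
#'
#' Bundles the time horizon, discounting and cost-cycle constants used
#' throughout the model. Defaults reproduce the base case: a 10-year
#' scale-up from 2021, 3% annual discounting, 5-year useful lives for the
#' promotion campaign and the handwashing facility (HWF), a one-off
#' formative-research investment with a 1-year life, annual top-up
#' promotion at 25% of the initial campaign cost, and 1.5 litres of water
#' per person per day for handwashing.
#'
#' @param discount_rate Annual discount rate (fraction, >= 0).
#' @param horizon Scale-up horizon in years (>= 1).
#' @param base_year First calendar year of implementation.
#' @param promo_life Useful life of the promotion campaign, years.
#' @param hwf_life Useful life of the handwashing facility, years.
#' @param formative_life Useful life of formative research, years.
#' @param topup_fraction Annual top-up promotion cost as a fraction of the
#'   initial campaign cost, in `[0, 1]`.
#' @param water_lpd Water used for handwashing, litres per person per day.
#' @return A `cost_parameters` list.
#' @export
cost_parameters <- function(discount_rate = 0.03,
                            horizon = 10L,
                            base_year = 2021L,
                            promo_life = 5L,
                            hwf_life = 5L,
                            formative_life = 1L,
                            topup_fraction = 0.25,
                            water_lpd = 1.5) {
  stopifnot(length(discount_rate) == 1, length(horizon) == 1)
  if (discount_rate < 0) {
    rlang::abort("`discount_rate` must be >= 0.", class = "hygienecost_validation_error")
  }
  if (horizon < 1) {
    rlang::abort("`horizon` must be >= 1.", class = "hygienecost_validation_error")
  }
  if (promo_life < 1 || hwf_life < 1 || formative_life < 1) {
    rlang::abort("useful lives must be >= 1 year.", class = "hygienecost_validation_error")
  }
  if (topup_fraction < 0 || topup_fraction > 1) {
    rlang::abort("`topup_fraction` must be in [0, 1].", class = "hygienecost_validation_error")
  }
  if (water_lpd < 0) {
    rlang::abort("`water_lpd` must be >= 0.", class = "hygienecost_validation_error")
  }
  structure(
    list(
      discount_rate = discount_rate,
      horizon = as.integer(horizon),
      base_year = as.integer(base_year),
      promo_life = as.integer(promo_life),
      hwf_life = as.integer(hwf_life),
      formative_life = as.integer(formative_life),
      topup_fraction = topup_fraction,
      water_lpd = water_lpd
    ),
    class = "cost_parameters"
  )
}

#' Scenario switches for a model run
#'
#' @param promotion_mode `"base"` (campaign including one-to-one household
#'   visits) or `"alternative"` (lower-cost campaign excluding one-to-one
#'   promotion).
#' @param promotion_target `"no_facility_only"` targets promotion at
#'   households with no handwashing facility; `"whole_population"` targets
#'   every household (promotion and top-up only — facilities and supplies
#'   are still costed for the no-facility stock).
#' @param include_limited_supplies If `TRUE`, soap and/or water costs are
#'   added for households with a "limited" service (facility present but
#'   soap and/or water missing), per their limiting factor.
#' @param economies_of_scale If `TRUE`, promotion (and top-up), HWF and soap
#'   prices fall year on year per [apply_scale_economies()].
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(promotion_mode = c("base", "alternative"),
                          promotion_target = c("no_facility_only", "whole_population"),
                          include_limited_supplies = FALSE,
                          economies_of_scale = FALSE) {
  structure(
    list(
      promotion_mode = match.arg(promotion_mode),
      promotion_target = match.arg(promotion_target),
      include_limited_supplies = isTRUE(include_limited_supplies),
      economies_of_scale = isTRUE(economies_of_scale)
    ),
    class = "scenario_spec"
  )
}

#' Monte Carlo configuration
#'
#' @param n_draws Number of simulation draws (>= 2).
#' @param seed Integer seed controlling the draw sequence.
#' @param interval Percentile pair for the uncertainty interval, in (0, 100).
#' @param sampled_categories Cost categories whose pooled price means are
#'   sampled from their gamma priors. Top-up always inherits the promotion
#'   draw (it is defined as a fraction of the initial campaign cost), and
#'   water is held at its constructed point value by default.
#' @return An `mc_config` list.
#' @export
mc_config <- function(n_draws = 1000L,
                      seed = 1L,
                      interval = c(2.5, 97.5),
                      sampled_categories = c("promotion", "hwf", "soap", "formative")) {
  if (n_draws < 2) {
    rlang::abort("`n_draws` must be >= 2.", class = "hygienecost_validation_error")
  }
  if (length(interval) != 2 || any(interval <= 0) || any(interval >= 100) ||
      interval[1] >= interval[2]) {
    rlang::abort("`interval` must be two percentiles in (0, 100), lower < upper.",
                 class = "hygienecost_validation_error")
  }
  ok <- c("promotion", "hwf", "soap", "formative", "water")
  bad <- setdiff(sampled_categories, ok)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown sampled categories: ", paste(bad, collapse = ", ")),
                 class = "hygienecost_validation_error")
  }
  structure(
    list(
      n_draws = as.integer(n_draws),
      seed = as.integer(seed),
      interval = interval,
      sampled_categories = sampled_categories
    ),
    class = "mc_config"
  )
}

#' Equivalent annual cost of a capital outlay
#'
#' Spreads a capital purchase over its useful life at the discount rate
#' (annuity factor `r / (1 - (1 + r)^-L)`). With a zero rate this reduces
#' to straight-line `amount / life`. Provided as an alternative reporting
#' mode for capital costs; the base case books capital purchases in full in
#' the year incurred.
#'
#' @param amount Capital outlay.
#' @param life Useful life in years (>= 1).
#' @param rate Annual discount rate (>= 0).
#' @return Equivalent annual cost.
#' @export
annuitize <- function(amount, life, rate) {
  if (any(life < 1)) {
    rlang::abort("`life` must be >= 1.", class = "hygienecost_validation_error")
  }
  if (any(rate < 0)) {
    rlang::abort("`rate` must be >= 0.", class = "hygienecost_validation_error")
  }
  ifelse(rate == 0, amount / life, amount * rate / (1 - (1 + rate)^(-life)))
}
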