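#' Economies-of-scale price schedule
#'
#' Under the economies-of-scale scenario, unit prices of promotion (and
#' top-up), handwashing facilities and soap fall as implementation scales
#' up: a 10% reduction on the year-1 price in year 2, then decrements of 2
#' percentage points (8% in year 3, 6% in year 4, ...), reaching a total
#' reduction of 30% from year 6 onwards. Reductions are additive on the
#' year-1 price, giving multipliers 1.00, 0.90, 0.82, 0.76, 0.72, 0.70,
#' 0.70, ...
#'
#' @param price Year-1 unit price.
#' @param implementation_year Implementation year (>= 1).
#' @return The adjusted price.
#' @export
apply_scale_economies <- function(price, implementation_year) {
  if (any(implementation_year < 1)) {
    rlang::abort("`implementation_year` must be >= 1.",
                 class = "hygienecost_validation_error")
  }
  reduction <- cumsum(c(0, 0.10, 0.08, 0.06, 0.04, 0.02))
  price * (1 - reduction[pmin(implementation_year, 6)])
}

#' Load the deterministic scenario catalogue
#'
#' The one-way scenarios are shipped as data (YAML) rather than code so
#' users can extend or replace them. Each entry names a perturbation type
#' (`price_ci`, `price_median`, `discount_rate`, `useful_life`,
#' `topup_fraction`, `economies_of_scale`, `alternative_promotion`, `null`)
#' with its parameters.
#'
#' @param path YAML file; defaults to the catalogue shipped with the
#'   package.
#' @return List of scenario definitions.
#' @export
load_scenario_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scenarios.yaml", package = "hygienecost")
  }
  if (!file.exists(path)) {
    rlang::abort(paste0("scenario catalogue not found: ", path),
                 class = "hygienecost_schema_error")
  }
  yaml::read_yaml(path)$scenarios
}

# Resolve the promotion alias to the distribution the active scenario uses.
resolve_dist_category <- function(category, scenario) {
  if (identical(category, "promotion")) {
    dist_category_for("promotion", scenario)
  } else if (identical(category, "soap")) {
    "soap_annual"
  } else {
    category
  }
}

set_dist_mean <- function(dists, category, new_mean) {
  i <- which(dists$category == category)
  if (length(i) != 1) {
    rlang::abort(paste0("no price distribution for category '", category, "'."),
                 class = "hygienecost_validation_error")
  }
  dists$i_mean[i] <- new_mean
  # keep the prior's spread; gamma parameters re-matched to the new mean
  if (dists$i_se[i] > 0) {
    g <- gamma_from_moments(new_mean, dists$i_se[i])
    dists$gamma_shape[i] <- g[["shape"]]
    dists$gamma_scale[i] <- g[["scale"]]
  }
  dists
}

modify_params <- function(params, field, value) {
  args <- unclass(params)
  args[[field]] <- value
  do.call(cost_parameters, args)
}

evaluate_perturbed <- function(model, dists = model$dists,
                               params = model$params,
                               scenario = model$scenario) {
  m <- evaluate_model(model$quantities, dists, model$factors, params, scenario)
  m$summary$grand_total
}

#' One-way deterministic sensitivity (tornado) analysis
#'
#' Re-runs the full deterministic model with each catalogued parameter at
#' its low and high plausible values (price CIs use the 2.5th/97.5th
#' percentiles of the fitted gamma prior; some scenarios are one-sided).
#' Results are oriented so `low_total <= base_total <= high_total` and
#' sorted by swing for tornado plotting.
#'
#' @param model Base-case `hygienecost_model`.
#' @param catalogue Scenario list from [load_scenario_catalogue()].
#' @return Tibble `scenario_id, parameter, low_total, high_total,
#'   base_total, swing`, sorted by decreasing swing.
#' @export
run_scenarios <- function(model, catalogue = load_scenario_catalogue()) {
  base_total <- model$summary$grand_total

  one <- function(sc) {
    type <- sc$type
    totals <- switch(type,
      null = c(base_total, base_total),
      price_ci = {
        cat <- resolve_dist_category(sc$category, model$scenario)
        i <- which(model$dists$category == cat)
        if (length(i) != 1 || is.na(model$dists$gamma_shape[i])) {
          rlang::abort(paste0("no gamma prior for category '", cat, "'."),
                       class = "hygienecost_validation_error")
        }
        probs <- if (!is.null(sc$probs)) unlist(sc$probs) else c(0.025, 0.975)
        bounds <- stats::qgamma(probs, shape = model$dists$gamma_shape[i],
                                scale = model$dists$gamma_scale[i])
        vapply(bounds, function(b) {
          evaluate_perturbed(model, dists = set_dist_mean(model$dists, cat, b))
        }, numeric(1))
      },
      price_median = {
        cat <- resolve_dist_category(sc$category, model$scenario)
        f19 <- model$factors[model$factors$year == 2019L, ]
        ratio_med <- stats::median(f19$ppp_lcu_per_int_dollar / f19$fx_lcu_per_usd)
        new_mean <- sc$value / ratio_med
        c(evaluate_perturbed(model, dists = set_dist_mean(model$dists, cat, new_mean)),
          NA_real_)
      },
      discount_rate = vapply(unlist(sc$values), function(r) {
        evaluate_perturbed(model, params = modify_params(model$params,
                                                         "discount_rate", r))
      }, numeric(1)),
      useful_life = vapply(unlist(sc$values), function(v) {
        evaluate_perturbed(model, params = modify_params(model$params,
                                                         sc$param, v))
      }, numeric(1)),
      topup_fraction = vapply(unlist(sc$values), function(v) {
        evaluate_perturbed(model, params = modify_params(model$params,
                                                         "topup_fraction", v))
      }, numeric(1)),
      economies_of_scale = {
        s <- model$scenario
        s$economies_of_scale <- TRUE
        c(evaluate_perturbed(model, scenario = s), NA_real_)
      },
      alternative_promotion = {
        s <- model$scenario
        s$promotion_mode <- "alternative"
        c(evaluate_perturbed(model, scenario = s), NA_real_)
      },
      rlang::abort(paste0("unknown scenario type '", type, "'."),
                   class = "hygienecost_validation_error")
    )
    vals <- totals[!is.na(totals)]
    low <- if (any(vals <= base_total)) min(vals) else NA_real_
    high <- if (any(vals >= base_total)) max(vals) else NA_real_
    swing <- if (!is.na(low) && !is.na(high)) {
      high - low
    } else {
      max(abs(vals - base_total))
    }
    tibble::tibble(scenario_id = sc$id, parameter = sc$parameter,
                   low_total = low, high_total = high,
                   base_total = base_total, swing = swing)
  }

  purrr::map_dfr(catalogue, one) |>
    dplyr::arrange(dplyr::desc(.data$swing))
}
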