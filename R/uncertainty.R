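# Map stream categories to the price distribution they are priced from.
dist_category_for <- function(stream_category, scenario) {
  promo <- if (scenario$promotion_mode == "alternative") {
    "promotion_alternative"
  } else {
    "promotion_base"
  }
  switch(stream_category,
         promotion = promo, topup = promo, hwf = "hwf", soap = "soap_annual",
         formative = "formative_research", water = NA_character_)
}

#' Draw pooled category price means from their gamma priors
#'
#' One draw per category per iteration: the uncertain quantity is the
#' pooled I$ mean itself, so a single draw is applied to every country
#' after localisation (perfect correlation across countries). Degenerate
#' distributions (`i_se = 0`) return their mean.
#'
#' @param dists Price distribution tibble.
#' @param n Number of iterations.
#' @return Numeric matrix `n` x `nrow(dists)`, columns named by category.
#' @export
sample_category_prices <- function(dists, n = 1) {
  draws <- vapply(seq_len(nrow(dists)), function(i) {
    shape <- dists$gamma_shape[i]
    scale <- dists$gamma_scale[i]
    if (dists$i_se[i] == 0 || is.na(shape)) {
      rep(dists$i_mean[i], n)
    } else {
      if (shape <= 0 || scale <= 0) {
        rlang::abort(paste0("invalid gamma parameters for category '",
                            dists$category[i], "'."),
                     class = "hygienecost_validation_error")
      }
      stats::rgamma(n, shape = shape, scale = scale)
    }
  }, numeric(n))
  draws <- matrix(draws, nrow = n)
  colnames(draws) <- dists$category
  draws
}

#' Monte Carlo uncertainty analysis of total cost
#'
#' Propagates price uncertainty through the model: each iteration draws one
#' pooled I$ mean per sampled category from its gamma prior and re-prices
#' the whole model (quantities are not varied). Because every cost stream
#' is exactly linear in its category's localised unit price, re-pricing
#' scales each category's discounted total by `draw / point mean`; top-up
#' inherits the promotion draw (it is defined as a fraction of the initial
#' campaign cost) and water is held at its constructed point value unless
#' explicitly sampled. The uncertainty interval is the empirical percentile
#' pair of the draw totals (linear interpolation between order statistics).
#'
#' @param model A `hygienecost_model` from [evaluate_model()] or
#'   [run_base_case()].
#' @param config An [mc_config()] object.
#' @param water_cv Coefficient of variation for the water price, required
#'   only if `"water"` is in `config$sampled_categories`.
#' @return An `mc_result` list: `draws` tibble (`draw, total,
#'   promotion_only, facilities_supplies`), `point_estimate`, `ci_lower`,
#'   `ci_upper`, per-aggregate `intervals`, and `seed_used`.
#' @export
run_monte_carlo <- function(model, config = mc_config(), water_cv = NULL) {
  totals <- model$summary$totals
  dists <- model$dists
  n <- config$n_draws

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  # Relative draw (draw / point mean) per sampled stream category.
  rel <- function(stream_cat) rep(1, n)
  rel_for <- list()
  for (sc in c("promotion", "hwf", "soap", "formative")) {
    if (!sc %in% config$sampled_categories) next
    dc <- dist_category_for(if (sc == "promotion") "promotion" else sc,
                            model$scenario)
    i <- which(dists$category == dc)
    if (length(i) != 1) {
      rlang::abort(paste0("no price distribution for sampled category '", sc, "'."),
                   class = "hygienecost_validation_error")
    }
    d <- sample_category_prices(dists[i, ], n)
    rel_for[[sc]] <- as.numeric(d) / dists$i_mean[i]
  }
  if ("water" %in% config$sampled_categories) {
    if (is.null(water_cv) || water_cv <= 0) {
      rlang::abort("sampling the water price requires a positive `water_cv`.",
                   class = "hygienecost_validation_error")
    }
    g <- gamma_from_moments(1, water_cv)
    rel_for$water <- stats::rgamma(n, shape = g[["shape"]], scale = g[["scale"]])
  }
  rel_of <- function(sc) if (!is.null(rel_for[[sc]])) rel_for[[sc]] else rep(1, n)

  draw_cat <- cbind(
    formative = totals[["formative"]] * rel_of("formative"),
    promotion = totals[["promotion"]] * rel_of("promotion"),
    topup = totals[["topup"]] * rel_of("promotion"),
    hwf = totals[["hwf"]] * rel_of("hwf"),
    soap = totals[["soap"]] * rel_of("soap"),
    water = totals[["water"]] * rel_of("water")
  )
  draws <- tibble::tibble(
    draw = seq_len(n),
    total = rowSums(draw_cat),
    promotion_only = rowSums(draw_cat[, c("formative", "promotion", "topup"),
                                      drop = FALSE]),
    facilities_supplies = rowSums(draw_cat[, c("hwf", "soap", "water"),
                                           drop = FALSE])
  )
  if (any(draws$total <= 0)) {
    rlang::abort("non-positive draw total encountered.",
                 class = "hygienecost_validation_error")
  }

  probs <- config$interval / 100
  interval_of <- function(x) stats::quantile(x, probs = probs, names = FALSE, type = 7)
  ci <- interval_of(draws$total)
  structure(
    list(
      draws = draws,
      point_estimate = model$summary$grand_total,
      ci_lower = ci[1], ci_upper = ci[2],
      intervals = list(
        total = ci,
        promotion_only = interval_of(draws$promotion_only),
        facilities_supplies = interval_of(draws$facilities_supplies)
      ),
      point_estimates = list(
        total = model$summary$grand_total,
        promotion_only = model$summary$promotion_only_total,
        facilities_supplies = model$summary$facilities_supplies_total
      ),
      seed_used = config$seed,
      config = config
    ),
    class = "mc_result"
  )
}
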