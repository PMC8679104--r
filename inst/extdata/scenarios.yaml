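# One-way deterministic sensitivity scenarios. Price CI scenarios move the
# pooled category mean to the 2.5th/97.5th percentiles of its gamma prior;
# one-sided scenarios have no opposite bound.
scenarios:
  - id: promotion_price_ci
    parameter: "Promotion price (95% CI)"
    type: price_ci
    category: promotion
  - id: hwf_price_ci
    parameter: "Handwashing facility price (95% CI)"
    type: price_ci
    category: hwf
  - id: soap_price_ci
    parameter: "Annual soap expenditure (95% CI)"
    type: price_ci
    category: soap
  - id: discount_rate
    parameter: "Discount rate (0% / 6%)"
    type: discount_rate
    values: [0.0, 0.06]
  - id: promo_life
    parameter: "Promotion useful life (3 / 10 years)"
    type: useful_life
    param: promo_life
    values: [3, 10]
  - id: hwf_life
    parameter: "HWF useful life (3 / 10 years)"
    type: useful_life
    param: hwf_life
    values: [3, 10]
  - id: topup_fraction
    parameter: "Top-up promotion fraction (10% / 40%)"
    type: topup_fraction
    values: [0.1, 0.4]
  - id: hwf_homemade
    parameter: "Home-made HWF (median US$1.2)"
    type: price_median
    category: hwf
    value: 1.2
  - id: economies_of_scale
    parameter: "Economies of scale (30% price reduction by year 7)"
    type: economies_of_scale
  - id: alternative_promotion
    parameter: "Alternative promotion (no one-to-one activities)"
    type: alternative_promotion
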