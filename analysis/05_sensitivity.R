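#!/usr/bin/env Rscript
# One-way deterministic sensitivity analysis: each catalogued parameter at
# its low/high plausible values (price CIs at the gamma priors' 2.5th/97.5th
# percentiles; economies of scale, home-made HWF and the alternative
# promotion package as one-sided scenarios). Output ordered for a tornado
# plot.

suppressPackageStartupMessages(library(hygienecost))

fixture <- reference_fixture()
model <- run_base_case(fixture)
tornado <- run_scenarios(model, load_scenario_catalogue())

dir.create("results", showWarnings = FALSE)
readr::write_csv(tornado, "results/tornado.csv")

cat(sprintf("base-case total: US$%.1f billion\n\n",
            model$summary$grand_total / 1e9))
cat("tornado (sorted by swing, US$ billion):\n")
out <- tornado
out$low_total <- round(out$low_total / 1e9, 1)
out$high_total <- round(out$high_total / 1e9, 1)
out$base_total <- round(out$base_total / 1e9, 1)
out$swing <- round(out$swing / 1e9, 1)
print(as.data.frame(out[c("scenario_id", "low_total", "high_total", "swing")]),
      row.names = FALSE)
cat("\nwrote results/tornado.csv\n")
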