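#!/usr/bin/env Rscript
# Generate the reference-46 synthetic inputs: 46 countries x urban/rural
# quantity strata, raw price datapoints in heterogeneous currencies/years,
# and per-country economic factor series. Writes the three CSVs other
# scripts (and any external tool) can consume.

suppressPackageStartupMessages(library(hygienecost))

fixture <- reference_fixture()
paths <- write_fixture_csvs(fixture, "results/data")

q <- fixture$quantities
nf_2021 <- sum(q$pop_2021 / q$household_size * q$share_no_facility)
lim_2021 <- sum(q$pop_2021 / q$household_size * q$share_limited)
rural_share <- sum(q$pop_2021[q$setting == "rural"]) / sum(q$pop_2021)

cat("reference-46 fixture (seed", fixture$config$seed, ")\n")
cat(sprintf("  strata: %d, price datapoints: %d\n", nrow(q), nrow(fixture$prices)))
cat(sprintf("  households with no facility (2021): %.0f million\n", nf_2021 / 1e6))
cat(sprintf("  households with limited service (2021): %.0f million\n", lim_2021 / 1e6))
cat(sprintf("  rural population share: %.0f%%\n", 100 * rural_share))
cat("  wrote:", paste(paths, collapse = ", "), "\n")
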