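#!/usr/bin/env Rscript
# Adjuvant-chemotherapy timing sensitivity analysis: restart the full model
# with chemotherapy beginning 4, 8 or 12 weeks after resection and check that
# the cost-effectiveness conclusion is unchanged. Uses the deterministic
# cohort evaluator so the comparison is noise-free.

library(wwcea)

rows <- list()
for (comparison in c("WW_vs_APR", "WW_vs_LAR")) {
  for (recipe in adjuvant_timing_scenarios(comparison)) {
    spec <- apply_recipe(recipe)
    ww <- cohort_expected_value(spec, "WW")
    sg <- cohort_expected_value(spec, "SURGERY")
    cmp <- compare(sg, ww, wtp = spec$timeline$wtp_threshold)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      comparison = comparison, scenario = recipe$name,
      ww_cost = ww$expected_cost, ww_qalys = ww$expected_qalys,
      surgery_cost = sg$expected_cost, surgery_qalys = sg$expected_qalys,
      ww_dominates = cmp$classification == "B_dominates"
    )
  }
}
tab <- dplyr::bind_rows(rows)
print(tab)
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/adjuvant_timing.csv", row.names = FALSE)
if (all(tab$ww_dominates)) {
  cat("WW remains dominant under every chemotherapy start time (4/8/12 weeks).\n")
} else {
  cat("WARNING: dominance is sensitive to chemotherapy timing in some scenario.\n")
}
cat("Table written to results/adjuvant_timing.csv\n")
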