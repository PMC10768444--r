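#!/usr/bin/env Rscript
# Stage 1: simulate the study cohorts.
#
# Two cohorts are generated at desk scale: a null cohort (exchangeable
# groups, effect_delta = 0) and an effect cohort in which group B carries a
# strong excess of clonally expanded T-cell clonotypes (expansion fraction
# 0.35 vs 0.05). Per-sample rearrangement depths are drawn log-uniformly
# over [1e3, 1e4], matching the order-of-magnitude spread of real targeted
# gDNA libraries. Count tables are written under results/cohorts/.

suppressMessages(library(tcrdiv))

seed <- 2026L
out <- "results/cohorts"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (scenario in c("null", "effect")) {
  delta <- if (scenario == "effect") 0.3 else 0
  cs <- cohort_spec(groups = c(A = 20, B = 20), base_expansion = 0.05,
                    effect_delta = delta, effect_groups = "B",
                    depth_range = c(1e3, 1e4), cell_type = "CD8",
                    chain = "beta", seed = seed + (scenario == "effect"))
  cohort <- simulate_cohort(cs)
  meta <- cohort[, c("sample_id", "group", "cell_type", "chain",
                     "expansion_fraction", "depth")]
  write.table(meta, file.path(out, paste0(scenario, "_samples.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- do.call(rbind, lapply(cohort_counts(cohort), function(cv)
    data.frame(sample_id = cv$sample_id, clone = seq_along(cv$counts),
               count = cv$counts)))
  write.table(counts, file.path(out, paste0(scenario, "_counts.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s cohort: %d samples, depths %d-%d", scenario,
                  nrow(cohort), min(cohort$depth), max(cohort$depth)))
}
message("wrote ", out)
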