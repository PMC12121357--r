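#!/usr/bin/env Rscript
# Stage 6 — biogeography composition report.
#
# Splits the photosynthetic read totals by biogeographical category within
# substrate x size-fraction panels and across bloom stages; fractions within
# each panel sum to 1 (unallocated included).

suppressMessages({library(asvbiogeo); library(dplyr)})

run_dir <- "results/run"
config <- run_config(out_dir = run_dir, seed = 1L)

counts_df <- read_table_prov(file.path(run_dir, "inputs", "asv_counts.tsv"))
counts <- as.matrix(counts_df[, -1]); rownames(counts) <- counts_df[[1]]
taxa <- read_table_prov(file.path(run_dir, "inputs", "asv_taxonomy.tsv"))
meta <- read_table_prov(file.path(run_dir, "inputs", "sample_metadata.tsv"))
assignment <- read_table_prov(file.path(run_dir, "casv_assignment.tsv"))
biogeo <- read_table_prov(file.path(run_dir, "biogeography.tsv"))

photo <- filter_photosynthetic(taxa, default_trophic_lookup())
pcounts <- counts[photo$asv_id, ]

by_panel <- category_read_fractions(pcounts, assignment, biogeo, meta,
                                    panel_vars = c("substrate", "size_fraction"))
by_stage <- category_read_fractions(pcounts, assignment, biogeo, meta,
                                    panel_vars = "stage")
write_table_prov(by_panel,
                 file.path(run_dir, "category_fractions_substrate_fraction.tsv"),
                 config)
write_table_prov(by_stage, file.path(run_dir, "category_fractions_stage.tsv"),
                 config)

cat("read fractions by category (ice vs water, all fractions pooled):\n")
pooled <- by_panel |>
  group_by(substrate, category) |>
  summarise(reads = sum(reads), .groups = "drop_last") |>
  mutate(frac = reads / sum(reads)) |>
  ungroup()
print(tidyr::pivot_wider(pooled |> select(-reads),
                         names_from = substrate, values_from = frac))
stopifnot(abs(tapply(by_panel$read_fraction,
                     paste(by_panel$substrate, by_panel$size_fraction), sum) - 1) < 1e-9)
cat("per-panel fractions sum to 1: OK\n")
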