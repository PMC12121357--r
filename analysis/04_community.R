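#!/usr/bin/env Rscript
# Stage 4 — community structure of the photosynthetic fraction.
#
# Keeps photosynthetic/mixotrophic ASVs via the trophic lookup, aggregates
# to species-level relative abundances, selects the key taxa jointly holding
# 75% of the reads, and tests community differences (Bray-Curtis + ANOSIM)
# across substrate, size fraction, bloom phase and stages within substrate.

suppressMessages({library(asvbiogeo); library(dplyr)})

run_dir <- "results/run"
config <- run_config(out_dir = run_dir, seed = 1L)

counts_df <- read_table_prov(file.path(run_dir, "inputs", "asv_counts.tsv"))
counts <- as.matrix(counts_df[, -1]); rownames(counts) <- counts_df[[1]]
taxa <- read_table_prov(file.path(run_dir, "inputs", "asv_taxonomy.tsv"))
meta <- read_table_prov(file.path(run_dir, "inputs", "sample_metadata.tsv"))

photo <- filter_photosynthetic(taxa, default_trophic_lookup())
pcounts <- counts[photo$asv_id, ]
cat(sprintf("%d of %d ASVs are photosynthetic/mixotrophic\n",
            nrow(photo), nrow(taxa)))

rel <- relative_abundance(pcounts, grouping = photo$species) |>
  left_join(meta |> select(sample_id, substrate, layer, size_fraction, stage, phase),
            by = "sample_id")
top <- select_top_taxa(pcounts, grouping = photo$species, coverage = config$coverage)
cat(sprintf("%d species jointly hold %.1f%% of the photosynthetic reads\n",
            nrow(top), 100 * max(top$cum_share)))

tot <- colSums(pcounts)
prel <- sweep(pcounts, 2, ifelse(tot == 0, 1, tot), "/")
bray <- bray_curtis(prel)

tests <- list(
  substrate = anosim_test(bray, meta$substrate, config$n_permutations, config$seed + 11L),
  size_fraction = anosim_test(bray, meta$size_fraction, config$n_permutations, config$seed + 12L),
  phase = anosim_test(bray, meta$phase, config$n_permutations, config$seed + 13L)
)
for (sub in c("ice", "water")) {
  k <- meta$substrate == sub
  tests[[paste0("stage_", sub)]] <- anosim_test(bray[k, k], meta$stage[k],
                                                config$n_permutations,
                                                config$seed + 14L + (sub == "water"))
}
for (nm in names(tests)) {
  cat(sprintf("ANOSIM %-14s R = %6.3f  p = %.4g\n", nm, tests[[nm]]$R, tests[[nm]]$p))
}

write_table_prov(rel, file.path(run_dir, "relative_abundance.tsv"), config)
write_table_prov(top, file.path(run_dir, "top_taxa.tsv"), config)
bd <- cbind(data.frame(sample_id = rownames(bray)), as.data.frame(round(bray, 10)))
write_table_prov(bd, file.path(run_dir, "bray_curtis.tsv"), config)
jsonlite::write_json(lapply(tests, unclass), file.path(run_dir, "anosim.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
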