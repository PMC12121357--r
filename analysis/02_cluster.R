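#!/usr/bin/env Rscript
# Stage 2 — cluster study ASVs with reference ASVs into cASVs.
#
# Cross-dataset matching uses 100% identity over the overlap region (exact
# substring or suffix/prefix overlap of at least 100 nt): amplicon variants
# of the same locus trimmed to different primer boundaries collapse into one
# cASV, while variants differing by even a single base stay apart.

suppressMessages({library(asvbiogeo); library(dplyr)})

run_dir <- "results/run"
config <- run_config(out_dir = run_dir, seed = 1L)

inp <- read_inputs(list(
  study_fasta = file.path(run_dir, "inputs", "study_asvs.fasta"),
  counts = file.path(run_dir, "inputs", "asv_counts.tsv"),
  metadata = file.path(run_dir, "inputs", "sample_metadata.tsv"),
  ref_fasta = file.path(run_dir, "inputs", "reference_asvs.fasta"),
  occurrences = file.path(run_dir, "inputs", "reference_occurrences.tsv")
))

entries <- bind_rows(
  tibble::tibble(id = inp$asv$id, sequence = inp$asv$sequence,
                 origin = "study",
                 total_reads = rowSums(inp$counts)[inp$asv$id]),
  tibble::tibble(id = inp$ref$id, sequence = inp$ref$sequence,
                 origin = "reference", total_reads = 0)
)
clusters <- cluster_asvs(entries, min_overlap = config$min_overlap)

write_table_prov(clusters$assignment,
                 file.path(run_dir, "casv_assignment.tsv"), config)
write_table_prov(clusters$members,
                 file.path(run_dir, "casv_members.tsv"), config)

n_matched <- clusters$members |>
  group_by(casv_id) |>
  summarise(has_ref = any(origin == "reference"),
            has_study = any(origin == "study")) |>
  summarise(matched = sum(has_ref & has_study), study_only = sum(!has_ref))
cat(sprintf("%d study ASVs -> %d cASVs (%d matched to the reference, %d study-only)\n",
            nrow(clusters$assignment), length(unique(clusters$members$casv_id)),
            n_matched$matched, n_matched$study_only))
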