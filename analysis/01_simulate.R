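#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study and reference corpus.
#
# Emulates the ice-camp design: 2 ice layers + 4 water depths x 3 size
# fractions x 9 dates across the three bloom stages, plus a global reference
# occurrence table spanning polar/temperate/tropical latitudes with planted
# biogeography labels, substrate/phase indicator taxa and single-mismatch
# ecotype pairs.  All downstream stages read the files written here.

suppressMessages(library(asvbiogeo))

run_dir <- "results/run"
dir.create(file.path(run_dir, "inputs"), recursive = TRUE, showWarnings = FALSE)
config <- run_config(out_dir = run_dir, seed = 1L)

study <- simulate_study(config$sim)
reference <- simulate_reference(config$sim, study)

write_fasta(study$asv[, c("asv_id", "sequence")],
            file.path(run_dir, "inputs", "study_asvs.fasta"))
write_fasta(reference$ref[, c("ref_id", "sequence")],
            file.path(run_dir, "inputs", "reference_asvs.fasta"))
write_table_prov(cbind(data.frame(asv_id = rownames(study$counts)),
                       as.data.frame(study$counts)),
                 file.path(run_dir, "inputs", "asv_counts.tsv"), config)
write_table_prov(study$asv, file.path(run_dir, "inputs", "asv_taxonomy.tsv"), config)
write_table_prov(study$metadata,
                 file.path(run_dir, "inputs", "sample_metadata.tsv"), config)
write_table_prov(reference$occurrences,
                 file.path(run_dir, "inputs", "reference_occurrences.tsv"), config)
jsonlite::write_json(
  list(zone = as.list(study$truth$zone),
       affinity = as.list(study$truth$affinity),
       trophic = as.list(study$truth$trophic),
       ecotype_pairs = study$truth$ecotype_pairs),
  file.path(run_dir, "inputs", "planted_truth.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE
)

aff <- table(study$truth$affinity)
cat(sprintf("simulated %d study ASVs over %d samples (%d with reference counterparts)\n",
            nrow(study$asv), nrow(study$metadata), nrow(reference$ref)))
cat(sprintf("reference corpus: %d samples, %d occurrence records\n",
            config$sim$n_ref_samples, nrow(reference$occurrences)))
cat(sprintf("planted: %d ecotype pairs; affinities: %s\n",
            nrow(study$truth$ecotype_pairs),
            paste(names(aff), aff, sep = "=", collapse = ", ")))
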