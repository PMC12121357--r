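#' Run configuration
#'
#' Collects every tunable of the full workflow.  Defaults mirror the study
#' analysis: 100 nt minimum overlap for cross-dataset sequence matching,
#' 0.1-degree geographic deduplication, a 5-occurrence floor below which a
#' cASV stays unallocated, a 75% read-coverage rule for key-taxa selection,
#' 9999 permutations for the significance tests and a screen of the 20 most
#' abundant photosynthetic ASVs.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed; the simulator and every permutation test derive
#'   their streams from it.
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param min_overlap minimum overlap (nt) for [cluster_asvs()].
#' @param dedup_precision degrees for [dedup_occurrences()].
#' @param min_samples occurrence floor for [classify_zone_counts()].
#' @param coverage read share for [select_top_taxa()].
#' @param n_permutations permutations for ANOSIM and the indicator screen.
#' @param top_n ASVs screened per indicator comparison.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("asvbiogeo_run_"),
                       seed = 1L,
                       sim = sim_config(seed = seed),
                       min_overlap = 100L,
                       dedup_precision = 0.1,
                       min_samples = 5L,
                       coverage = 0.75,
                       n_permutations = 9999L,
                       top_n = 20L) {
  for (nm in c("min_overlap", "min_samples", "n_permutations", "top_n")) {
    if (!is_count(get(nm))) stop_config(sprintf("%s must be a positive integer", nm))
  }
  if (dedup_precision <= 0) stop_config("dedup_precision must be positive")
  if (coverage <= 0 || coverage > 1) stop_config("coverage must be in (0, 1]")
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), sim = sim,
    min_overlap = as.integer(min_overlap), dedup_precision = dedup_precision,
    min_samples = as.integer(min_samples), coverage = coverage,
    n_permutations = as.integer(n_permutations), top_n = as.integer(top_n)
  ), class = "run_config")
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

#' Read-fraction composition by biogeographical category
#'
#' Splits the study read totals of a set of ASVs by the biogeographical
#' category of their cASV, within each panel of a sample grouping (e.g.
#' substrate x size fraction).  Fractions within a panel sum to 1, with
#' unallocated reads included.
#'
#' @param counts ASV x sample count matrix.
#' @param assignment tibble `asv_id` -> `casv_id` (from [cluster_asvs()]).
#' @param biogeo tibble `casv_id` -> `category` (from [classify_all()]).
#' @param metadata sample metadata tibble with `sample_id`.
#' @param panel_vars metadata columns defining the panels.
#' @return tibble with the panel variables, `category`, `reads`,
#'   `read_fraction`.
#' @export
category_read_fractions <- function(counts, assignment, biogeo, metadata,
                                    panel_vars = c("substrate", "size_fraction")) {
  cat_of <- assignment |>
    left_join(biogeo |> select("casv_id", "category"), by = "casv_id") |>
    mutate(category = tidyr::replace_na(.data$category, "unallocated"))
  long <- tibble(
    asv_id = rep(rownames(counts), times = ncol(counts)),
    sample_id = rep(colnames(counts), each = nrow(counts)),
    reads = as.vector(counts)
  ) |>
    left_join(cat_of, by = "asv_id") |>
    mutate(category = tidyr::replace_na(.data$category, "unallocated")) |>
    left_join(metadata |> select(dplyr::all_of(c("sample_id", panel_vars))),
              by = "sample_id")
  long |>
    group_by(dplyr::across(dplyr::all_of(c(panel_vars, "category")))) |>
    summarise(reads = sum(.data$reads), .groups = "drop_last") |>
    mutate(read_fraction = .data$reads / sum(.data$reads)) |>
    ungroup() |>
    arrange(dplyr::across(dplyr::all_of(panel_vars)), .data$category)
}

#' Run the full analysis workflow on synthetic data
#'
#' Chains every stage: simulate the study and reference corpus, write the
#' input bundle, cluster study against reference ASVs, classify cASV
#' biogeography, filter to photosynthetic taxa, compute species-level
#' relative abundances and key taxa, Bray-Curtis/ANOSIM community tests,
#' indicator screens for substrate and bloom phase, and a report of
#' per-category read fractions.  All artifacts are written under
#' `config$out_dir` with provenance headers; a rerun with the same
#' configuration reproduces every file byte for byte.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with all intermediate and final tables:
#'   `study`, `reference`, `clusters`, `biogeo`, `photo`, `rel_abund`,
#'   `top_taxa`, `bray`, `anosim`, `indicators`, `report`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop_config("config must be a run_config()")
  dir.create(file.path(config$out_dir, "inputs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "results"), recursive = TRUE, showWarnings = FALSE)
  ipath <- function(...) file.path(config$out_dir, "inputs", ...)
  rpath <- function(...) file.path(config$out_dir, "results", ...)

  # stage 1: synthetic study + reference corpus
  study <- simulate_study(config$sim)
  reference <- simulate_reference(config$sim, study)
  write_fasta(study$asv[, c("asv_id", "sequence")], ipath("study_asvs.fasta"))
  write_fasta(reference$ref[, c("ref_id", "sequence")], ipath("reference_asvs.fasta"))
  write_table_prov(counts_to_df(study$counts), ipath("asv_counts.tsv"), config)
  write_table_prov(study$metadata, ipath("sample_metadata.tsv"), config)
  write_table_prov(reference$occurrences, ipath("reference_occurrences.tsv"), config)
  write_json_prov(list(
    zone = as.list(study$truth$zone),
    affinity = as.list(study$truth$affinity),
    trophic = as.list(study$truth$trophic),
    ecotype_pairs = study$truth$ecotype_pairs
  ), ipath("planted_truth.json"), config)

  # stage 2: cASV clustering of study against reference sequences
  entries <- bind_rows(
    tibble(id = study$asv$asv_id, sequence = study$asv$sequence,
           origin = "study", total_reads = rowSums(study$counts)),
    tibble(id = reference$ref$ref_id, sequence = reference$ref$sequence,
           origin = "reference", total_reads = 0)
  )
  clusters <- cluster_asvs(entries, min_overlap = config$min_overlap)
  write_table_prov(clusters$assignment, rpath("casv_assignment.tsv"), config)
  write_table_prov(clusters$members, rpath("casv_members.tsv"), config)

  # stage 3: biogeographical classification
  occ <- reference$occurrences
  if (is.null(occ)) occ <- tibble(ref_id = character(0), sample_id = character(0),
                                  dataset_id = character(0), latitude = numeric(0),
                                  longitude = numeric(0))
  biogeo <- classify_all(clusters, occ, precision = config$dedup_precision,
                         min_samples = config$min_samples)
  write_table_prov(biogeo, rpath("biogeography.tsv"), config)

  # stage 4: community structure on photosynthetic ASVs
  photo <- filter_photosynthetic(study$asv, default_trophic_lookup())
  pcounts <- study$counts[photo$asv_id, , drop = FALSE]
  rel <- relative_abundance(pcounts, grouping = photo$species)
  rel <- rel |>
    left_join(study$metadata |>
                select("sample_id", "substrate", "layer", "size_fraction",
                       "stage", "phase"),
              by = "sample_id")
  top <- select_top_taxa(pcounts, grouping = photo$species,
                         coverage = config$coverage)
  totals <- colSums(pcounts)
  prel <- sweep(pcounts, 2, ifelse(totals == 0, 1, totals), "/")
  bray <- bray_curtis(prel)
  meta <- study$metadata[match(colnames(pcounts), study$metadata$sample_id), ]
  anosim_res <- list(
    substrate = anosim_test(bray, meta$substrate, config$n_permutations,
                            seed = config$seed + 11L),
    size_fraction = anosim_test(bray, meta$size_fraction, config$n_permutations,
                                seed = config$seed + 12L),
    phase = anosim_test(bray, meta$phase, config$n_permutations,
                        seed = config$seed + 13L)
  )
  for (sub in c("ice", "water")) {
    keep <- meta$substrate == sub
    anosim_res[[paste0("stage_", sub)]] <- anosim_test(
      bray[keep, keep], meta$stage[keep], config$n_permutations,
      seed = config$seed + 14L + (sub == "water")
    )
  }
  write_table_prov(rel, rpath("relative_abundance.tsv"), config)
  write_table_prov(top, rpath("top_taxa.tsv"), config)
  write_table_prov(counts_to_df(round(bray, 10)) |>
                     dplyr::rename(sample_id = "asv_id"),
                   rpath("bray_curtis.tsv"), config)
  write_json_prov(lapply(anosim_res, unclass), rpath("anosim.json"), config)

  # stage 5: indicator screen (substrate, bloom phase) on photosynthetic ASVs
  indicators <- run_indicator_screen(
    pcounts, study$metadata, comparisons = c("substrate", "phase"),
    n_top = config$top_n, n_permutations = config$n_permutations,
    seed = config$seed
  )
  write_table_prov(indicators, rpath("indicators.tsv"), config)

  # stage 6: report — category read fractions per panel
  report <- list(
    by_substrate_fraction = category_read_fractions(
      pcounts, clusters$assignment, biogeo, study$metadata,
      panel_vars = c("substrate", "size_fraction")
    ),
    by_stage = category_read_fractions(
      pcounts, clusters$assignment, biogeo, study$metadata,
      panel_vars = "stage"
    ),
    asv_per_category = clusters$assignment |>
      left_join(biogeo |> select("casv_id", "category"), by = "casv_id") |>
      filter(.data$asv_id %in% photo$asv_id) |>
      count(.data$category, name = "n_asvs")
  )
  write_table_prov(report$by_substrate_fraction,
                   rpath("category_fractions_substrate_fraction.tsv"), config)
  write_table_prov(report$by_stage, rpath("category_fractions_stage.tsv"), config)
  write_table_prov(report$asv_per_category, rpath("asvs_per_category.tsv"), config)

  invisible(list(
    config = config, study = study, reference = reference, clusters = clusters,
    biogeo = biogeo, photo = photo, rel_abund = rel, top_taxa = top,
    bray = bray, anosim = anosim_res, indicators = indicators, report = report
  ))
}
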