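#' Simulation configuration for the synthetic study
#'
#' Bundles and validates every knob of the synthetic-data generator.  The
#' defaults describe the emulated study design: a landfast-ice time series
#' with two ice layers and four water depths sampled in three size fractions
#' across an under-ice bloom, matched against a scaled-down global reference
#' occurrence corpus spanning polar, temperate and tropical latitudes.
#'
#' @param seed integer seed; a fixed seed makes every generated table
#'   byte-identical across runs.
#' @param n_taxa number of study ASVs to simulate.
#' @param n_ref_samples number of reference samples in the global occurrence
#'   corpus.
#' @param zone_mix length-3 numeric (polar, temperate, tropical) proportions
#'   of reference samples per latitudinal zone; must sum to 1.
#' @param library_size expected total reads per study sample (per-sample
#'   totals are Poisson around this, then split multinomially).
#' @param affinity_effect multiplicative fold-change applied to a planted
#'   indicator taxon's expected abundance in its preferred substrate or bloom
#'   phase (dimensionless, >= 1).
#' @param stray_rate probability that a planted-zone taxon occurs in a
#'   reference sample outside its true zone (0-1).
#' @param seq_length length of the simulated ASV sequences in nucleotides.
#' @param ecotype_pairs number of planted sequence pairs differing at exactly
#'   one internal position (microdiversity "ecotypes").
#' @param sigma_log standard deviation (log scale) of the log-normal base
#'   abundances; 1.5 gives the strong dominance/rarity spread typical of
#'   amplicon communities.
#' @param ref_presence probability that a reference-represented taxon occurs
#'   in a reference sample of its own zone.
#' @param ref_fraction fraction of study taxa that have a counterpart in the
#'   reference corpus at all; the rest are unique to the study and should be
#'   classified unallocated.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_taxa = 150L,
                       n_ref_samples = 400L,
                       zone_mix = c(polar = 0.30, temperate = 0.45, tropical = 0.25),
                       library_size = 50000L,
                       affinity_effect = 8,
                       stray_rate = 0.005,
                       seq_length = 380L,
                       ecotype_pairs = 3L,
                       sigma_log = 1.5,
                       ref_presence = 0.8,
                       ref_fraction = 0.85) {
  if (!is_count(seed + 1)) stop_config("seed must be a single integer")
  if (!is_count(n_taxa)) stop_config("n_taxa must be a positive integer")
  if (!is_count(library_size)) stop_config("library_size must be a positive integer")
  if (!is_count(n_ref_samples)) stop_config("n_ref_samples must be a positive integer")
  if (!is_count(seq_length) || seq_length < 60) {
    stop_config("seq_length must be a positive integer >= 60")
  }
  if (!is.numeric(zone_mix) || length(zone_mix) != 3L || any(zone_mix < 0) ||
      abs(sum(zone_mix) - 1) > 1e-9) {
    stop_config("zone_mix must be 3 nonnegative proportions summing to 1")
  }
  if (!is.numeric(affinity_effect) || affinity_effect < 1) {
    stop_config("affinity_effect must be >= 1")
  }
  if (stray_rate < 0 || stray_rate > 1) stop_config("stray_rate must be in [0, 1]")
  if (ref_presence <= 0 || ref_presence > 1) stop_config("ref_presence must be in (0, 1]")
  if (ref_fraction < 0 || ref_fraction > 1) stop_config("ref_fraction must be in [0, 1]")
  if (!is.numeric(ecotype_pairs) || ecotype_pairs < 0 ||
      ecotype_pairs != round(ecotype_pairs)) {
    stop_config("ecotype_pairs must be a nonnegative integer")
  }
  if (2L * ecotype_pairs > n_taxa) stop_config("too many ecotype_pairs for n_taxa")
  zone_mix <- stats::setNames(as.numeric(zone_mix), c("polar", "temperate", "tropical"))
  structure(list(
    seed = as.integer(seed), n_taxa = as.integer(n_taxa),
    n_ref_samples = as.integer(n_ref_samples), zone_mix = zone_mix,
    library_size = as.integer(library_size), affinity_effect = affinity_effect,
    stray_rate = stray_rate, seq_length = as.integer(seq_length),
    ecotype_pairs = as.integer(ecotype_pairs), sigma_log = sigma_log,
    ref_presence = ref_presence, ref_fraction = ref_fraction
  ), class = "sim_config")
}

# independent sub-streams for the study and reference generators, both a pure
# function of config$seed so generate_reference(config, study) is reproducible
# on its own
derive_seeds <- function(config) {
  withr::with_seed(config$seed, sample.int(2147483646L, 2L))
}

#' Fixed lineage catalogue used by the simulator
#'
#' A small catalogue of real protist lineages (division; class; genus) spanning
#' the photosynthetic classes that dominate Arctic sympagic and under-ice
#' communities (diatoms, mamiellophytes, haptophytes, cryptophytes, pelagophytes,
#' bolidophytes) plus heterotrophic and mixotrophic classes so that trophic-mode
#' filtering has something to remove.
#'
#' @return a tibble with columns `division`, `class`, `genus`, `trophic_mode`.
#' @export
lineage_catalogue <- function() {
  tribble_rows <- list(
    c("Ochrophyta", "Bacillariophyceae", "Navicula", "photosynthetic"),
    c("Ochrophyta", "Bacillariophyceae", "Nitzschia", "photosynthetic"),
    c("Ochrophyta", "Bacillariophyceae", "Fragilariopsis", "photosynthetic"),
    c("Ochrophyta", "Bacillariophyceae", "Pseudo-nitzschia", "photosynthetic"),
    c("Ochrophyta", "Mediophyceae", "Thalassiosira", "photosynthetic"),
    c("Ochrophyta", "Mediophyceae", "Attheya", "photosynthetic"),
    c("Ochrophyta", "Mediophyceae", "Porosira", "photosynthetic"),
    c("Ochrophyta", "Pelagophyceae", "Ankylochrysis", "photosynthetic"),
    c("Ochrophyta", "Pelagophyceae", "Plocamiomonas", "photosynthetic"),
    c("Ochrophyta", "Bolidophyceae", "Triparma", "photosynthetic"),
    c("Chlorophyta", "Mamiellophyceae", "Micromonas", "photosynthetic"),
    c("Chlorophyta", "Mamiellophyceae", "Bathycoccus", "photosynthetic"),
    c("Chlorophyta", "Pyramimonadophyceae", "Pyramimonas", "photosynthetic"),
    c("Haptophyta", "Prymnesiophyceae", "Phaeocystis", "photosynthetic"),
    c("Haptophyta", "Prymnesiophyceae", "Chrysochromulina", "mixotrophic"),
    c("Cryptophyta", "Cryptophyceae", "Baffinella", "photosynthetic"),
    c("Cryptophyta", "Cryptophyceae", "Geminigera", "photosynthetic"),
    c("Dinoflagellata", "Dinophyceae", "Heterocapsa", "mixotrophic"),
    c("Dinoflagellata", "Dinophyceae", "Gymnodinium", "heterotrophic"),
    c("Dinoflagellata", "Syndiniales", "Amoebophrya", "heterotrophic"),
    c("Ciliophora", "Spirotrichea", "Strombidium", "heterotrophic"),
    c("Ciliophora", "Spirotrichea", "Laboea", "heterotrophic"),
    c("Sagenista", "Labyrinthulea", "Aplanochytrium", "heterotrophic")
  )
  m <- do.call(rbind, tribble_rows)
  tibble(
    division = m[, 1], class = m[, 2], genus = m[, 3], trophic_mode = m[, 4]
  )
}

#' Default trophic-mode lookup table
#'
#' Taxon-name to trophic-mode lookup in the style of curated trophic databases:
#' mostly class-level entries, with genus-level entries where a class mixes
#' modes (e.g. Dinophyceae, Prymnesiophyceae).  Used by
#' [filter_photosynthetic()], which matches the deepest rank present.
#'
#' @return a tibble with columns `taxon` and `trophic_mode`.
#' @export
default_trophic_lookup <- function() {
  cat <- lineage_catalogue()
  by_class <- cat |>
    group_by(.data$class) |>
    summarise(n_modes = dplyr::n_distinct(.data$trophic_mode),
              trophic_mode = .data$trophic_mode[1], .groups = "drop")
  class_rows <- by_class |>
    filter(.data$n_modes == 1L) |>
    transmute(taxon = .data$class, trophic_mode = .data$trophic_mode)
  mixed <- by_class$class[by_class$n_modes > 1L]
  genus_rows <- cat |>
    filter(.data$class %in% mixed) |>
    transmute(taxon = .data$genus, trophic_mode = .data$trophic_mode)
  bind_rows(class_rows, genus_rows)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_base <- function(seq, pos) {
  old <- substr(seq, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  paste0(substr(seq, 1L, pos - 1L), new, substr(seq, pos + 1L, nchar(seq)))
}

# the emulated field campaign: 6 depth layers x 3 size fractions x 9 dates
# covering all three bloom stages, with the stage boundary dates included so
# the half-open stage intervals are exercised
study_design_grid <- function() {
  layers <- c("ICE_0", "ICE_1", "WATER_1", "WATER_2", "WATER_3", "WATER_4")
  fractions <- c("pico", "nano", "micro")
  dates <- as.Date(c(
    "2016-05-01", "2016-05-15", "2016-05-30", "2016-06-03", "2016-06-10",
    "2016-06-15", "2016-06-25", "2016-07-05", "2016-07-18"
  ))
  grid <- expand.grid(layer = layers, size_fraction = fractions, date = dates,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tibble(
    sample_id = sprintf("%s_%s_%s", grid$layer, grid$size_fraction,
                        format(grid$date, "%Y%m%d")),
    substrate = ifelse(startsWith(grid$layer, "ICE"), "ice", "water"),
    layer = grid$layer,
    size_fraction = grid$size_fraction,
    date = grid$date,
    latitude = 67.4797, longitude = -63.7895
  ) |>
    mutate(stage = assign_stage(.data$date),
           phase = ifelse(.data$stage == "I", "dark", "light"))
}

#' Simulate a study ASV table with planted ground truth
#'
#' Generates the full study bundle: an ASV table (sequence + taxonomy), a
#' count matrix over the ice-camp design grid, per-sample metadata, and the
#' planted truth used by recovery tests.  Counts are drawn per sample as a
#' multinomial over log-normal base abundances, with each planted indicator
#' taxon's expected abundance multiplied by `affinity_effect` in its preferred
#' substrate (ice/water) or bloom phase (dark/light).  Planted biogeography
#' labels (polar/temperate/tropical, or unallocated for taxa absent from the
#' reference corpus) and single-mismatch ecotype pairs are recorded in the
#' truth object.
#'
#' @param config a [sim_config()].
#' @return a list with elements `asv` (tibble: asv_id, sequence, taxonomy and
#'   its split ranks), `counts` (integer matrix, ASVs x samples), `metadata`
#'   (tibble, one row per sample), `truth` (list: `zone`, `affinity`,
#'   `trophic`, named by asv_id; `ecotype_pairs` tibble), and `config`.
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  seeds <- derive_seeds(config)
  withr::with_seed(seeds[1], simulate_study_impl(config))
}

simulate_study_impl <- function(config) {
  n <- config$n_taxa
  meta <- study_design_grid()
  cat <- lineage_catalogue()

  # taxonomy: draw lineages weighted so ~3/4 of taxa are photosynthetic
  photo <- cat$trophic_mode != "heterotrophic"
  w <- ifelse(photo, 0.75 / sum(photo), 0.25 / sum(!photo))
  lin <- cat[sample.int(nrow(cat), n, replace = TRUE, prob = w), ]
  species <- paste0(lin$genus, "_sp", sample.int(3L, n, replace = TRUE))
  asv_id <- sprintf("ASV_%04d", seq_len(n))
  taxonomy <- paste(lin$division, lin$class, lin$genus, species, sep = ";")

  # sequences; regenerate on the (astronomically unlikely) duplicate draw so
  # non-ecotype pairs are always at Hamming distance >= 2
  seqs <- random_dna(n, config$seq_length)
  while (anyDuplicated(seqs)) seqs <- random_dna(n, config$seq_length)

  # ecotype pairs: overwrite the second member with a single internal
  # substitution of the first; members are kept photosynthetic when possible
  ec <- tibble(asv_a = character(0), asv_b = character(0), position = integer(0))
  if (config$ecotype_pairs > 0L) {
    photo_idx <- which(lin$trophic_mode != "heterotrophic")
    pool <- if (length(photo_idx) >= 2L * config$ecotype_pairs) photo_idx else seq_len(n)
    picked <- sample(pool, 2L * config$ecotype_pairs)
    a_idx <- picked[seq_len(config$ecotype_pairs)]
    b_idx <- picked[config$ecotype_pairs + seq_len(config$ecotype_pairs)]
    lo <- max(2L, floor(config$seq_length * 0.25))
    hi <- min(config$seq_length - 1L, ceiling(config$seq_length * 0.75))
    pos <- sample(seq(lo, hi), config$ecotype_pairs, replace = TRUE)
    for (k in seq_len(config$ecotype_pairs)) {
      seqs[b_idx[k]] <- mutate_base(seqs[a_idx[k]], pos[k])
      # pair members share a lineage: ecotypes are conspecific variants
      lin[b_idx[k], ] <- lin[a_idx[k], ]
      species[b_idx[k]] <- species[a_idx[k]]
      taxonomy[b_idx[k]] <- taxonomy[a_idx[k]]
    }
    ec <- tibble(asv_a = asv_id[a_idx], asv_b = asv_id[b_idx], position = pos)
  }

  base <- rlnorm(n, meanlog = 0, sdlog = config$sigma_log)

  # planted substrate/phase affinities go to the most abundant photosynthetic
  # taxa (dominant bloom taxa are the substrate specialists), so indicator
  # screens over the top-N abundance ranks can recover them
  affinity <- rep("none", n)
  photo_idx <- which(lin$trophic_mode != "heterotrophic")
  ranked <- photo_idx[order(base[photo_idx], decreasing = TRUE)]
  top <- ranked[seq_len(max(4L, ceiling(0.4 * length(ranked))))]
  kinds <- rep(c("ice", "water", "dark", "light", "none"),
               times = pmax(1L, round(length(top) * c(0.25, 0.25, 0.15, 0.15, 0.20))))
  affinity[top] <- sample(kinds, length(top), replace = length(kinds) < length(top))
  if (nrow(ec) > 0L) {
    # ecotype pairs mirror the ice/pelagic split seen in cryptophyte ecotypes
    affinity[match(ec$asv_a, asv_id)] <- "ice"
    affinity[match(ec$asv_b, asv_id)] <- "water"
  }

  # expected composition per sample, then Poisson total + multinomial split
  boost <- matrix(1, nrow = n, ncol = nrow(meta))
  in_group <- rbind(
    ice = meta$substrate == "ice",
    water = meta$substrate == "water",
    dark = meta$phase == "dark",
    light = meta$phase == "light"
  )
  for (kind in rownames(in_group)) {
    rows <- affinity == kind
    if (any(rows)) boost[rows, in_group[kind, ]] <- config$affinity_effect
  }
  weights <- base * boost
  totals <- rpois(nrow(meta), config$library_size)
  counts <- vapply(seq_len(nrow(meta)), function(j) {
    as.integer(rmultinom(1L, totals[j], weights[, j]))
  }, integer(n))
  dimnames(counts) <- list(asv_id, meta$sample_id)

  # biogeography truth: reference-represented taxa get a single-zone label
  # drawn from zone_mix; study-only taxa are truly unallocated
  has_ref <- runif(n) < config$ref_fraction
  if (nrow(ec) > 0L) has_ref[match(c(ec$asv_a, ec$asv_b), asv_id)] <- TRUE
  zone <- rep("unallocated", n)
  zone[has_ref] <- sample(names(config$zone_mix), sum(has_ref), replace = TRUE,
                          prob = config$zone_mix)

  asv <- tibble(
    asv_id = asv_id, sequence = seqs, taxonomy = taxonomy,
    division = lin$division, class = lin$class, genus = lin$genus,
    species = species
  )
  truth <- list(
    zone = stats::setNames(zone, asv_id),
    affinity = stats::setNames(affinity, asv_id),
    trophic = stats::setNames(lin$trophic_mode, asv_id),
    ecotype_pairs = ec
  )
  list(asv = asv, counts = counts, metadata = meta, truth = truth, config = config)
}

#' Simulate a global reference occurrence corpus
#'
#' Builds the reference side of the biogeography analysis: `n_ref_samples`
#' reference samples with latitudes drawn per `zone_mix` (polar |lat| >= 66,
#' temperate 23-66, tropical < 23) across several dataset ids, one reference
#' ASV per reference-represented study taxon (an exact copy, truncation or
#' flank-extension of the study sequence, so overlap clustering is exercised),
#' and an occurrence table in which each taxon is present in samples of its
#' true zone with probability `ref_presence` and elsewhere with probability
#' `stray_rate`.  One polar station is re-occupied ~25 times within a single
#' dataset at (71.0 N, 70.0 W) with sub-0.05 degree jitter, to exercise
#' geographic deduplication.
#'
#' @param config a [sim_config()].
#' @param study the output of [simulate_study()] (its `truth` provides the
#'   planted zone labels).
#' @return a list with `ref` (tibble: ref_id, source_asv, sequence),
#'   `samples` (tibble: sample_id, dataset_id, latitude, longitude, zone) and
#'   `occurrences` (tibble: ref_id, sample_id, dataset_id, latitude,
#'   longitude).
#' @export
simulate_reference <- function(config, study) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  zones_in_truth <- setdiff(unique(study$truth$zone), "unallocated")
  empty <- names(config$zone_mix)[config$zone_mix == 0]
  if (length(intersect(zones_in_truth, empty)) > 0L) {
    stop_config(sprintf(
      "zone_mix gives zero weight to zone(s) %s present in the planted truth",
      paste(intersect(zones_in_truth, empty), collapse = ", ")
    ))
  }
  seeds <- derive_seeds(config)
  withr::with_seed(seeds[2], simulate_reference_impl(config, study))
}

simulate_reference_impl <- function(config, study) {
  n_ref <- config$n_ref_samples
  zone <- sample(names(config$zone_mix), n_ref, replace = TRUE,
                 prob = config$zone_mix)
  mag <- numeric(n_ref)
  mag[zone == "polar"] <- runif(sum(zone == "polar"), 66, 88)
  mag[zone == "temperate"] <- runif(sum(zone == "temperate"), 23, 66)
  mag[zone == "tropical"] <- runif(sum(zone == "tropical"), 0, 23)
  lat <- round(mag * sample(c(-1, 1), n_ref, replace = TRUE), 4)
  lon <- round(runif(n_ref, -180, 180), 4)
  dataset <- sprintf("DS%02d", sample.int(8L, n_ref, replace = TRUE))

  # repeated-station time series: many revisits of one polar point in one
  # dataset; the station sits on a 0.1-degree grid centre and the jitter stays
  # inside the rounding cell, so deduplication must collapse it to one record
  polar_idx <- which(zone == "polar")
  k <- min(25L, length(polar_idx))
  if (k > 0L) {
    st <- polar_idx[seq_len(k)]
    lat[st] <- round(71.0 + runif(k, -0.02, 0.02), 4)
    lon[st] <- round(-70.0 + runif(k, -0.02, 0.02), 4)
    dataset[st] <- "DS01"
  }
  samples <- tibble(
    sample_id = sprintf("REF_%04d", seq_len(n_ref)),
    dataset_id = dataset, latitude = lat, longitude = lon, zone = zone
  )

  truth <- study$truth
  rep_ids <- names(truth$zone)[truth$zone != "unallocated"]
  asv <- study$asv
  ec_members <- c(truth$ecotype_pairs$asv_a, truth$ecotype_pairs$asv_b)

  make_ref_seq <- function(s, kind) {
    len <- nchar(s)
    switch(kind,
      copy = s,
      trunc = {
        d1 <- sample(5:20, 1L); d2 <- sample(5:20, 1L)
        substr(s, 1L + d1, len - d2)
      },
      extend = paste0(
        paste(sample(c("A", "C", "G", "T"), sample(8:12, 1L), TRUE), collapse = ""),
        s,
        paste(sample(c("A", "C", "G", "T"), sample(8:12, 1L), TRUE), collapse = "")
      )
    )
  }
  kind <- sample(c("copy", "trunc", "extend"), length(rep_ids), replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
  # ecotype-pair references are exact copies: a truncation could cut off the
  # single diagnostic mismatch and spuriously merge the pair
  kind[rep_ids %in% ec_members] <- "copy"
  ref_seq <- vapply(seq_along(rep_ids), function(i) {
    make_ref_seq(asv$sequence[match(rep_ids[i], asv$asv_id)], kind[i])
  }, character(1))
  ref <- tibble(
    ref_id = sub("^ASV", "RASV", rep_ids),
    source_asv = rep_ids,
    sequence = ref_seq
  )

  # occurrence draws: in-zone presence with prob ref_presence, out-of-zone
  # with prob stray_rate
  tz <- truth$zone[rep_ids]
  pmat <- matrix(config$stray_rate, nrow = length(rep_ids), ncol = n_ref)
  for (z in names(config$zone_mix)) {
    pmat[tz == z, samples$zone == z] <- config$ref_presence
  }
  hit <- matrix(runif(length(pmat)) < pmat, nrow = nrow(pmat))
  idx <- which(hit, arr.ind = TRUE)
  occurrences <- tibble(
    ref_id = ref$ref_id[idx[, 1]],
    sample_id = samples$sample_id[idx[, 2]],
    dataset_id = samples$dataset_id[idx[, 2]],
    latitude = samples$latitude[idx[, 2]],
    longitude = samples$longitude[idx[, 2]]
  ) |>
    arrange(.data$ref_id, .data$sample_id)
  list(ref = ref, samples = samples, occurrences = occurrences)
}
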