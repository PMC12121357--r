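test_that("configuration is validated", {
  expect_error(sim_config(n_taxa = 0), class = "asvbiogeo_config_error")
  expect_error(sim_config(library_size = -5), class = "asvbiogeo_config_error")
  expect_error(sim_config(zone_mix = c(0.5, 0.5, 0.5)), class = "asvbiogeo_config_error")
  expect_error(sim_config(affinity_effect = 0.5), class = "asvbiogeo_config_error")
  expect_error(sim_config(n_taxa = 4, ecotype_pairs = 3), class = "asvbiogeo_config_error")
})

test_that("a fixed seed reproduces the study and reference tables exactly", {
  cfg <- sim_config(seed = 11, n_taxa = 50, n_ref_samples = 120)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$asv, s2$asv)
  expect_identical(s1$truth, s2$truth)
  r1 <- simulate_reference(cfg, s1)
  r2 <- simulate_reference(cfg, s1)
  expect_identical(r1$occurrences, r2$occurrences)
  expect_identical(r1$ref, r2$ref)
})

test_that("the design grid covers layers, fractions and all bloom stages", {
  st <- small_sim(seed = 3)$study
  meta <- st$metadata
  expect_setequal(unique(meta$layer),
                  c("ICE_0", "ICE_1", "WATER_1", "WATER_2", "WATER_3", "WATER_4"))
  expect_setequal(unique(meta$size_fraction), c("pico", "nano", "micro"))
  expect_setequal(unique(meta$stage), c("I", "II", "III"))
  expect_identical(meta$phase, ifelse(meta$stage == "I", "dark", "light"))
  # one sample per grid cell
  expect_identical(nrow(meta), 6L * 3L * 9L)
  expect_false(anyDuplicated(meta$sample_id) > 0)
})

test_that("sample read totals stay near the nominal library size", {
  sim <- small_sim(seed = 5)
  tot <- colSums(sim$study$counts)
  lam <- sim$cfg$library_size
  # Poisson totals: individual samples sit within a few sd of the target,
  # and the grand mean is tight
  expect_true(all(abs(tot - lam) <= 4 * sqrt(lam)))
  expect_lt(abs(mean(tot) - lam), 3 * sqrt(lam / length(tot)))
})

test_that("planted ecotype pairs differ at exactly one internal position", {
  for (seed in 1:3) {
    st <- small_sim(seed = seed, ecotype_pairs = 3L)$study
    ec <- st$truth$ecotype_pairs
    expect_identical(nrow(ec), 3L)
    seqs <- setNames(st$asv$sequence, st$asv$asv_id)
    hamming <- function(a, b) {
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }
    for (k in seq_len(nrow(ec))) {
      a <- seqs[ec$asv_a[k]]; b <- seqs[ec$asv_b[k]]
      expect_identical(hamming(a, b), 1L)
      expect_true(substr(a, ec$position[k], ec$position[k]) !=
                    substr(b, ec$position[k], ec$position[k]))
    }
    # every non-planted equal-length pair is at distance >= 2
    planted <- paste(pmin(ec$asv_a, ec$asv_b), pmax(ec$asv_a, ec$asv_b))
    ids <- names(seqs)
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1):length(ids)) {
        if (paste(ids[i], ids[j]) %in% planted) next
        if (nchar(seqs[i]) == nchar(seqs[j])) {
          expect_gte(hamming(seqs[[i]], seqs[[j]]), 2L)
        }
      }
    }
  }
})

test_that("planted ice indicators are more abundant in ice than water", {
  # oracle: direct group means on the emitted table, across 10 seeds
  hits <- 0L; total <- 0L
  for (seed in 1:10) {
    st <- simulate_study(sim_config(seed = seed, n_taxa = 40,
                                    affinity_effect = 8))
    rel <- sweep(st$counts, 2, colSums(st$counts), "/")
    ice <- st$metadata$substrate == "ice"
    planted <- names(st$truth$affinity)[st$truth$affinity == "ice"]
    for (id in planted) {
      total <- total + 1L
      if (mean(rel[id, ice]) > mean(rel[id, !ice])) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("reference latitudes honour the zone pools and stray rate", {
  cfg <- sim_config(seed = 2, n_taxa = 30, n_ref_samples = 100,
                    zone_mix = c(1, 0, 0))
  st <- simulate_study(cfg)
  rf <- simulate_reference(cfg, st)
  expect_true(all(abs(rf$samples$latitude) >= 66))

  # stray_rate = 0: a polar taxon never occurs out of zone
  cfg0 <- sim_config(seed = 4, n_taxa = 30, n_ref_samples = 150, stray_rate = 0)
  st0 <- simulate_study(cfg0)
  rf0 <- simulate_reference(cfg0, st0)
  polar_refs <- sub("^ASV", "RASV",
                    names(st0$truth$zone)[st0$truth$zone == "polar"])
  occ <- rf0$occurrences[rf0$occurrences$ref_id %in% polar_refs, ]
  expect_true(all(abs(occ$latitude) >= 66))
})

test_that("a zone present in the truth but absent from zone_mix is rejected", {
  sim <- small_sim(seed = 6)
  cfg_bad <- sim$cfg
  cfg_bad$zone_mix <- c(polar = 0.5, temperate = 0.5, tropical = 0)
  expect_error(simulate_reference(cfg_bad, sim$study),
               class = "asvbiogeo_config_error")
})

test_that("the repeated station collapses to one occurrence after dedup", {
  sim <- small_sim(seed = 8)
  occ <- sim$ref$occurrences
  station <- occ[occ$dataset_id == "DS01" &
                   abs(occ$latitude - 71) < 0.05, ]
  # many raw records at the station for at least one taxon...
  counts <- table(station$ref_id)
  expect_gt(max(counts), 3)
  id <- names(which.max(counts))
  one <- station[station$ref_id == id, ]
  dd <- dedup_occurrences(
    data.frame(casv_id = one$ref_id, sample_id = one$sample_id,
               dataset_id = one$dataset_id, latitude = one$latitude,
               longitude = one$longitude)
  )
  expect_identical(nrow(dd), 1L)
})
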