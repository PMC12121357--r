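test_that("IndVal components reproduce hand-computed values", {
  g <- c("g1", "g1", "g2", "g2")
  # perfect indicator: all abundance and full fidelity in the target group
  perfect <- indval(c(2, 2, 0, 0), g, "g1")
  expect_equal(perfect$A, 1)
  expect_equal(perfect$B, 1)
  expect_equal(perfect$stat, 1)

  # even abundance: A = 0.5, B = 1, stat = sqrt(0.5)
  even <- indval(c(1, 1, 1, 1), g, "g1")
  expect_equal(even$A, 0.5, tolerance = 1e-12)
  expect_equal(even$B, 1)
  expect_equal(even$stat, sqrt(0.5), tolerance = 1e-12)

  # absent from the target group: no fidelity, zero statistic
  absent_target <- indval(c(0, 0, 3, 1), g, "g1")
  expect_equal(absent_target$B, 0)
  expect_equal(absent_target$stat, 0)

  # absent everywhere: flagged, statistic zero
  gone <- indval(c(0, 0, 0, 0), g, "g1")
  expect_true(gone$absent)
  expect_equal(gone$stat, 0)
})

test_that("the group-size correction uses group means, not pooled sums", {
  # unbalanced design: 1 sample in g1 with abundance 4; 3 samples in g2 with 2
  x <- c(4, 2, 2, 2)
  g <- c("g1", "g2", "g2", "g2")
  res <- indval(x, g, "g1")
  expect_equal(res$A, 4 / (4 + 2), tolerance = 1e-12)
})

test_that("stat and A*B agree, and the stat is scale invariant", {
  withr::with_seed(70, {
    for (k in 1:20) {
      x <- rpois(12, 3) * runif(12)
      g <- sample(rep(c("a", "b", "c"), each = 4))
      r <- indval(x, g, "b")
      expect_equal(r$stat^2, r$A * r$B, tolerance = 1e-12)
      r10 <- indval(10 * x, g, "b")
      expect_equal(r$stat, r10$stat, tolerance = 1e-12)
    }
  })
})

test_that("best_group maximises the statistic with name-order tie-break", {
  g <- c("ice", "ice", "water", "water")
  expect_identical(best_group(c(5, 6, 0, 0), g)$group, "ice")
  # perfectly symmetric abundances: tie broken by group-name order
  expect_identical(best_group(c(1, 1, 1, 1), g)$group, "ice")

  # argmax equals brute-force per-group evaluation on random tables
  withr::with_seed(71, {
    for (k in 1:25) {
      x <- rpois(15, 2) * runif(15)
      g <- sample(rep(c("a", "b", "c"), each = 5))
      got <- best_group(x, g)
      stats <- vapply(c("a", "b", "c"), function(t) indval(x, g, t)$stat, numeric(1))
      expect_identical(got$group, names(stats)[which.max(stats)])
      expect_equal(got$stat, max(stats), tolerance = 1e-12)
    }
  })
})

test_that("a constant taxon has permutation p of exactly 1", {
  x <- rep(3, 12)
  g <- rep(c("ice", "water"), each = 6)
  res <- indval_permutation_test(x, g, n_permutations = 199, seed = 5)
  expect_identical(res$p, 1)
})

test_that("permutation p-values are seed-reproducible and bounded below", {
  withr::with_seed(72, {
    x <- rpois(20, 4) * runif(20)
    g <- rep(c("ice", "water"), each = 10)
  })
  a <- indval_permutation_test(x, g, n_permutations = 99, seed = 17)
  b <- indval_permutation_test(x, g, n_permutations = 99, seed = 17)
  expect_identical(a$p, b$p)
  expect_gte(a$p, 1 / 100)
  expect_error(indval_permutation_test(x, rep("one", 20)),
               class = "asvbiogeo_input_error")
})

test_that("a strongly planted indicator is detected", {
  withr::with_seed(73, {
    x <- c(rlnorm(12, 3, 0.3), rlnorm(12, 0, 0.3))  # ~20x higher in group 1
    g <- rep(c("ice", "water"), each = 12)
    res <- indval_permutation_test(x, g, n_permutations = 999, seed = 3)
    expect_identical(res$group, "ice")
    expect_lt(res$p, 0.05)
  })
})

test_that("the indicator screen emits one row per ASV and comparison", {
  sim <- small_sim(seed = 19)
  photo <- suppressMessages(
    filter_photosynthetic(sim$study$asv, default_trophic_lookup())
  )
  counts <- sim$study$counts[photo$asv_id, ]
  scr <- run_indicator_screen(counts, sim$study$metadata,
                              comparisons = c("substrate", "phase"),
                              n_top = 5, n_permutations = 99, seed = 2)
  expect_identical(nrow(scr), 10L)
  expect_setequal(unique(scr$comparison), c("substrate", "phase"))
  expect_true(all(scr$p >= 1 / 100 & scr$p <= 1))
  expect_true(all(scr$stars[scr$p >= 0.05] == ""))
  expect_true(all(scr$p_holm >= scr$p))

  one <- run_indicator_screen(counts, sim$study$metadata,
                              comparisons = "substrate",
                              n_top = 1, n_permutations = 49, seed = 2)
  expect_identical(nrow(one), 1L)

  # asking for more ASVs than exist screens everything, with a note
  few <- counts[1:3, ]
  expect_message(
    all3 <- run_indicator_screen(few, sim$study$metadata,
                                 comparisons = "substrate",
                                 n_top = 20, n_permutations = 49, seed = 2),
    "screening all"
  )
  expect_identical(nrow(all3), 3L)
})

test_that("planted substrate indicators in the top ranks are recovered", {
  sim <- small_sim(seed = 23, affinity_effect = 8)
  photo <- filter_photosynthetic(sim$study$asv, default_trophic_lookup())
  counts <- sim$study$counts[photo$asv_id, ]
  scr <- run_indicator_screen(counts, sim$study$metadata,
                              comparisons = "substrate",
                              n_top = 20, n_permutations = 499, seed = 4)
  aff <- sim$study$truth$affinity
  planted_ice <- intersect(scr$asv_id, names(aff)[aff == "ice"])
  hit <- scr[scr$asv_id %in% planted_ice, ]
  expect_gt(length(planted_ice), 0)
  expect_true(all(hit$group == "ice" & hit$p < 0.05))
})
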