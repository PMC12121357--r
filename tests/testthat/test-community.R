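test_that("bloom stages follow the campaign calendar with half-open bounds", {
  expect_identical(assign_stage(as.Date("2016-05-10")), "I")
  expect_identical(assign_stage(as.Date("2016-06-03")), "II")  # boundary -> later stage
  expect_identical(assign_stage(as.Date("2016-06-15")), "III")
  expect_identical(assign_stage(as.Date("2016-07-18")), "III")
  expect_identical(assign_stage(as.Date(c("2016-05-01", "2016-06-02", "2016-06-14"))),
                   c("I", "I", "II"))
  expect_error(assign_stage(as.Date("2016-04-30")), class = "asvbiogeo_input_error")
  expect_error(assign_stage(as.Date("2016-07-19")), class = "asvbiogeo_input_error")
  expect_error(assign_stage("not-a-date"), class = "asvbiogeo_input_error")
})

test_that("trophic filtering keeps photosynthetic and mixotrophic taxa", {
  asv <- tibble::tibble(
    asv_id = sprintf("A%d", 1:5),
    taxonomy = c(
      "Ochrophyta;Bacillariophyceae;Navicula;Navicula_sp1",     # photo (class)
      "Dinoflagellata;Dinophyceae;Heterocapsa;Heterocapsa_sp1", # mixo (genus)
      "Dinoflagellata;Dinophyceae;Gymnodinium;Gymnodinium_sp1", # het (genus)
      "Ciliophora;Spirotrichea;Strombidium;Strombidium_sp1",    # het (class)
      "Unknown;UnknownClass;UnknownGenus;UnknownGenus_sp1"      # unmatched
    )
  )
  expect_message(out <- filter_photosynthetic(asv, default_trophic_lookup()),
                 "without trophic annotation")
  expect_setequal(out$asv_id, c("A1", "A2"))
  expect_error(filter_photosynthetic(asv, data.frame()),
               class = "asvbiogeo_config_error")
  empty <- filter_photosynthetic(asv[0, ], default_trophic_lookup())
  expect_identical(nrow(empty), 0L)
})

test_that("the deepest matching rank wins in the trophic lookup", {
  lookup <- tibble::tibble(taxon = c("ClassX", "GenusY"),
                           trophic_mode = c("heterotrophic", "photosynthetic"))
  asv <- tibble::tibble(asv_id = "A1", taxonomy = "Div;ClassX;GenusY;GenusY_sp1")
  expect_identical(filter_photosynthetic(asv, lookup)$asv_id, "A1")
})

test_that("the synthetic photosynthetic set matches the planted trophic truth", {
  sim <- small_sim(seed = 14)
  out <- filter_photosynthetic(sim$study$asv, default_trophic_lookup())
  truth <- sim$study$truth$trophic
  expect_setequal(out$asv_id, names(truth)[truth != "heterotrophic"])
})

test_that("relative abundances are proportions that sum to one per sample", {
  counts <- matrix(c(3, 1, 0, 0), nrow = 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(out <- relative_abundance(counts), "zero reads")
  s1 <- out[out$sample_id == "s1", ]
  expect_equal(s1$proportion[s1$taxon == "a"], 0.75)
  expect_equal(s1$proportion[s1$taxon == "b"], 0.25)
  expect_equal(out$proportion[out$sample_id == "s2"], c(0, 0))

  # aggregation: two ASVs of one species sum their proportions
  counts2 <- matrix(c(3, 1, 4), ncol = 1,
                    dimnames = list(c("a1", "a2", "b1"), "s1"))
  agg <- relative_abundance(counts2, grouping = c("spA", "spA", "spB"))
  expect_equal(agg$proportion[agg$taxon == "spA"], 0.5)

  sim <- small_sim(seed = 15)
  ra <- relative_abundance(sim$study$counts)
  sums <- tapply(ra$proportion, ra$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(relative_abundance(-counts), class = "asvbiogeo_input_error")
})

test_that("top-taxa selection finds the minimal covering prefix", {
  counts <- matrix(c(50, 30, 20), ncol = 1,
                   dimnames = list(c("x", "y", "z"), "s1"))
  expect_identical(select_top_taxa(counts, coverage = 0.75)$taxon, c("x", "y"))
  expect_identical(select_top_taxa(counts, coverage = 1)$taxon, c("x", "y", "z"))
  # zero-read taxa are never selected at full coverage
  counts0 <- rbind(counts, w = 0)
  expect_false("w" %in% select_top_taxa(counts0, coverage = 1)$taxon)

  # brute-force minimal-prefix oracle on random tables
  withr::with_seed(33, {
    for (k in 1:20) {
      m <- matrix(rpois(60, 30), nrow = 12,
                  dimnames = list(sprintf("t%02d", 1:12), sprintf("s%d", 1:5)))
      cov <- runif(1, 0.3, 0.95)
      got <- select_top_taxa(m, coverage = cov)$taxon
      tot <- sort(rowSums(m), decreasing = TRUE)
      shares <- cumsum(tot) / sum(tot)
      n_min <- which(shares >= cov)[1]
      expect_identical(length(got), as.integer(n_min))
      expect_gte(sum(rowSums(m)[got]) / sum(m), cov)
    }
  })
  expect_error(select_top_taxa(matrix(numeric(0), 0, 0)),
               class = "asvbiogeo_input_error")
})

test_that("Bray-Curtis reproduces the defining formula", {
  m <- matrix(c(1, 1, 1, 0), nrow = 2, dimnames = list(c("t1", "t2"), c("a", "b")))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 1 / 3, tolerance = 1e-12)  # 1 - 2*1/(2+1)
  ident <- matrix(c(5, 3, 5, 3), nrow = 2,
                  dimnames = list(c("t1", "t2"), c("a", "b")))
  expect_equal(bray_curtis(ident)["a", "b"], 0)
  disjoint <- matrix(c(5, 0, 0, 3), nrow = 2,
                     dimnames = list(c("t1", "t2"), c("a", "b")))
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)

  withr::with_seed(40, {
    m <- matrix(rpois(60, 10), nrow = 6,
                dimnames = list(sprintf("t%d", 1:6), sprintf("s%d", 1:10)))
    d <- bray_curtis(m)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    # hand formula on one random pair
    a <- m[, 3]; b <- m[, 7]
    expect_equal(d[3, 7], 1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b)),
                 tolerance = 1e-12)
  })

  zz <- matrix(c(0, 0, 0, 0, 1, 2), nrow = 2,
               dimnames = list(c("t1", "t2"), c("a", "b", "c")))
  expect_warning(dz <- bray_curtis(zz), "all-zero")
  expect_equal(dz["a", "b"], 0)
})

test_that("ANOSIM attains its limits and matches vegan on random data", {
  # perfect separation: every between-group pair exceeds every within pair
  d <- matrix(0.9, 6, 6)
  d[1:3, 1:3] <- 0.1; d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  g <- rep(c("x", "y"), each = 3)
  expect_equal(anosim_test(d, g, n_permutations = 99, seed = 1)$R, 1)

  # all dissimilarities equal: fully tied ranks, R = 0
  d0 <- matrix(0.5, 6, 6); diag(d0) <- 0
  expect_equal(anosim_test(d0, g, n_permutations = 99, seed = 1)$R, 0)

  # agreement with the vegan implementation on random communities
  withr::with_seed(50, {
    m <- matrix(rpois(15 * 40, 20), nrow = 40,
                dimnames = list(sprintf("t%d", 1:40), sprintf("s%d", 1:15)))
    grp <- rep(c("a", "b", "c"), each = 5)
    d <- bray_curtis(m)
    ours <- anosim_test(d, grp, n_permutations = 0, seed = 1)
    ref <- vegan::anosim(stats::as.dist(d), grp, permutations = 0)
    expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-12)
  })
})

test_that("ANOSIM p-values are reproducible and bounded below", {
  withr::with_seed(60, {
    m <- matrix(rpois(12 * 30, 15), nrow = 30)
    colnames(m) <- sprintf("s%d", 1:12); rownames(m) <- sprintf("t%d", 1:30)
    d <- bray_curtis(m)
    g <- rep(c("a", "b"), each = 6)
  })
  r1 <- anosim_test(d, g, n_permutations = 199, seed = 99)
  r2 <- anosim_test(d, g, n_permutations = 199, seed = 99)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 200)
  expect_error(anosim_test(d, rep("a", 12)), class = "asvbiogeo_input_error")
  expect_error(anosim_test(d, c("a", rep("b", 11))), class = "asvbiogeo_input_error")
})
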