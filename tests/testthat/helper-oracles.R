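# Independent oracles, written deliberately differently from the package
# implementations (character-vector loops, explicit if/else chains), plus
# small instance generators shared across test files.

# overlap oracle: explicit character-level scan of every alignment offset
oracle_overlap <- function(a, b, min_overlap) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  na <- length(va); nb <- length(vb)
  # substring: slide the shorter over the longer
  s <- if (na <= nb) va else vb
  l <- if (na <= nb) vb else va
  for (off in 0:(length(l) - length(s))) {
    if (all(s == l[off + seq_along(s)])) return(TRUE)
  }
  # suffix/prefix overlaps of length L >= min_overlap in both orientations
  for (L in seq_len(min(na, nb) - 1L)) {
    if (L < min_overlap) next
    if (all(va[(na - L + 1L):na] == vb[1:L])) return(TRUE)
    if (all(vb[(nb - L + 1L):nb] == va[1:L])) return(TRUE)
  }
  FALSE
}

# brute-force clustering oracle: all-pairs overlap + connected components
oracle_partition <- function(ids, seqs, min_overlap) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (oracle_overlap(seqs[i], seqs[j], min_overlap)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(ids, roots), function(m) sort(m)))
}

canonical_partition <- function(groups) {
  # groups: list of character vectors -> canonical sorted-of-sorted form
  out <- unname(lapply(groups, sort))
  out[order(vapply(out, `[`, character(1), 1L))]
}

# independently coded biogeography rule evaluator (plain if/else on percents)
oracle_classify <- function(p, t, r, min_samples = 5) {
  n <- p + t + r
  if (n < min_samples) return("unallocated")
  pp <- 100 * p / n; pt <- 100 * t / n; pr <- 100 * r / n
  if (pp >= 90) return("polar")
  if (pt >= 90) return("temperate")
  if (pr >= 90) return("tropical")
  if (pp + pt >= 90) return("polar-temperate")
  if (pt + pr >= 90) return("temperate-tropical")
  if (p >= 1 && t >= 1 && r >= 1) return("cosmopolitan")
  "unallocated"
}

rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")

# clustering instance: families of sequence variants derived from distinct
# random base sequences; each family is internally connected under the
# overlap rule (copies, truncations, at most one flank extension), so
# tie-break assignment and transitive merging give the same partition
random_cluster_instance <- function(seed, n_base = 25, len = 250, min_overlap = 100) {
  withr::with_seed(seed, {
    entries <- list()
    expected <- list()
    for (b in seq_len(n_base)) {
      s <- rand_seq(len)
      fam_study <- sample(0:2, 1)   # study members in the family
      fam_ref <- sample(0:3, 1)     # reference members
      if (fam_study + fam_ref == 0) fam_study <- 1L
      # several study copies only share a cASV through a common reference
      # member, so multi-study families always carry one
      if (fam_study > 1 && fam_ref == 0) fam_ref <- 1L
      ids <- character(0)
      variant <- function(kind) {
        switch(kind,
          copy = s,
          trunc = {
            d1 <- sample(0:30, 1); d2 <- sample(0:30, 1)
            substr(s, 1 + d1, len - d2)
          },
          extend = paste0(rand_seq(sample(5:12, 1)), s, rand_seq(sample(5:12, 1)))
        )
      }
      kinds_ref <- character(0)
      if (fam_ref > 0) {
        kinds_ref <- sample(c("copy", "trunc"), fam_ref, replace = TRUE)
        if (fam_ref > 1 && runif(1) < 0.3) kinds_ref[1] <- "extend"
      }
      for (k in seq_len(fam_study)) {
        id <- sprintf("S%03d_%d", b, k)
        entries[[length(entries) + 1]] <- data.frame(
          id = id, sequence = s, origin = "study",
          total_reads = sample(100:10000, 1)
        )
        ids <- c(ids, id)
      }
      for (k in seq_len(fam_ref)) {
        id <- sprintf("R%03d_%d", b, k)
        entries[[length(entries) + 1]] <- data.frame(
          id = id, sequence = variant(kinds_ref[k]), origin = "reference",
          total_reads = 0
        )
        ids <- c(ids, id)
      }
      expected[[b]] <- ids
    }
    list(entries = do.call(rbind, entries), families = expected)
  })
}

# small, fast simulation bundle used by several test files
small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, n_taxa = 40L, n_ref_samples = 150L,
                    library_size = 20000L, ...)
  study <- simulate_study(cfg)
  ref <- simulate_reference(cfg, study)
  list(cfg = cfg, study = study, ref = ref)
}

cluster_entries <- function(study, ref) {
  rbind(
    data.frame(id = study$asv$asv_id, sequence = study$asv$sequence,
               origin = "study", total_reads = rowSums(study$counts)),
    data.frame(id = ref$ref$ref_id, sequence = ref$ref$sequence,
               origin = "reference", total_reads = 0)
  )
}
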