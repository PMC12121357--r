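#' Indicator value of one ASV for one group
#'
#' Group-size-corrected IndVal: specificity A is the target group's mean
#' abundance divided by the sum of all group mean abundances (so unequal
#' group sizes do not bias A), fidelity B is the fraction of target-group
#' samples in which the ASV is present, and the reported statistic is
#' sqrt(A * B).  Abundances are typically per-sample relative abundances,
#' which makes A robust to unequal library sizes; the statistic itself is
#' invariant to rescaling all abundances by a positive constant.
#'
#' @param x numeric vector of per-sample abundances of one ASV.
#' @param groups group label per sample.
#' @param target the group to score.
#' @return list with `A`, `B`, `stat`, and `absent` (TRUE when the ASV has
#'   zero abundance everywhere, in which case A is undefined/NA and stat is 0).
#' @examples
#' indval(c(2, 2, 0, 0), c("ice", "ice", "water", "water"), "ice")  # perfect
#' indval(c(1, 1, 1, 1), c("ice", "ice", "water", "water"), "ice")  # A = 0.5
#' @export
indval <- function(x, groups, target) {
  if (length(x) != length(groups)) stop_input("x and groups lengths differ")
  groups <- as.character(groups)
  if (!target %in% groups) stop_input(sprintf("target group '%s' has no samples", target))
  if (any(x < 0)) stop_input("abundances must be nonnegative")
  gm <- tapply(x, groups, mean)
  B <- mean(x[groups == target] > 0)
  if (sum(gm) == 0) {
    return(list(A = NA_real_, B = B, stat = 0, absent = TRUE))
  }
  A <- unname(gm[target] / sum(gm))
  list(A = A, B = B, stat = sqrt(A * B), absent = FALSE)
}

# IndVal best-group statistics for a batch of label assignments at once.
# memb: n x P matrix of labels (each column one labelling); returns per column
# the max over groups of sqrt(A_g * B_g) and which group attains it.
indval_best_batch <- function(x, memb, levels) {
  p_cols <- ncol(memb)
  xpos <- as.numeric(x > 0)
  means <- matrix(0, nrow = length(levels), ncol = p_cols)
  bs <- matrix(0, nrow = length(levels), ncol = p_cols)
  for (gi in seq_along(levels)) {
    sel <- memb == levels[gi]
    sizes <- colSums(sel)
    means[gi, ] <- colSums(x * sel) / sizes
    bs[gi, ] <- colSums(xpos * sel) / sizes
  }
  tot <- colSums(means)
  tot[tot == 0] <- NA_real_
  stats <- sqrt(sweep(means, 2, tot, "/") * bs)
  stats[is.na(stats)] <- 0
  best <- apply(stats, 2, which.max)  # ties -> first group in level order
  list(stat = stats[cbind(best, seq_len(p_cols))], group = levels[best],
       all = stats)
}

#' Best-associated group for one ASV
#'
#' Evaluates [indval()] against every group and returns the group with the
#' largest statistic; ties are broken by group-name sort order.
#'
#' @inheritParams indval
#' @return list with `group`, `A`, `B`, `stat`.
#' @export
best_group <- function(x, groups) {
  groups <- as.character(groups)
  levels <- sort(unique(groups))
  if (length(levels) < 2L) stop_input("need at least 2 groups")
  res <- lapply(levels, function(g) indval(x, groups, g))
  stats <- vapply(res, `[[`, numeric(1), "stat")
  k <- which.max(stats)  # which.max takes the first (alphabetical) tie
  c(list(group = levels[k]), res[[k]])
}

#' Permutation test of the IndVal association
#'
#' Observed statistic is the best-group IndVal; group labels are then
#' permuted uniformly `n_permutations` times, the best-group statistic is
#' recomputed for each relabelling, and
#' p = (#\{permuted >= observed\} + 1) / (n_permutations + 1).
#' Deterministic given `seed`.
#'
#' @inheritParams indval
#' @param n_permutations number of label permutations.
#' @param seed integer seed.
#' @return list with `group`, `A`, `B`, `stat`, `p`, `n_permutations`,
#'   `absent`.
#' @export
indval_permutation_test <- function(x, groups, n_permutations = 9999L, seed = 1L) {
  groups <- as.character(groups)
  levels <- sort(unique(groups))
  if (length(levels) < 2L) stop_input("permutation test needs >= 2 groups")
  if (!is_count(n_permutations)) stop_input("n_permutations must be a positive integer")
  obs <- best_group(x, groups)
  n <- length(groups)
  perm_stat <- withr::with_seed(seed, {
    memb <- vapply(seq_len(n_permutations), function(k) sample(groups), character(n))
    indval_best_batch(x, memb, levels)$stat
  })
  p <- (sum(perm_stat >= obs$stat - 1e-12) + 1) / (n_permutations + 1)
  c(obs, list(p = p, n_permutations = as.integer(n_permutations)))
}

signif_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Indicator screen of the most abundant ASVs
#'
#' Screens the `n_top` most abundant ASVs (by total reads; ties by id) for
#' association with each sample grouping in `comparisons` — typically
#' substrate (ice vs water) and bloom phase (dark = stage I vs light =
#' stages II + III).  Abundances are normalised per sample before scoring.
#' Raw permutation p-values are starred at 0.05 / 0.01 / 0.001; a
#' Holm-adjusted column is emitted alongside for reference but not used for
#' the flags.
#'
#' @param counts numeric matrix, ASVs x samples (typically restricted to
#'   photosynthetic ASVs beforehand).
#' @param metadata tibble with `sample_id` and one column per comparison.
#' @param comparisons named character vector or character vector of metadata
#'   column names to test (default `c("substrate", "phase")`).
#' @param n_top number of top-abundance ASVs to screen (default 20; if the
#'   table is smaller, all ASVs are screened and a note is emitted).
#' @param n_permutations permutations per test.
#' @param seed integer seed; each ASV x comparison test gets its own derived
#'   sub-seed.
#' @return tibble with columns `asv_id`, `comparison`, `group`, `A`, `B`,
#'   `stat`, `p`, `p_holm`, `stars`.
#' @export
run_indicator_screen <- function(counts, metadata,
                                 comparisons = c("substrate", "phase"),
                                 n_top = 20L, n_permutations = 9999L,
                                 seed = 1L) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_input("counts must be a matrix with ASV row names and sample column names")
  }
  metadata <- as_tibble(metadata)
  if (!all(colnames(counts) %in% metadata$sample_id)) {
    stop_input("metadata does not cover all samples in the count matrix")
  }
  missing_cols <- setdiff(comparisons, names(metadata))
  if (length(missing_cols) > 0L) {
    stop_input(sprintf("metadata lacks comparison column(s): %s",
                       paste(missing_cols, collapse = ", ")))
  }
  meta <- metadata[match(colnames(counts), metadata$sample_id), ]
  if (n_top > nrow(counts)) {
    inform(sprintf("n_top = %d exceeds the %d available ASVs; screening all",
                   n_top, nrow(counts)))
    n_top <- nrow(counts)
  }
  ord <- order(-rowSums(counts), rownames(counts))
  top_ids <- rownames(counts)[ord[seq_len(n_top)]]

  totals <- colSums(counts)
  rel <- sweep(counts, 2, ifelse(totals == 0, 1, totals), "/")

  out <- list()
  for (cmp in comparisons) {
    groups <- as.character(meta[[cmp]])
    for (i in seq_along(top_ids)) {
      id <- top_ids[i]
      sub_seed <- (seed + 7919L * match(cmp, comparisons) + i) %% 2147483647L
      res <- indval_permutation_test(rel[id, ], groups,
                                     n_permutations = n_permutations,
                                     seed = sub_seed)
      out[[length(out) + 1L]] <- tibble(
        asv_id = id, comparison = cmp, group = res$group,
        A = res$A %||% NA_real_, B = res$B, stat = res$stat, p = res$p
      )
    }
  }
  bind_rows(out) |>
    group_by(.data$comparison) |>
    mutate(p_holm = stats::p.adjust(.data$p, method = "holm")) |>
    ungroup() |>
    mutate(stars = signif_stars(.data$p))
}
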