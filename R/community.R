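#' Bloom stage of a sampling date
#'
#' Assigns the three under-ice bloom stages of the 2016 ice-camp time series:
#' stage I (snow-covered) from May 1 up to but excluding June 3, stage II
#' (snow-melt) from June 3 up to but excluding June 15, and stage III
#' (ice-melt) from June 15 through July 18.  Interval boundaries are
#' half-open, so a boundary date belongs to the later stage.
#'
#' @param date a `Date` vector (or strings coercible to dates) within
#'   2016-05-01 .. 2016-07-18.
#' @return character vector of `"I"`, `"II"`, `"III"`.
#' @examples
#' assign_stage(as.Date(c("2016-05-10", "2016-06-03", "2016-07-18")))
#' @export
assign_stage <- function(date) {
  date <- tryCatch(as.Date(date), error = function(e) NA)
  if (any(is.na(date))) stop_input("unparseable sampling date")
  lo <- as.Date("2016-05-01"); hi <- as.Date("2016-07-18")
  if (any(date < lo | date > hi)) {
    stop_input(sprintf("sampling date out of campaign range %s..%s", lo, hi))
  }
  dplyr::case_when(
    date < as.Date("2016-06-03") ~ "I",
    date < as.Date("2016-06-15") ~ "II",
    TRUE ~ "III"
  )
}

# rank names in lineage order, deepest last, matching the taxonomy strings
split_taxonomy <- function(taxonomy) {
  strsplit(taxonomy, ";", fixed = TRUE)
}

#' Keep photosynthetic ASVs
#'
#' Retains ASVs whose deepest taxon with an entry in the trophic-mode lookup
#' is photosynthetic or mixotrophic (mixotrophs photosynthesise and are
#' kept).  The lookup can mix ranks: a genus-level entry overrides a
#' class-level one for that genus.  ASVs whose lineage matches nothing in the
#' lookup are dropped, with an informational count.
#'
#' @param asv tibble with columns `asv_id` and `taxonomy`
#'   (`"Division;Class;Genus;Species"` strings).
#' @param trophic lookup tibble with columns `taxon` and `trophic_mode`
#'   (values `photosynthetic`, `mixotrophic`, `heterotrophic`), e.g.
#'   [default_trophic_lookup()].
#' @return the subset of `asv` rows retained, with a `trophic_mode` column.
#' @export
filter_photosynthetic <- function(asv, trophic) {
  asv <- as_tibble(asv)
  trophic <- as_tibble(trophic)
  if (nrow(trophic) == 0L || !all(c("taxon", "trophic_mode") %in% names(trophic))) {
    stop_config("trophic lookup must be a nonempty table with columns taxon, trophic_mode")
  }
  if (nrow(asv) == 0L) return(mutate(asv, trophic_mode = character(0)))
  modes <- vapply(split_taxonomy(asv$taxonomy), function(ranks) {
    hit <- match(rev(ranks), trophic$taxon)  # deepest rank first
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) NA_character_ else trophic$trophic_mode[hit[1L]]
  }, character(1))
  n_unmatched <- sum(is.na(modes))
  if (n_unmatched > 0L) {
    inform(sprintf("filter_photosynthetic: %d ASV(s) without trophic annotation dropped",
                   n_unmatched))
  }
  asv |>
    mutate(trophic_mode = modes) |>
    filter(.data$trophic_mode %in% c("photosynthetic", "mixotrophic"))
}

#' Species-level relative abundances
#'
#' Aggregates ASV counts to an arbitrary grouping (typically species) and
#' normalises within each sample, so proportions sum to 1 per sample.
#' Samples with zero total reads yield all-zero rows and a warning.
#'
#' @param counts numeric matrix, taxa x samples, nonnegative.
#' @param grouping character vector along `rownames(counts)` giving the
#'   aggregation key (e.g. species name); defaults to the row names (no
#'   aggregation).
#' @return long tibble with columns `sample_id`, `taxon`, `reads`,
#'   `proportion`.
#' @export
relative_abundance <- function(counts, grouping = rownames(counts)) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_input("counts must be a numeric matrix (taxa x samples)")
  }
  if (any(counts < 0)) stop_input("counts must be nonnegative")
  if (length(grouping) != nrow(counts)) {
    stop_input("grouping must have one entry per count-matrix row")
  }
  agg <- rowsum(counts, group = grouping, reorder = TRUE)
  totals <- colSums(agg)
  if (any(totals == 0)) {
    warn(sprintf("%d sample(s) with zero reads: all-zero proportion rows emitted",
                 sum(totals == 0)))
  }
  prop <- sweep(agg, 2, ifelse(totals == 0, 1, totals), "/")
  tibble(
    sample_id = rep(colnames(agg), each = nrow(agg)),
    taxon = rep(rownames(agg), times = ncol(agg)),
    reads = as.vector(agg),
    proportion = as.vector(prop)
  )
}

#' Smallest set of taxa covering a read share
#'
#' Ranks taxa by total reads (ties broken by name) and returns the smallest
#' prefix whose cumulative share of all reads reaches `coverage` — the rule
#' used to pick the key taxa shown in community-composition panels (e.g. the
#' taxa jointly holding 75% of all photosynthetic reads).
#'
#' @param counts numeric matrix, taxa x samples.
#' @param grouping aggregation key along rows (default row names).
#' @param coverage target cumulative read share in (0, 1].
#' @return tibble with `taxon`, `reads`, `share`, `cum_share`, in rank order.
#' @export
select_top_taxa <- function(counts, grouping = rownames(counts), coverage = 0.75) {
  if (!is.numeric(coverage) || length(coverage) != 1L || coverage <= 0 || coverage > 1) {
    stop_input("coverage must be in (0, 1]")
  }
  if (!is.matrix(counts) || nrow(counts) == 0L) stop_input("counts must be a nonempty matrix")
  totals <- rowsum(rowSums(counts), group = grouping, reorder = TRUE)
  tot <- tibble(taxon = rownames(totals), reads = as.vector(totals)) |>
    arrange(desc(.data$reads), .data$taxon) |>
    mutate(share = .data$reads / sum(.data$reads),
           cum_share = cumsum(.data$share))
  if (sum(tot$reads) == 0) stop_input("no reads in count table")
  n_keep <- which(tot$cum_share >= coverage - 1e-12)[1L]
  if (coverage == 1) n_keep <- sum(tot$reads > 0)
  tot[seq_len(n_keep), ]
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computes d(a, b) = 1 - 2 * sum(min(a_i, b_i)) / (sum(a_i) + sum(b_i))
#' between all sample pairs (columns).  Pairs where both samples are all-zero
#' are undefined; they are set to 0 with a warning so that downstream
#' rank-based tests are not poisoned by NaN.
#'
#' @param counts numeric matrix, taxa x samples, at least 2 samples.
#' @return symmetric numeric matrix of dissimilarities in \[0, 1\] with zero
#'   diagonal, dimnames = sample names.
#' @export
bray_curtis <- function(counts) {
  if (!is.matrix(counts) || ncol(counts) < 2L) {
    stop_input("counts must be a matrix with at least 2 samples (columns)")
  }
  if (any(counts < 0)) stop_input("counts must be nonnegative")
  # vegdist warns about empty rows on its own; the package-level warning
  # below covers that case with the chosen 0 convention
  d <- as.matrix(suppressWarnings(vegan::vegdist(t(counts), method = "bray")))
  if (any(!is.finite(d))) {
    warn("all-zero sample pair(s): Bray-Curtis undefined, set to 0")
    d[!is.finite(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test for differences in community composition
#' between groups.  With the off-diagonal dissimilarities ranked (ties
#' averaged), R = (mean rank between groups - mean rank within groups) /
#' (n(n-1)/4); R is 1 when all between-group pairs are more dissimilar than
#' every within-group pair, near 0 under random grouping.  Significance is a
#' one-sided permutation p-value over random relabellings:
#' p = (#\{permuted R >= observed R\} + 1) / (n_permutations + 1).
#'
#' @param d symmetric dissimilarity matrix (e.g. [bray_curtis()]).
#' @param groups grouping vector along the samples; at least 2 groups with at
#'   least 2 members each.
#' @param n_permutations number of random relabellings.
#' @param seed integer seed making the permutation stream reproducible.
#' @return list of class `anosim_result`: `R`, `p`, `n_permutations`,
#'   `n_samples`.
#' @export
anosim_test <- function(d, groups, n_permutations = 9999L, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || n != length(groups)) {
    stop_input("d must be square with one row per group label")
  }
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop_input("ANOSIM needs >= 2 groups with >= 2 samples each")
  }
  if (!identical(as.numeric(n_permutations), 0) && !is_count(n_permutations)) {
    stop_input("n_permutations must be a nonnegative integer")
  }
  lower <- which(lower.tri(d))
  rk <- rank(d[lower])  # ties averaged
  pair_i <- row(d)[lower]
  pair_j <- col(d)[lower]
  denom <- n * (n - 1) / 4
  r_stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  r_obs <- r_stat(groups)
  p <- NA_real_
  if (n_permutations > 0L) {
    perm_r <- withr::with_seed(seed, vapply(
      seq_len(n_permutations), function(k) r_stat(sample(groups)), numeric(1)
    ))
    p <- (sum(perm_r >= r_obs) + 1) / (n_permutations + 1)
  }
  structure(list(R = r_obs, p = p, n_permutations = as.integer(n_permutations),
                 n_samples = n), class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4g (%d permutations, %d samples)\n",
              x$R, x$p, x$n_permutations, x$n_samples))
  invisible(x)
}
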