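#' Exact identity over overlap regions
#'
#' Two ASV sequences "match" when they are 100% identical over their overlap
#' region: either one is an exact substring of the other, or a suffix of one
#' equals a prefix of the other with overlap length at least `min_overlap`
#' and zero mismatches.  This is the cross-dataset matching rule used to
#' merge study ASVs with reference ASVs that were trimmed to different primer
#' boundaries; matching is gapless by design (amplicon variants of one locus
#' differ by trimming, not indels).  The relation is symmetric and reflexive
#' but not transitive.
#'
#' @param a,b DNA strings (uppercase A/C/G/T).
#' @param min_overlap minimum suffix/prefix overlap length (nt) for a
#'   non-substring match.
#' @return `TRUE` if the sequences match, else `FALSE`.
#' @examples
#' overlap_match("ACGTACGT", "GTACGTAA", min_overlap = 6)  # suffix/prefix
#' overlap_match("ACGTACGT", "ACGAACGT", min_overlap = 6)  # 1 mismatch
#' @export
overlap_match <- function(a, b, min_overlap = 100L) {
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b) ||
      !nzchar(a) || !nzchar(b)) {
    stop_input("overlap_match() needs two nonempty sequences")
  }
  if (!is_count(min_overlap)) stop_input("min_overlap must be a positive integer")
  na <- nchar(a); nb <- nchar(b)
  if (na <= nb) {
    if (grepl(a, b, fixed = TRUE)) return(TRUE)
  } else if (grepl(b, a, fixed = TRUE)) {
    return(TRUE)
  }
  mo <- min(na, nb)
  if (min_overlap >= mo) return(FALSE)
  ls <- min_overlap:(mo - 1L)
  # suffix of a vs prefix of b, pre-filtered on the terminal base of a
  keep <- substring(b, ls, ls) == substring(a, na, na)
  if (any(keep) &&
      any(substring(a, na - ls[keep] + 1L, na) == substring(b, 1L, ls[keep]))) {
    return(TRUE)
  }
  keep <- substring(a, ls, ls) == substring(b, nb, nb)
  if (any(keep) &&
      any(substring(b, nb - ls[keep] + 1L, nb) == substring(a, 1L, ls[keep]))) {
    return(TRUE)
  }
  FALSE
}

# candidate pre-screen: any overlap match of length >= m implies one sequence
# contains the other's first-m or last-m substring, so exact substring search
# of those anchors prunes the all-pairs test to near-certain matches
match_adjacency <- function(seqs, min_overlap) {
  n <- length(seqs)
  len <- nchar(seqs)
  m <- pmin(min_overlap, len)
  pref <- substr(seqs, 1L, m)
  suf <- substr(seqs, len - m + 1L, len)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    cand <- grepl(pref[i], seqs, fixed = TRUE) | grepl(suf[i], seqs, fixed = TRUE)
    adj[i, ] <- adj[i, ] | cand
    adj[, i] <- adj[, i] | cand
  }
  for (i in seq_len(n)) {
    js <- which(adj[i, ] & seq_len(n) > i)
    for (j in js) {
      ok <- overlap_match(seqs[i], seqs[j], min_overlap)
      adj[i, j] <- ok
      adj[j, i] <- ok
    }
  }
  diag(adj) <- TRUE
  adj
}

#' Cluster study and reference ASVs into cASVs
#'
#' Matches study ASVs against a reference ASV set under the
#' [overlap_match()] rule.  Reference-reference matches are merged first by
#' connected components; each study ASV then joins the reference cluster of a
#' matching reference sequence.  A study ASV matching several reference
#' clusters joins the best-sampled one: the cluster with the greatest summed
#' `total_reads` over all study ASVs that match it (ties broken by
#' lexicographically smallest cASV id) — a rule that does not depend on input
#' order.  Study ASVs matching no reference found new singleton cASVs.
#'
#' @param entries a data frame with columns `id`, `sequence`, `origin`
#'   (`"study"` or `"reference"`) and `total_reads` (0 for reference entries).
#' @param min_overlap minimum overlap length passed to [overlap_match()].
#' @return a list with `assignment` (tibble: `asv_id`, `casv_id`; one row per
#'   study ASV) and `members` (tibble: `casv_id`, `member_id`, `origin`; all
#'   clusters, including reference-only ones).
#' @export
cluster_asvs <- function(entries, min_overlap = 100L) {
  entries <- as_tibble(entries)
  need <- c("id", "sequence", "origin", "total_reads")
  if (!all(need %in% names(entries))) {
    stop_input(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(entries$id)) {
    stop_input(sprintf("duplicate ids: %s",
                       paste(unique(entries$id[duplicated(entries$id)]), collapse = ", ")))
  }
  if (!all(entries$origin %in% c("study", "reference"))) {
    stop_input("origin must be 'study' or 'reference'")
  }
  assert_dna(entries$sequence)
  n <- nrow(entries)
  is_study <- entries$origin == "study"
  if (n == 0L) {
    return(list(
      assignment = tibble(asv_id = character(0), casv_id = character(0)),
      members = tibble(casv_id = character(0), member_id = character(0),
                       origin = character(0))
    ))
  }

  adj <- match_adjacency(entries$sequence, min_overlap)

  # reference clusters by connected components over reference-reference matches
  ref_idx <- which(!is_study)
  ref_cluster <- integer(0)
  casv_of_cluster <- character(0)
  if (length(ref_idx) > 0L) {
    sub <- adj[ref_idx, ref_idx, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    ref_cluster <- comp
    casv_of_cluster <- vapply(seq_len(max(comp)), function(k) {
      sprintf("cASV_%s", min(entries$id[ref_idx[comp == k]]))
    }, character(1))
  }

  # which reference clusters does each study ASV match?
  study_idx <- which(is_study)
  match_sets <- lapply(study_idx, function(i) {
    hit <- adj[i, ref_idx]
    sort(unique(ref_cluster[hit]))
  })

  # order-invariant tie-break weight: total study reads matching each cluster
  weight <- numeric(length(casv_of_cluster))
  for (s in seq_along(study_idx)) {
    for (k in match_sets[[s]]) {
      weight[k] <- weight[k] + entries$total_reads[study_idx[s]]
    }
  }

  casv <- character(n)
  for (s in seq_along(study_idx)) {
    ks <- match_sets[[s]]
    i <- study_idx[s]
    if (length(ks) == 0L) {
      casv[i] <- sprintf("cASV_%s", entries$id[i])
    } else {
      best <- ks[weight[ks] == max(weight[ks])]
      casv[i] <- min(casv_of_cluster[best])
    }
  }
  casv[ref_idx] <- casv_of_cluster[ref_cluster]

  list(
    assignment = tibble(asv_id = entries$id[study_idx], casv_id = casv[study_idx]),
    members = tibble(casv_id = casv, member_id = entries$id,
                     origin = entries$origin) |>
      arrange(.data$casv_id, .data$member_id)
  )
}
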