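#' Latitudinal zone of a coordinate
#'
#' Bins latitudes into the three major zones: polar (|lat| >= 66, poleward of
#' the polar circles), temperate (23 <= |lat| < 66) and tropical (|lat| < 23,
#' between the tropics).  Boundary values follow a half-open convention: 66
#' is polar, 23 is temperate.
#'
#' @param latitude numeric vector of decimal degrees in \[-90, 90\].
#' @return character vector: `"polar"`, `"temperate"` or `"tropical"`.
#' @examples
#' assign_zone(c(67.4797, 45, 0, -70))
#' @export
assign_zone <- function(latitude) {
  if (!is.numeric(latitude) || any(is.na(latitude)) ||
      any(abs(latitude) > 90)) {
    stop_input("latitude must be numeric in [-90, 90]")
  }
  a <- abs(latitude)
  dplyr::case_when(a >= 66 ~ "polar", a >= 23 ~ "temperate", TRUE ~ "tropical")
}

#' Collapse repeated samplings of one geographical point
#'
#' Multiple reference samples of the same cASV taken at one geographical
#' point — typically a re-occupied time-series station — count as a single
#' occurrence.  Occurrences sharing (cASV, dataset id, latitude and longitude
#' rounded to `precision`) collapse to one record; the retained record is the
#' one with the lexicographically smallest sample id, so output never depends
#' on row order.
#'
#' @param occ tibble with columns `casv_id`, `sample_id`, `dataset_id`,
#'   `latitude`, `longitude`.
#' @param precision rounding grid in decimal degrees (default 0.1, about
#'   10 km in latitude: wide enough to absorb GPS jitter at a station, narrow
#'   enough to keep distinct stations apart).
#' @return the deduplicated occurrence tibble (same columns).
#' @export
dedup_occurrences <- function(occ, precision = 0.1) {
  occ <- as_tibble(occ)
  need <- c("casv_id", "sample_id", "dataset_id", "latitude", "longitude")
  if (!all(need %in% names(occ))) {
    stop_input(sprintf("occurrence table must have columns %s",
                       paste(need, collapse = ", ")))
  }
  if (nrow(occ) == 0L) return(occ)
  if (any(abs(occ$latitude) > 90) || any(abs(occ$longitude) > 180)) {
    stop_input("occurrence coordinates out of bounds")
  }
  if (!is.numeric(precision) || precision <= 0) {
    stop_input("precision must be a positive number of degrees")
  }
  occ |>
    mutate(.lat_bin = round(.data$latitude / precision),
           .lon_bin = round(.data$longitude / precision)) |>
    group_by(.data$casv_id, .data$dataset_id, .data$.lat_bin, .data$.lon_bin) |>
    arrange(.data$sample_id, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select(dplyr::all_of(need)) |>
    arrange(.data$casv_id, .data$sample_id)
}

#' Biogeographical category from zone occurrence counts
#'
#' Applies the occupancy rules to post-deduplication zone counts; the first
#' matching rule wins.  Single-zone dominance is checked before the two-zone
#' combinations, so "polar-temperate" means a genuine mixture rather than a
#' profile already >= 90% in one zone:
#' fewer than `min_samples` occurrences -> unallocated;
#' polar >= 90% -> polar; temperate >= 90% -> temperate; tropical >= 90% ->
#' tropical; polar + temperate >= 90% -> polar-temperate;
#' temperate + tropical >= 90% -> temperate-tropical; presence in all three
#' zones with no dominance -> cosmopolitan; anything else (a polar + tropical
#' mixture with no temperate occurrences) -> unallocated with a warning.
#'
#' @param n_polar,n_temperate,n_tropical nonnegative integer vectors of
#'   deduplicated occurrence counts per zone (recycled to a common length).
#' @param min_samples minimum occurrences for allocation (default 5).
#' @return tibble with `n_polar`, `n_temperate`, `n_tropical`, `n_total`,
#'   zone fractions `frac_polar`, `frac_temperate`, `frac_tropical` and
#'   `category`.
#' @examples
#' classify_zone_counts(9, 1, 0)   # polar (90% >= 90%)
#' classify_zone_counts(3, 3, 3)   # cosmopolitan
#' classify_zone_counts(2, 1, 1)   # unallocated (4 < 5 occurrences)
#' @export
classify_zone_counts <- function(n_polar, n_temperate, n_tropical,
                                 min_samples = 5L) {
  p <- as.numeric(n_polar); t <- as.numeric(n_temperate); r <- as.numeric(n_tropical)
  k <- max(length(p), length(t), length(r))
  p <- rep_len(p, k); t <- rep_len(t, k); r <- rep_len(r, k)
  if (any(is.na(c(p, t, r))) || any(c(p, t, r) < 0)) {
    stop_input("zone counts must be nonnegative")
  }
  if (!is_count(min_samples)) stop_input("min_samples must be a positive integer")
  tot <- p + t + r
  tot_safe <- ifelse(tot == 0, 1, tot)
  fp <- p / tot_safe; ft <- t / tot_safe; fr <- r / tot_safe
  # combined-zone shares are computed from the summed counts, not by adding
  # the single-zone fractions: (6 + 3) / 10 hits the 90% boundary exactly
  # where 0.6 + 0.3 does not
  category <- dplyr::case_when(
    tot < min_samples ~ "unallocated",
    fp >= 0.9 ~ "polar",
    ft >= 0.9 ~ "temperate",
    fr >= 0.9 ~ "tropical",
    (p + t) / tot_safe >= 0.9 ~ "polar-temperate",
    (t + r) / tot_safe >= 0.9 ~ "temperate-tropical",
    p > 0 & t > 0 & r > 0 ~ "cosmopolitan",
    TRUE ~ "unallocated"
  )
  uncovered <- tot >= min_samples & category == "unallocated"
  if (any(uncovered)) {
    warn(sprintf(
      "%d zone-count profile(s) (polar+tropical mixtures) match no rule; set unallocated",
      sum(uncovered)
    ))
  }
  tibble(
    n_polar = p, n_temperate = t, n_tropical = r, n_total = tot,
    frac_polar = fp, frac_temperate = ft, frac_tropical = fr,
    category = category
  )
}

#' Classify every study cASV from reference occurrences
#'
#' End-to-end biogeography: reference occurrences are mapped to cASVs through
#' the cluster membership, deduplicated by geographical point within dataset,
#' binned into latitudinal zones, and classified with
#' [classify_zone_counts()].  Study cASVs without any reference occurrence
#' (unique to the study) are unallocated with zero counts.
#'
#' @param assign result of [cluster_asvs()].
#' @param occurrences tibble of raw reference occurrences with columns
#'   `ref_id`, `sample_id`, `dataset_id`, `latitude`, `longitude`.
#' @param precision passed to [dedup_occurrences()].
#' @param min_samples passed to [classify_zone_counts()].
#' @return tibble with one row per study cASV: `casv_id`, zone counts and
#'   fractions, `category`.
#' @export
classify_all <- function(assign, occurrences, precision = 0.1, min_samples = 5L) {
  members <- assign$members
  study_casvs <- sort(unique(assign$assignment$casv_id))
  occurrences <- as_tibble(occurrences)
  occ <- occurrences |>
    inner_join(members |> select(member_id = "member_id", casv_id = "casv_id"),
               by = c(ref_id = "member_id")) |>
    select("casv_id", "sample_id", "dataset_id", "latitude", "longitude") |>
    filter(.data$casv_id %in% study_casvs)
  occ <- dedup_occurrences(occ, precision = precision)
  counts <- occ |>
    mutate(zone = assign_zone(.data$latitude)) |>
    count(.data$casv_id, .data$zone) |>
    tidyr::pivot_wider(names_from = "zone", values_from = "n", values_fill = 0L)
  for (z in c("polar", "temperate", "tropical")) {
    if (!z %in% names(counts)) counts[[z]] <- 0L
  }
  counts <- tibble(casv_id = study_casvs) |>
    left_join(counts, by = "casv_id") |>
    mutate(across(dplyr::all_of(c("polar", "temperate", "tropical")),
                  ~ tidyr::replace_na(.x, 0L)))
  bind_cols(
    counts["casv_id"],
    classify_zone_counts(counts$polar, counts$temperate, counts$tropical,
                         min_samples = min_samples)
  )
}
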