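#' @importFrom readr read_tsv write_tsv
NULL

#' Read a FASTA file of ASV sequences
#'
#' Sequences are uppercased on read (lowercase input is accepted and
#' reported) and validated against the A/C/G/T alphabet.
#'
#' @param path FASTA file path.
#' @return tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("FASTA file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  n_lower <- sum(grepl("[acgtn]", raw[!startsWith(raw, ">")]))
  if (n_lower > 0L) {
    inform(sprintf("read_fasta: %d lowercase sequence line(s) uppercased", n_lower))
  }
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  assert_dna(seqs, what = sprintf("sequences in %s", basename(path)))
  tibble(id = names(ss), sequence = unname(seqs))
}

#' Write a FASTA file
#'
#' @param df data frame with an id column (first) and a sequence column
#'   named `sequence`.
#' @param path output path.
#' @export
write_fasta <- function(df, path) {
  ss <- Biostrings::DNAStringSet(stats::setNames(df$sequence, df[[1L]]))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

provenance_header <- function(config) {
  c(
    sprintf("# asvbiogeo %s", as.character(utils::packageVersion("asvbiogeo"))),
    sprintf("# config_hash=%s", config_hash(config)),
    sprintf("# seed=%d", config$seed)
  )
}

#' Write a table with a provenance header
#'
#' Tab-separated output preceded by `#` comment lines recording the package
#' version, a hash of the run configuration and the seed, so every artifact
#' is traceable to the run that produced it.  No timestamps are written:
#' rerunning with the same configuration reproduces files byte for byte.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param config a [run_config()] (or any list with a `seed`).
#' @export
write_table_prov <- function(df, path, config) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  readr::write_tsv(df, con, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a provenance-headed table
#' @param path file written by [write_table_prov()].
#' @return a tibble.
#' @export
read_table_prov <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

write_json_prov <- function(x, path, config) {
  payload <- c(list(provenance = list(
    package = sprintf("asvbiogeo %s", as.character(utils::packageVersion("asvbiogeo"))),
    config_hash = config_hash(config), seed = config$seed
  )), x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

counts_to_df <- function(counts) {
  bind_cols(tibble(asv_id = rownames(counts)), as_tibble(counts))
}

df_to_counts <- function(df) {
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- !vapply(df[-1L], is.numeric, logical(1))
  if (any(bad)) {
    stop_input(sprintf("non-numeric counts in column(s): %s",
                       paste(names(df)[-1L][bad], collapse = ", ")))
  }
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' Read and cross-validate the pipeline input bundle
#'
#' Loads the study FASTA, count matrix, sample metadata, reference FASTA and
#' reference occurrence table, and validates their mutual consistency: FASTA
#' ids must match count-matrix rows exactly, metadata must cover the count
#' columns exactly, coordinates and dates must be in range.  Violations raise
#' typed errors naming the offending records.
#'
#' @param paths named list with elements `study_fasta`, `counts`, `metadata`,
#'   `ref_fasta`, `occurrences` (the last two optional: without them the
#'   classification stage reports everything unallocated).
#' @return list with `asv`, `counts`, `metadata`, `ref`, `occurrences`.
#' @export
read_inputs <- function(paths) {
  asv <- read_fasta(paths$study_fasta)
  counts <- df_to_counts(read_table_prov(paths$counts))
  meta <- read_table_prov(paths$metadata)

  only_fasta <- setdiff(asv$id, rownames(counts))
  only_counts <- setdiff(rownames(counts), asv$id)
  if (length(only_fasta) || length(only_counts)) {
    stop_input(sprintf(
      "FASTA/count id mismatch; only in FASTA: %s; only in counts: %s",
      paste(utils::head(only_fasta, 5), collapse = ","),
      paste(utils::head(only_counts, 5), collapse = ",")
    ))
  }
  extra <- setdiff(colnames(counts), meta$sample_id)
  missing <- setdiff(meta$sample_id, colnames(counts))
  if (length(extra)) {
    stop_input(sprintf("count column(s) without metadata: %s",
                       paste(extra, collapse = ", ")))
  }
  if (length(missing)) {
    stop_input(sprintf("metadata sample(s) missing from counts: %s",
                       paste(missing, collapse = ", ")))
  }
  meta$date <- as.Date(meta$date)
  meta$stage <- assign_stage(meta$date)  # also validates the date range
  meta$phase <- ifelse(meta$stage == "I", "dark", "light")

  ref <- NULL; occ <- NULL
  if (!is.null(paths$ref_fasta) && file.exists(paths$ref_fasta)) {
    ref <- read_fasta(paths$ref_fasta)
  }
  if (!is.null(paths$occurrences) && file.exists(paths$occurrences)) {
    occ <- read_table_prov(paths$occurrences)
    if (any(abs(occ$latitude) > 90) || any(abs(occ$longitude) > 180)) {
      bad <- occ$sample_id[abs(occ$latitude) > 90 | abs(occ$longitude) > 180]
      stop_input(sprintf("occurrence coordinates out of bounds for: %s",
                         paste(utils::head(bad, 5), collapse = ", ")))
    }
    if (!is.null(ref)) {
      orphan <- setdiff(occ$ref_id, ref$id)
      if (length(orphan)) {
        stop_input(sprintf("occurrence ref_id(s) missing from reference FASTA: %s",
                           paste(utils::head(orphan, 5), collapse = ", ")))
      }
    }
  }
  list(asv = asv, counts = counts, metadata = meta, ref = ref, occurrences = occ)
}
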