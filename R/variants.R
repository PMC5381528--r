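#' Detection thresholds for putative editing sites
#'
#' Bundles the per-sample variant-calling thresholds: a position is reported
#' when its depth (A+C+G+T calls) reaches `min_depth`, exactly one alternative
#' base reaches `min_alt_reads`, and that base's fraction of the depth reaches
#' `min_alt_fraction`. Positions with qualifying indel evidence, or with two or
#' more distinct alternative bases each at `min_alt_reads`, are discarded.
#' `genome_error_fraction` is the per-sample alternative-base fraction above
#' which a position seen in *all* covered samples is treated as a genome
#' sequence error or strain difference rather than editing.
#'
#' @param min_depth Minimum read depth (default 5; 3 is appropriate for
#'   low-coverage data sets).
#' @param min_alt_fraction Minimum alternative-base fraction (default 0.03).
#' @param min_alt_reads Minimum alternative-base read count (default 2).
#' @param genome_error_fraction Fraction for the genome-error screen
#'   (default 0.95).
#' @param strict_single_alt If `TRUE`, any read of a second alternative base
#'   voids the position (the literal single-alternative reading); by default a
#'   second alternative must itself reach `min_alt_reads` to void, so a single
#'   stray error read does not disqualify deep positions.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_depth = 5L, min_alt_fraction = 0.03,
                             min_alt_reads = 2L,
                             genome_error_fraction = 0.95,
                             strict_single_alt = FALSE) {
  stopifnot(min_depth >= 1, min_alt_fraction > 0, min_alt_fraction <= 1,
            min_alt_reads >= 1,
            genome_error_fraction > 0, genome_error_fraction <= 1)
  structure(
    list(min_depth = as.integer(min_depth),
         min_alt_fraction = min_alt_fraction,
         min_alt_reads = as.integer(min_alt_reads),
         genome_error_fraction = genome_error_fraction,
         strict_single_alt = isTRUE(strict_single_alt)),
    class = "detection_params"
  )
}

#' Call candidate variant sites in one sample
#'
#' Applies the detection thresholds to a per-base count table from a single
#' sample and returns the positions where exactly one alternative base
#' qualifies. This is pure filtering: positions failing any rule are silently
#' dropped, never an error.
#'
#' @param counts Base-count tibble for one sample (`gene_id`, `pos`, `ref`,
#'   `A`, `C`, `G`, `T`, optional `indel_reads`).
#' @param params A [detection_params()] object.
#' @return Tibble of variant sites: `gene_id`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count`, `alt_fraction`.
#' @export
call_variants <- function(counts, params = detection_params()) {
  counts <- as_tibble(counts)
  if (!"indel_reads" %in% names(counts)) counts$indel_reads <- 0L
  mat <- as.matrix(counts[, BASES])
  storage.mode(mat) <- "integer"
  depth <- rowSums(mat)

  # per-row counts with the reference base masked out
  ref_idx <- match(counts$ref, BASES)
  alt_mat <- mat
  alt_mat[cbind(seq_len(nrow(mat)), ref_idx)] <- 0L

  qualifying <- alt_mat >= params$min_alt_reads
  n_qualifying <- rowSums(qualifying)
  n_nonzero_alt <- rowSums(alt_mat > 0L)

  single_alt_ok <- if (params$strict_single_alt) {
    n_qualifying == 1L & n_nonzero_alt == 1L
  } else {
    n_qualifying == 1L
  }

  keep <- depth >= params$min_depth &
    single_alt_ok &
    counts$indel_reads < params$min_alt_reads

  if (!any(keep)) return(empty_variant_sites())

  kept <- counts[keep, c("gene_id", "pos", "ref")]
  alt_idx <- apply(qualifying[keep, , drop = FALSE], 1, which)
  kept$alt <- BASES[alt_idx]
  kept$depth <- as.integer(depth[keep])
  kept$alt_count <- alt_mat[keep, , drop = FALSE][
    cbind(seq_len(sum(keep)), alt_idx)]
  kept$alt_fraction <- kept$alt_count / kept$depth
  kept <- kept[kept$alt_fraction >= params$min_alt_fraction, , drop = FALSE]
  as_tibble(kept)
}

empty_variant_sites <- function() {
  tibble(gene_id = character(), pos = integer(), ref = character(),
         alt = character(), depth = integer(), alt_count = integer(),
         alt_fraction = numeric())
}

#' Count covered bases
#'
#' Number of positions whose depth (A+C+G+T calls) reaches the coverage
#' threshold; the denominator of the "events per million covered bases"
#' normalization.
#'
#' @param counts Base-count tibble for one sample.
#' @param min_depth Coverage threshold (default 5).
#' @return Integer count of covered positions.
#' @export
count_covered_bases <- function(counts, min_depth = 5L) {
  if (!nrow(counts)) return(0L)
  depth <- rowSums(as.matrix(counts[, BASES]))
  sum(depth >= min_depth)
}

#' Screen for genome-sequence errors and strain differences
#'
#' A variant position supported at near-fixation in *every* sample is more
#' plausibly a reference-sequence error (or a strain difference from the
#' sequenced reference) than RNA editing. This screen flags positions where,
#' in each sample with depth at or above `min_depth`, one and the same
#' alternative base accounts for at least `genome_error_fraction` of the
#' calls. Samples without coverage at a position abstain; positions covered by
#' no sample are skipped.
#'
#' @param counts_by_sample Either a named list of per-sample base-count
#'   tibbles, or one long tibble with a `sample` column.
#' @param params A [detection_params()] object.
#' @return Tibble of flagged positions: `gene_id`, `pos`, `ref`, `alt`,
#'   `n_samples_covered`, `min_alt_fraction_observed`.
#' @export
flag_reference_discrepancies <- function(counts_by_sample,
                                         params = detection_params()) {
  long <- if (is.data.frame(counts_by_sample)) {
    stopifnot("sample" %in% names(counts_by_sample))
    as_tibble(counts_by_sample)
  } else {
    if (length(counts_by_sample) < 2) {
      abort("the genome-error screen needs at least 2 samples")
    }
    bind_rows(counts_by_sample, .id = "sample")
  }

  mat <- as.matrix(long[, BASES])
  depth <- rowSums(mat)
  covered <- depth >= params$min_depth
  long <- long[covered, , drop = FALSE]
  mat <- mat[covered, , drop = FALSE]
  depth <- depth[covered]
  if (!nrow(long)) {
    return(tibble(gene_id = character(), pos = integer(), ref = character(),
                  alt = character(), n_samples_covered = integer(),
                  min_alt_fraction_observed = numeric()))
  }

  alt_mat <- mat
  alt_mat[cbind(seq_len(nrow(mat)), match(long$ref, BASES))] <- 0L
  top_idx <- max.col(alt_mat, ties.method = "first")
  long$top_alt <- BASES[top_idx]
  long$top_alt_fraction <- alt_mat[cbind(seq_len(nrow(mat)), top_idx)] / depth

  long |>
    group_by(.data$gene_id, .data$pos, .data$ref) |>
    summarise(
      n_samples_covered = n(),
      alt = .data$top_alt[1],
      same_alt = n_distinct(.data$top_alt) == 1L,
      min_alt_fraction_observed = min(.data$top_alt_fraction),
      .groups = "drop"
    ) |>
    filter(.data$same_alt,
           .data$min_alt_fraction_observed >= params$genome_error_fraction) |>
    select("gene_id", "pos", "ref", "alt", "n_samples_covered",
           "min_alt_fraction_observed") |>
    arrange(.data$gene_id, .data$pos)
}

#' Remove flagged reference discrepancies from a site table
#'
#' @param sites Variant or editing-site tibble with `gene_id`, `pos`.
#' @param flagged Output of [flag_reference_discrepancies()].
#' @return `sites` without the flagged positions.
#' @export
exclude_flagged <- function(sites, flagged) {
  if (!nrow(flagged) || !nrow(sites)) return(sites)
  anti_join(sites, flagged[, c("gene_id", "pos")],
            by = c("gene_id", "pos"))
}
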