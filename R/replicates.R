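#' Intersect variant calls from two biological replicates
#'
#' A site is reproducible when the identical key (`gene_id`, `pos`, `ref`,
#' `alt`) passes detection in both independent replicates of a condition.
#' Per-replicate evidence is carried forward with `_rep1` / `_rep2` suffixes,
#' together with a pooled editing fraction (alt reads and depth summed over
#' the two replicates).
#'
#' @param rep1,rep2 Variant-site tibbles from [call_variants()], both from the
#'   same condition.
#' @return Tibble of reproducible sites with columns `gene_id`, `pos`, `ref`,
#'   `alt`, `depth_rep1`, `alt_count_rep1`, `alt_fraction_rep1`, likewise for
#'   rep2, and `alt_fraction_pooled`.
#' @export
intersect_replicates <- function(rep1, rep2) {
  key <- c("gene_id", "pos", "ref", "alt")
  out <- inner_join(rep1, rep2, by = key, suffix = c("_rep1", "_rep2"))
  out |>
    mutate(alt_fraction_pooled =
             (.data$alt_count_rep1 + .data$alt_count_rep2) /
             (.data$depth_rep1 + .data$depth_rep2)) |>
    arrange(.data$gene_id, .data$pos)
}

#' Identify condition-specific reproducible sites
#'
#' A reproducible site is specific to a condition when its key appears in no
#' other condition's reproducible set. Input is the long table of reproducible
#' sites across conditions (a `condition` column plus the site key).
#'
#' @param sites Long tibble of reproducible sites with a `condition` column.
#' @param strict If `TRUE`, additionally supply `raw_calls` and require the
#'   key to be absent from every other condition's *single-replicate* raw
#'   calls, not just from their reproducible sets.
#' @param raw_calls Optional long tibble of per-sample raw variant calls with
#'   `condition` and the site key; only used when `strict = TRUE`.
#' @return `sites` with a logical `specific` column and a `specific_to` column
#'   (the condition for specific rows, `NA` otherwise).
#' @export
condition_specific <- function(sites, strict = FALSE, raw_calls = NULL) {
  key <- c("gene_id", "pos", "ref", "alt")
  stopifnot(all(c("condition", key) %in% names(sites)))
  other <- if (strict) {
    if (is.null(raw_calls)) {
      abort("strict = TRUE needs raw_calls (per-replicate variant calls)")
    }
    raw_calls
  } else {
    sites
  }

  occurrences <- other |>
    distinct(.data$condition, .data$gene_id, .data$pos, .data$ref, .data$alt)

  sites |>
    left_join(
      occurrences |>
        count(.data$gene_id, .data$pos, .data$ref, .data$alt,
              name = "n_conditions"),
      by = key
    ) |>
    mutate(
      n_conditions = dplyr::coalesce(.data$n_conditions, 1L),
      specific = .data$n_conditions == 1L,
      specific_to = if_else(.data$specific, .data$condition, NA_character_)
    ) |>
    select(-"n_conditions")
}

#' Events per million covered bases
#'
#' @param count Number of events (sites).
#' @param covered_bases Number of covered positions (depth at or above the
#'   coverage threshold); must be positive.
#' @return `1e6 * count / covered_bases`.
#' @export
normalize_per_million <- function(count, covered_bases) {
  if (any(covered_bases <= 0)) {
    abort("covered_bases must be positive")
  }
  1e6 * count / covered_bases
}

#' Replicate-reproducibility percentage
#'
#' The "both as percent of the replicate mean" statistic:
#' `100 * norm_both / mean(norm_rep1, norm_rep2)`. Undefined (NA) when both
#' replicate rates are zero.
#'
#' @param norm_rep1,norm_rep2 Per-replicate normalized site rates.
#' @param norm_both Normalized rate of sites present in both replicates.
#' @return Percentage (0-200 by construction).
#' @export
pct_both <- function(norm_rep1, norm_rep2, norm_both) {
  denom <- (norm_rep1 + norm_rep2) / 2
  if_else(denom > 0, 100 * norm_both / denom, NA_real_)
}

#' Summarize replicate reproducibility for one condition
#'
#' Computes one summary row per condition: per-replicate site counts
#' normalized by each replicate's own covered bases, the reproducible
#' (intersection) count normalized by the mean of the two covered-base
#' counts, and the reproducibility percentage. An optional substitution-type
#' filter (e.g. `"AG"`) restricts all counts to that type.
#'
#' @param rep1,rep2 Variant-site tibbles for the two replicates.
#' @param covered_rep1,covered_rep2 Covered-base counts for the two
#'   replicates (positive).
#' @param condition Condition label carried into the output.
#' @param type_filter Optional substitution type label (one of the 12 ordered
#'   types, e.g. `"AG"`).
#' @return One-row tibble: `condition`, `type`, `covered_bases_mean`,
#'   `n_rep1`, `n_rep2`, `n_both`, `norm_rep1`, `norm_rep2`, `norm_both`,
#'   `pct_both`.
#' @export
summarize_condition <- function(rep1, rep2, covered_rep1, covered_rep2,
                                condition = NA_character_,
                                type_filter = NULL) {
  stopifnot(covered_rep1 > 0, covered_rep2 > 0)
  if (!is.null(type_filter)) {
    stopifnot(type_filter %in% SUBSTITUTION_TYPES)
    rep1 <- filter(rep1, substitution_type(.data$ref, .data$alt) == type_filter)
    rep2 <- filter(rep2, substitution_type(.data$ref, .data$alt) == type_filter)
  }
  n1 <- nrow(rep1)
  n2 <- nrow(rep2)
  n_both <- nrow(intersect_replicates(rep1, rep2))
  covered_mean <- (covered_rep1 + covered_rep2) / 2
  norm1 <- normalize_per_million(n1, covered_rep1)
  norm2 <- normalize_per_million(n2, covered_rep2)
  norm_both <- normalize_per_million(n_both, covered_mean)
  tibble(
    condition = condition,
    type = if (is.null(type_filter)) "all" else type_filter,
    covered_bases_mean = covered_mean,
    n_rep1 = n1, n_rep2 = n2, n_both = n_both,
    norm_rep1 = norm1, norm_rep2 = norm2, norm_both = norm_both,
    pct_both = pct_both(norm1, norm2, norm_both)
  )
}

#' Round a replicate summary to table precision
#'
#' Normalized rates and percentages rounded to 1 decimal for display;
#' internal arithmetic elsewhere stays unrounded.
#'
#' @param summary Tibble from [summarize_condition()] (one or more rows).
#' @return The tibble with `norm_*` and `pct_both` rounded to 1 decimal.
#' @export
format_summary_table <- function(summary) {
  mutate(summary,
         across(c("norm_rep1", "norm_rep2", "norm_both", "pct_both"),
                ~ round(.x, 1)))
}
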