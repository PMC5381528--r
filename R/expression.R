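#' Assign genes to editing-status groups
#'
#' The three nested gene groups used when relating editing to expression:
#' * `any` — genes with any type of putative (reproducible) editing site in
#'   any condition;
#' * `specific` — genes with an A-to-G site specific to the focal condition;
#' * `aa` — genes with a focal-specific A-to-G site that changes the amino
#'   acid (nonsynonymous or stop-loss) and is edited in at least
#'   `min_edit_fraction` of observed transcripts (pooled over replicates).
#'
#' By construction `aa` is a subset of `specific`, which is a subset of
#' `any`.
#'
#' @param sites Classified reproducible sites across conditions: long tibble
#'   with `condition`, site key, `specific` (see [condition_specific()]),
#'   `category`, and a pooled fraction column (`alt_fraction_pooled` or
#'   `alt_fraction`).
#' @param focal_condition Condition defining the `specific` and `aa` groups.
#' @param min_edit_fraction Editing-fraction threshold for the `aa` group
#'   (default 0.10).
#' @return Tibble with `gene_id` and logical columns `any`, `specific`, `aa`.
#' @export
assign_groups <- function(sites, focal_condition, min_edit_fraction = 0.10) {
  frac_col <- if ("alt_fraction_pooled" %in% names(sites)) {
    "alt_fraction_pooled"
  } else {
    "alt_fraction"
  }
  stopifnot(all(c("condition", "gene_id", "ref", "alt", "specific") %in%
                  names(sites)))
  sites |>
    group_by(.data$gene_id) |>
    summarise(
      any = n() > 0,
      specific = any(.data$ref == "A" & .data$alt == "G" & .data$specific &
                       .data$condition == focal_condition),
      aa = any(.data$ref == "A" & .data$alt == "G" & .data$specific &
                 .data$condition == focal_condition &
                 .data$category %in% c("nonsynonymous", "stop_loss") &
                 .data[[frac_col]] >= min_edit_fraction),
      .groups = "drop"
    )
}

#' Quartile summary of expression ratios per editing group
#'
#' For each gene the expression ratio
#' `(numerator + pseudocount) / (denominator + pseudocount)` between two
#' conditions is computed; per group the count, median and quartiles (linear
#' interpolation between order statistics, quantile type 7) are reported —
#' the numbers behind a boxplot of expression ratios by editing group.
#'
#' @param expr Long expression tibble: `gene_id`, `condition`, `value`
#'   (non-negative abundance units, as produced upstream).
#' @param groups Output of [assign_groups()].
#' @param numerator,denominator Condition labels for the ratio.
#' @param pseudocount Added to both numerator and denominator (default 1
#'   abundance unit) so zero denominators stay finite.
#' @param log2_ratio If `TRUE`, summarize `log2` ratios instead of linear
#'   ratios.
#' @return Tibble with one row per group (`any`, `specific`, `aa`): `n`,
#'   `q1`, `median`, `q3`. Empty groups get `n = 0` and `NA` statistics.
#' @export
group_ratio_summary <- function(expr, groups, numerator, denominator,
                                pseudocount = 1, log2_ratio = FALSE) {
  have <- unique(expr$condition)
  if (!all(c(numerator, denominator) %in% have)) {
    abort("numerator and denominator conditions must be present in expr")
  }
  wide <- expr |>
    filter(.data$condition %in% c(numerator, denominator)) |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "condition",
                       values_from = "value") |>
    mutate(ratio = (.data[[numerator]] + pseudocount) /
             (.data[[denominator]] + pseudocount))
  if (log2_ratio) wide$ratio <- log2(wide$ratio)

  purrr::map_dfr(c("any", "specific", "aa"), function(g) {
    genes <- groups$gene_id[groups[[g]]]
    r <- wide$ratio[wide$gene_id %in% genes]
    r <- r[is.finite(r)]
    if (!length(r)) {
      tibble(group = g, n = 0L, q1 = NA_real_, median = NA_real_,
             q3 = NA_real_)
    } else {
      q <- quantile(r, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      tibble(group = g, n = length(r), q1 = q[1], median = q[2], q3 = q[3])
    }
  })
}
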