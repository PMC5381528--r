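#' Run the editing-discovery analysis across conditions
#'
#' The full discovery chain on a study's per-base counts: per-sample variant
#' calling under the detection thresholds, covered-base accounting,
#' replicate intersection per condition, the genome-error screen across all
#' samples (flagged positions are excluded from the editing calls),
#' condition-specificity, per-condition replicate summaries (all types and
#' A-to-G), and substitution spectra of the reproducible sites.
#'
#' @param counts Long base-count tibble with `condition` and `replicate`
#'   columns (two replicates per condition), e.g. `simulate_study()$counts`
#'   or stacked [parse_mpileup()] outputs.
#' @param params A [detection_params()] object.
#' @return An object of class `editing_analysis`: list with
#'   `reproducible` (long site tibble with `condition`, per-replicate
#'   evidence, pooled fraction, `specific`), `flagged` (genome-error screen
#'   hits), `covered` (covered bases per sample), `summary` (per condition x
#'   {all, AG} replicate summaries), and `spectra` (12-type spectrum per
#'   condition). Methods: `print()`, [tidy.editing_analysis()],
#'   [glance.editing_analysis()], [autoplot.editing_analysis()].
#' @export
analyze_editing <- function(counts, params = detection_params()) {
  stopifnot(all(c("condition", "replicate") %in% names(counts)))
  conditions <- unique(counts$condition)

  per_sample <- counts |>
    group_by(.data$condition, .data$replicate) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(
      calls = purrr::map(.data$data, call_variants, params = params),
      covered = purrr::map_int(.data$data, count_covered_bases,
                               min_depth = params$min_depth)
    )

  flagged <- flag_reference_discrepancies(
    counts |>
      mutate(sample = paste(.data$condition, .data$replicate, sep = ":")),
    params
  )

  per_condition <- purrr::map(conditions, function(cond) {
    rows <- per_sample |> filter(.data$condition == cond)
    stopifnot(nrow(rows) == 2)
    rep1 <- rows$calls[[match(1, rows$replicate)]]
    rep2 <- rows$calls[[match(2, rows$replicate)]]
    cov1 <- rows$covered[match(1, rows$replicate)]
    cov2 <- rows$covered[match(2, rows$replicate)]
    repro <- intersect_replicates(rep1, rep2) |>
      exclude_flagged(flagged) |>
      mutate(condition = cond)
    list(
      reproducible = repro,
      summary = bind_rows(
        summarize_condition(rep1, rep2, cov1, cov2, cond),
        summarize_condition(rep1, rep2, cov1, cov2, cond,
                            type_filter = "AG")
      ),
      spectrum = spectrum(repro, (cov1 + cov2) / 2, cond)
    )
  })

  reproducible <- purrr::map_dfr(per_condition, "reproducible") |>
    condition_specific()

  structure(
    list(
      reproducible = reproducible,
      flagged = flagged,
      covered = per_sample |> select("condition", "replicate", "covered"),
      summary = purrr::map_dfr(per_condition, "summary"),
      spectra = purrr::map_dfr(per_condition, "spectrum"),
      params = params
    ),
    class = "editing_analysis"
  )
}

#' @export
print.editing_analysis <- function(x, ...) {
  cat("Editing analysis: ", nrow(x$covered), " samples, ",
      length(unique(x$covered$condition)), " condition(s)\n", sep = "")
  cat("  reproducible sites: ", nrow(x$reproducible),
      " (", sum(x$reproducible$specific), " condition-specific)\n", sep = "")
  cat("  genome-error screen: ", nrow(x$flagged),
      " position(s) flagged and excluded\n", sep = "")
  print(format_summary_table(x$summary))
  invisible(x)
}

#' Reproducible sites of an editing analysis as a tibble
#'
#' @param x An `editing_analysis`.
#' @param ... Unused.
#' @return The long reproducible-site tibble.
#' @export
tidy.editing_analysis <- function(x, ...) {
  x$reproducible
}

#' One-row-per-condition summary of an editing analysis
#'
#' @param x An `editing_analysis`.
#' @param ... Unused.
#' @return Tibble with per-condition reproducible/specific site counts and
#'   A-to-G share of the reproducible spectrum.
#' @export
glance.editing_analysis <- function(x, ...) {
  x$reproducible |>
    group_by(.data$condition) |>
    summarise(
      n_reproducible = n(),
      n_specific = sum(.data$specific),
      n_ag = sum(.data$ref == "A" & .data$alt == "G"),
      ag_fraction = .data$n_ag / .data$n_reproducible,
      .groups = "drop"
    )
}
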