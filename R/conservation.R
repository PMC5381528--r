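#' Compare editing between two species over ortholog pairs
#'
#' Given an ortholog-pair table (with protein sequences) and classified,
#' replicate-reproducible site lists from each species, reports (i) ortholog
#' pairs in which *both* genes carry a qualifying editing site, and (ii) for
#' pairs where a site in each species causes the same amino-acid substitution,
#' whether those sites fall at orthologous alignment positions under a global
#' protein alignment.
#'
#' Qualifying sites are A-to-G, optionally restricted to amino-acid-changing
#' consequences (`nonsynonymous` or `stop_loss`), with a pooled editing
#' fraction of at least `min_edit_fraction`.
#'
#' @param pairs Tibble with `gene_id_a`, `gene_id_b`, `protein_a`,
#'   `protein_b`.
#' @param sites_a,sites_b Classified site tibbles (see [classify_sites()])
#'   carrying `alt_fraction_pooled` (or `alt_fraction`).
#' @param min_edit_fraction Minimum pooled editing fraction (default 0.10).
#' @param aa_changing_only Keep only amino-acid-changing sites (default TRUE).
#' @param ... Passed to [global_align()] (scoring scheme).
#' @return A `shared_editing_report`: list with `pairs` (one row per shared
#'   pair: site counts, `n_same_aa_change`, `n_positionally_orthologous`),
#'   `edited_genes_a`, `edited_genes_b`, `unpaired_a`, `unpaired_b`.
#'   `tidy()` returns the pair table, `glance()` the summary counts.
#' @export
shared_editing <- function(pairs, sites_a, sites_b,
                           min_edit_fraction = 0.10,
                           aa_changing_only = TRUE, ...) {
  fa <- filter_conserved_sites(sites_a, min_edit_fraction, aa_changing_only)
  fb <- filter_conserved_sites(sites_b, min_edit_fraction, aa_changing_only)

  edited_a <- unique(fa$gene_id)
  edited_b <- unique(fb$gene_id)
  unpaired_a <- setdiff(edited_a, pairs$gene_id_a)
  unpaired_b <- setdiff(edited_b, pairs$gene_id_b)
  if (length(unpaired_a) || length(unpaired_b)) {
    warn(paste0(length(unpaired_a) + length(unpaired_b),
                " edited gene(s) absent from the ortholog-pair table"))
  }

  shared <- pairs |>
    filter(.data$gene_id_a %in% edited_a, .data$gene_id_b %in% edited_b)

  align_args <- list(...)
  rows <- purrr::pmap(shared, function(gene_id_a, gene_id_b,
                                       protein_a, protein_b, ...) {
    sa <- filter(fa, .data$gene_id == gene_id_a)
    sb <- filter(fb, .data$gene_id == gene_id_b)
    combos <- tidyr::crossing(
      sa |> select(idx_a = "codon_index", ref_aa_a = "ref_aa",
                   alt_aa_a = "alt_aa"),
      sb |> select(idx_b = "codon_index", ref_aa_b = "ref_aa",
                   alt_aa_b = "alt_aa")
    ) |>
      filter(.data$ref_aa_a == .data$ref_aa_b,
             .data$alt_aa_a == .data$alt_aa_b)
    n_ortho <- 0L
    if (nrow(combos)) {
      aln <- do.call(global_align,
                     c(list(protein_a, protein_b), align_args))
      mapped <- map_aligned_position(aln, combos$idx_a)
      n_ortho <- sum(!is.na(mapped) & mapped == combos$idx_b)
    }
    tibble(gene_id_a = gene_id_a, gene_id_b = gene_id_b,
           n_sites_a = nrow(sa), n_sites_b = nrow(sb),
           n_same_aa_change = nrow(combos),
           n_positionally_orthologous = n_ortho)
  })

  pair_rows <- if (length(rows)) {
    bind_rows(rows)
  } else {
    tibble(gene_id_a = character(), gene_id_b = character(),
           n_sites_a = integer(), n_sites_b = integer(),
           n_same_aa_change = integer(),
           n_positionally_orthologous = integer())
  }
  structure(
    list(pairs = pair_rows,
         edited_genes_a = edited_a, edited_genes_b = edited_b,
         unpaired_a = unpaired_a, unpaired_b = unpaired_b),
    class = "shared_editing_report"
  )
}

filter_conserved_sites <- function(sites, min_edit_fraction,
                                   aa_changing_only) {
  frac_col <- if ("alt_fraction_pooled" %in% names(sites)) {
    "alt_fraction_pooled"
  } else {
    "alt_fraction"
  }
  out <- sites |>
    filter(.data$ref == "A", .data$alt == "G",
           .data[[frac_col]] >= min_edit_fraction)
  if (aa_changing_only) {
    out <- filter(out, .data$category %in% c("nonsynonymous", "stop_loss"))
  }
  out
}

#' @export
print.shared_editing_report <- function(x, ...) {
  cat("Shared-editing report: ", nrow(x$pairs), " ortholog pair(s) edited in",
      " both species\n", sep = "")
  print(x$pairs)
  invisible(x)
}

#' @rdname shared_editing
#' @param x A `shared_editing_report`.
#' @export
tidy.shared_editing_report <- function(x, ...) {
  x$pairs
}

#' @rdname shared_editing
#' @export
glance.shared_editing_report <- function(x, ...) {
  tibble(
    n_edited_genes_a = length(x$edited_genes_a),
    n_edited_genes_b = length(x$edited_genes_b),
    n_shared_pairs = nrow(x$pairs),
    n_shared_sites = sum(x$pairs$n_sites_a) + sum(x$pairs$n_sites_b),
    n_same_aa_change = sum(x$pairs$n_same_aa_change),
    n_positionally_orthologous = sum(x$pairs$n_positionally_orthologous),
    n_unpaired = length(x$unpaired_a) + length(x$unpaired_b)
  )
}
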