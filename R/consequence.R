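## Genetic code helpers (standard nuclear code, translation table 1).
translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(character(0))
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

model_row <- function(models, gene_id) {
  i <- match(gene_id, models$gene_id)
  if (is.na(i)) abort(paste0("no gene model for ", gene_id))
  models[i, ]
}

## CDS segments of one model row, with cumulative spliced offsets.
cds_segments <- function(model) {
  seg <- model$segments[[1]]
  cds <- seg[seg$kind == "cds", , drop = FALSE]
  if (nrow(cds)) {
    len <- cds$end - cds$start + 1L
    cds$cum_before <- cumsum(c(0L, len[-length(len)]))
  }
  cds
}

spliced_cds <- function(model, seq = model$seq) {
  cds <- cds_segments(model)
  paste(substring(seq, cds$start, cds$end), collapse = "")
}

#' Locate a gene-space position within its gene model
#'
#' Returns the segment kind containing the position and, for CDS positions,
#' the 1-based offset within the spliced CDS (introns excised, CDS segments
#' concatenated in order). Positions in genes without any CDS segment are
#' reported as `noncoding_gene`.
#'
#' @param model One gene-model row (from [read_gene_models()] or
#'   [simulate_genes()]).
#' @param pos 1-based gene-space position (scalar).
#' @return List with `region` and `cds_offset` (`NA` outside the CDS).
#' @export
locate_site <- function(model, pos) {
  if (pos < 1 || pos > model$length) {
    abort(paste0("position ", pos, " outside gene ", model$gene_id,
                 " (length ", model$length, ")"))
  }
  seg <- model$segments[[1]]
  hit <- which(seg$start <= pos & seg$end >= pos)[1]
  kind <- seg$kind[hit]
  if (!any(seg$kind == "cds")) {
    return(list(region = "noncoding_gene", cds_offset = NA_integer_))
  }
  if (kind != "cds") {
    return(list(region = kind, cds_offset = NA_integer_))
  }
  cds <- cds_segments(model)
  j <- which(cds$start <= pos & cds$end >= pos)[1]
  list(region = "cds",
       cds_offset = cds$cum_before[j] + (pos - cds$start[j]) + 1L)
}

#' Classify the coding consequence of editing sites
#'
#' Maps each site onto its gene model and, for CDS sites, substitutes the
#' alternative base into the codon and compares reference and edited codons
#' under the standard genetic code. Categories: `synonymous`,
#' `nonsynonymous`, `stop_loss` (reference codon is a stop, edited codon is
#' not; translation then reads through into downstream sequence),
#' `stop_retained` (both are stops), and `stop_gain` (edited codon is a stop;
#' impossible for A-to-G edits, possible for other substitution types). For
#' stop-loss sites, `extension_aa` is the number of residues gained by
#' read-through (see [edited_protein()]).
#'
#' @param sites Site tibble with `gene_id`, `pos`, `ref`, `alt`.
#' @param models Gene-model tibble.
#' @return `sites` with added columns `region`, `cds_offset`, `codon_index`,
#'   `codon_position`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `category`, `extension_aa`.
#' @export
classify_sites <- function(sites, models) {
  if (!nrow(sites)) {
    return(bind_cols(sites, tibble(
      region = character(), cds_offset = integer(),
      codon_index = integer(), codon_position = integer(),
      ref_codon = character(), alt_codon = character(),
      ref_aa = character(), alt_aa = character(),
      category = character(), extension_aa = integer())))
  }
  ann <- purrr::pmap(
    list(sites$gene_id, sites$pos, sites$ref, sites$alt),
    function(gene_id, pos, ref, alt) {
      model <- model_row(models, gene_id)
      model_base <- substring(model$seq, pos, pos)
      if (model_base != ref) {
        abort(paste0(
          "reference mismatch at ", gene_id, ":", pos, " (site ref ", ref,
          ", model sequence ", model_base,
          "); annotation and sequence are out of sync"))
      }
      loc <- locate_site(model, pos)
      out <- list(region = loc$region, cds_offset = loc$cds_offset,
                  codon_index = NA_integer_, codon_position = NA_integer_,
                  ref_codon = NA_character_, alt_codon = NA_character_,
                  ref_aa = NA_character_, alt_aa = NA_character_,
                  category = NA_character_, extension_aa = NA_integer_)
      if (loc$region != "cds") return(out)

      off <- loc$cds_offset
      ci <- (off - 1L) %/% 3L + 1L
      cp <- off - 3L * (ci - 1L)
      cds <- spliced_cds(model)
      ref_codon <- substring(cds, 3L * ci - 2L, 3L * ci)
      alt_codon <- ref_codon
      substring(alt_codon, cp, cp) <- alt
      ref_aa <- translate_codons(ref_codon)
      alt_aa <- translate_codons(alt_codon)
      category <- if (ref_aa == "*" && alt_aa == "*") {
        "stop_retained"
      } else if (ref_aa == "*") {
        "stop_loss"
      } else if (alt_aa == "*") {
        "stop_gain"
      } else if (ref_aa == alt_aa) {
        "synonymous"
      } else {
        "nonsynonymous"
      }
      ext <- NA_integer_
      if (category == "stop_loss") {
        ep <- edited_protein(model, tibble(pos = pos, ref = ref, alt = alt),
                             check_ag = FALSE)
        ext <- ep$extension_aa
      }
      list(region = "cds", cds_offset = off, codon_index = ci,
           codon_position = cp, ref_codon = ref_codon, alt_codon = alt_codon,
           ref_aa = ref_aa, alt_aa = alt_aa, category = category,
           extension_aa = ext)
    }
  )
  bind_cols(sites, purrr::map_dfr(ann, as_tibble))
}

#' Predict the edited protein product, including stop-loss read-through
#'
#' Applies edits to the gene sequence, translates the spliced CDS and, when
#' the annotated stop codon has been lost, continues translation in frame
#' through the literal downstream gene sequence (introns beyond the annotated
#' CDS are *not* excised, because annotation past the stop is untrusted)
#' until the next stop codon or the end of the transcript.
#'
#' @param model One gene-model row.
#' @param sites Tibble of edits to apply (`pos`, `alt`; `ref` optional) —
#'   A-to-G edits within the gene.
#' @param check_ag Require all applied edits to be A-to-G (default TRUE).
#' @return List with `protein` (single-letter string, no stop), the number of
#'   residues gained past the annotated CDS (`extension_aa`), and `overran`
#'   (`TRUE` when translation ran off the end of the transcript without
#'   finding a stop).
#' @export
edited_protein <- function(model, sites = NULL, check_ag = TRUE) {
  seq <- model$seq
  if (!is.null(sites) && nrow(sites)) {
    if (any(sites$pos < 1 | sites$pos > model$length)) {
      abort("edit position outside the gene")
    }
    ref_bases <- substring(seq, sites$pos, sites$pos)
    if (check_ag && !all(ref_bases == "A" & sites$alt == "G")) {
      abort("edited_protein applies A-to-G edits only")
    }
    for (i in seq_len(nrow(sites))) {
      substring(seq, sites$pos[i], sites$pos[i]) <- sites$alt[i]
    }
  }
  cds <- spliced_cds(model, seq)
  aas <- translate_codons(split_codons(cds))
  stop_at <- which(aas == "*")[1]
  if (!is.na(stop_at)) {
    return(list(protein = paste(aas[seq_len(stop_at - 1L)], collapse = ""),
                extension_aa = 0L, overran = FALSE))
  }

  # stop codon lost (or CDS lacks one): read through downstream gene sequence
  cds_end <- max(cds_segments(model)$end)
  downstream <- if (cds_end < model$length) {
    substring(seq, cds_end + 1L, model$length)
  } else {
    ""
  }
  ext_aas <- translate_codons(split_codons(downstream))
  ext_stop <- which(ext_aas == "*")[1]
  if (is.na(ext_stop)) {
    ext <- ext_aas
    overran <- TRUE
  } else {
    ext <- ext_aas[seq_len(ext_stop - 1L)]
    overran <- FALSE
  }
  list(protein = paste(c(aas, ext), collapse = ""),
       extension_aa = length(ext), overran = overran)
}

#' Reference protein of a gene model
#'
#' @param model One gene-model row.
#' @return Single-letter protein string (translation up to the first stop).
#' @export
reference_protein <- function(model) {
  edited_protein(model, NULL)$protein
}

#' Tally coding consequences of a classified site set
#'
#' The accounting used for "different gene product" statements: among CDS
#' sites, `nonsynonymous + stop_loss` change the product; `synonymous` and
#' `stop_retained` do not. The percentage is taken over *all* sites passed in
#' (coding and noncoding alike).
#'
#' @param sites Output of [classify_sites()].
#' @param include_stop_retained_in_coding Whether `stop_retained` events count
#'   among coding sites (default TRUE; both conventions are exposed because
#'   edited stops that stay stops need a home in the binary
#'   changed-vs-unchanged summary).
#' @return One-row tibble: `n_sites`, `n_cds`, `n_synonymous`,
#'   `n_nonsynonymous`, `n_stop_loss`, `n_stop_retained`,
#'   `pct_product_changed`.
#' @export
consequence_summary <- function(sites,
                                include_stop_retained_in_coding = TRUE) {
  cds <- filter(sites, .data$region == "cds")
  n_syn <- sum(cds$category == "synonymous")
  n_nonsyn <- sum(cds$category == "nonsynonymous")
  n_sl <- sum(cds$category == "stop_loss")
  n_sr <- sum(cds$category == "stop_retained")
  n_cds <- if (include_stop_retained_in_coding) {
    nrow(cds)
  } else {
    nrow(cds) - n_sr
  }
  tibble(
    n_sites = nrow(sites),
    n_cds = n_cds,
    n_synonymous = n_syn,
    n_nonsynonymous = n_nonsyn,
    n_stop_loss = n_sl,
    n_stop_retained = n_sr,
    pct_product_changed = 100 * (n_nonsyn + n_sl) / nrow(sites)
  )
}
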