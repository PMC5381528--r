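## Deterministic child seeds: every stochastic operation derives its own seed
## from (master seed, purpose, condition, replicate, ...) so that replicates
## differ only by their seed derivation and any sub-result is reproducible in
## isolation. Kept below 2^31 - 1.
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

NON_STOP_CODONS <- setdiff(
  names(Biostrings::GENETIC_CODE),
  c("TAA", "TAG", "TGA")
)

#' Configuration for the synthetic RNA-seq study
#'
#' Defaults emulate a two-replicate, multi-condition RNA-seq editing study on
#' a fungal gene space: genes with UTR/CDS/intron structure, negative-binomial
#' coverage around 50x with a smooth positional profile, 0.5% per-base
#' sequencing error, and 100 A-to-G editing sites planted in the focal
#' (sexual-development) condition only — 20 "tracked" sites at solid editing
#' fractions of which 5 are stop-loss edits on TGA/TAG stop codons, and 80
#' background sites whose fractions reach down to the 3% detection threshold
#' (low-penetrance sites). Three reference errors (near-fixed alternative
#' base in every sample) emulate genome-sequence errors or strain
#' differences.
#'
#' @param n_genes Number of genes.
#' @param utr5_range,utr3_range 5'/3' UTR length ranges (bases).
#' @param n_codons_range CDS length range in codons (incl. start and stop).
#' @param n_introns_range,intron_length_range Intron count/length ranges;
#'   introns fall at codon boundaries in the middle of the CDS.
#' @param conditions Condition labels (two replicates each).
#' @param focal_condition The condition carrying the planted editing.
#' @param mean_coverage Mean per-base read depth.
#' @param coverage_dispersion Negative-binomial size parameter (smaller =
#'   more overdispersed).
#' @param expr_sdlog Log-normal sd of per-gene expression multipliers.
#' @param profile_amplitude Amplitude of the smooth positional coverage
#'   profile (0 = flat).
#' @param three_prime_bias Strength of an optional 3'-bias coverage ramp
#'   (0 = none; 1 = coverage rises linearly to 2x at the 3' end relative to
#'   the 5' end), emulating linearly amplified libraries.
#' @param error_rate Per-base sequencing error rate (errors uniform over the
#'   three wrong bases).
#' @param n_tracked,tracked_fraction_range Number and editing-fraction range
#'   of tracked focal-specific sites.
#' @param n_stop_loss How many tracked sites are placed on stop codons.
#' @param n_background,background_fraction_range Number and fraction range of
#'   background focal-specific sites.
#' @param n_shared Editing sites shared by all conditions (default 0).
#' @param n_ref_errors Planted reference errors.
#' @param aa_expression_upshift Expression fold-change of aa-changing edited
#'   genes in the focal condition (used by [simulate_expression()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L,
                       utr5_range = c(60L, 140L),
                       n_codons_range = c(150L, 350L),
                       n_introns_range = c(0L, 2L),
                       intron_length_range = c(50L, 90L),
                       utr3_range = c(120L, 260L),
                       conditions = c("veg", "sex", "proto"),
                       focal_condition = "proto",
                       mean_coverage = 50,
                       coverage_dispersion = 15,
                       expr_sdlog = 0.25,
                       profile_amplitude = 0.2,
                       three_prime_bias = 0,
                       error_rate = 0.005,
                       n_tracked = 20L,
                       tracked_fraction_range = c(0.25, 0.9),
                       n_stop_loss = 5L,
                       n_background = 80L,
                       background_fraction_range = c(0.03, 0.7),
                       n_shared = 0L,
                       n_ref_errors = 3L,
                       aa_expression_upshift = 2) {
  stopifnot(focal_condition %in% conditions,
            n_stop_loss <= n_tracked,
            error_rate >= 0, error_rate < 1,
            mean_coverage >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate gene models with UTR/CDS/intron structure
#'
#' Reproducible for a fixed seed. Each CDS begins with ATG, contains no
#' internal stop, and ends with a stop codon drawn from TAA/TAG/TGA; introns
#' are placed at codon boundaries away from the CDS ends so start and stop
#' codons stay contiguous; a 3' UTR is always present so stop-loss
#' read-through has downstream sequence to run into.
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @return Gene-model tibble in the same shape as [read_gene_models()].
#' @export
simulate_genes <- function(config = sim_config(), seed = 1) {
  n <- config$n_genes
  if (n == 0) {
    return(tibble(gene_id = character(), length = integer(),
                  coding = logical(), cds_complete = logical(),
                  seq = character(), segments = list()))
  }
  with_seed(child_seed(seed, "genes"), {
    models <- purrr::map(seq_len(n), function(i) {
      gene_id <- sprintf("g%03d", i)
      u5 <- sample(config$utr5_range[1]:config$utr5_range[2], 1)
      u3 <- sample(config$utr3_range[1]:config$utr3_range[2], 1)
      n_codons <- sample(config$n_codons_range[1]:config$n_codons_range[2], 1)
      stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
      codons <- c("ATG",
                  sample(NON_STOP_CODONS, n_codons - 2, replace = TRUE),
                  stop_codon)
      cds <- paste(codons, collapse = "")

      n_introns <- sample(config$n_introns_range[1]:config$n_introns_range[2], 1)
      # codon boundaries (after codon b), keeping >= 10 codons clear of ends
      boundaries <- sort(sample(10:(n_codons - 10), n_introns))
      intron_lens <- sample(
        config$intron_length_range[1]:config$intron_length_range[2],
        n_introns, replace = TRUE)

      random_seq <- function(len) {
        paste(sample(BASES, len, replace = TRUE), collapse = "")
      }

      # assemble gene-space sequence and segment table
      pieces <- character(0)
      segs <- list()
      cursor <- 0L
      add_segment <- function(kind, piece) {
        pieces[[length(pieces) + 1]] <<- piece
        segs[[length(segs) + 1]] <<- tibble(
          kind = kind, start = cursor + 1L,
          end = cursor + nchar(piece))
        cursor <<- cursor + nchar(piece)
      }
      add_segment("five_utr", random_seq(u5))
      chunk_starts <- c(1L, boundaries * 3L + 1L)
      chunk_ends <- c(boundaries * 3L, n_codons * 3L)
      for (j in seq_along(chunk_starts)) {
        add_segment("cds", substring(cds, chunk_starts[j], chunk_ends[j]))
        if (j <= n_introns) {
          add_segment("intron", random_seq(intron_lens[j]))
        }
      }
      add_segment("three_utr", random_seq(u3))

      tibble(gene_id = gene_id,
             length = cursor,
             coding = TRUE,
             cds_complete = TRUE,
             seq = paste(pieces, collapse = ""),
             segments = list(bind_rows(segs)))
    })
    bind_rows(models)
  })
}

#' Write simulated gene models to FASTA and segment TSV
#'
#' @param models Gene-model tibble.
#' @param fasta_path,segments_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_gene_models <- function(models, fasta_path, segments_path) {
  set <- Biostrings::DNAStringSet(setNames(models$seq, models$gene_id))
  Biostrings::writeXStringSet(set, fasta_path)
  seg <- models |>
    select("gene_id", "segments") |>
    tidyr::unnest("segments")
  readr::write_tsv(seg, segments_path)
  invisible(c(fasta_path, segments_path))
}

#' Plant editing sites and reference errors with known truth
#'
#' Editing sites are placed only on A bases of the sense-strand gene
#' sequences. Focal-specific sites get editing fraction 0 in every other
#' condition; stop-loss sites are placed on the editable A of TGA/TAG stop
#' codons (TGA -> TGG, TAG -> TGG). Reference errors are planted at
#' near-fixation (fraction 1) in *all* conditions at positions disjoint from
#' the editing sites, with a random alternative base.
#'
#' @param models Gene models from [simulate_genes()].
#' @param config A [sim_config()].
#' @param seed Master seed (same value as used downstream).
#' @return Truth tibble: `gene_id`, `pos`, `ref`, `alt`, `kind`
#'   (`editing` / `reference_error`), `class` (`tracked` / `stop_loss` /
#'   `background` / `shared`), `region`, `category`, plus one
#'   `fraction_<condition>` column per condition.
#' @export
plant_editing <- function(models, config = sim_config(), seed = 1) {
  with_seed(child_seed(seed, "truth"), {
    # stop-loss sites: genes whose stop codon is TGA (A at last CDS base) or
    # TAG (A at second-to-last CDS base)
    stop_info <- purrr::map_dfr(seq_len(nrow(models)), function(i) {
      model <- models[i, ]
      cds <- cds_segments(model)
      e <- max(cds$end)
      stop_codon <- substring(model$seq, e - 2L, e)
      tibble(gene_id = model$gene_id, stop_codon = stop_codon,
             pos = if (stop_codon == "TGA") e
                   else if (stop_codon == "TAG") e - 1L
                   else NA_integer_)
    }) |>
      filter(!is.na(.data$pos))
    if (nrow(stop_info) < config$n_stop_loss) {
      abort("not enough TGA/TAG-terminated genes to place stop-loss sites")
    }
    sl <- stop_info[sample.int(nrow(stop_info), config$n_stop_loss), ]
    sl_sites <- tibble(gene_id = sl$gene_id, pos = sl$pos, ref = "A",
                       alt = "G", kind = "editing", class = "stop_loss")

    # remaining sites: random A positions, unique, avoiding the stop sites
    a_positions <- purrr::map_dfr(seq_len(nrow(models)), function(i) {
      chars <- strsplit(models$seq[i], "")[[1]]
      tibble(gene_id = models$gene_id[i], pos = which(chars == "A"))
    }) |>
      anti_join(sl_sites[, c("gene_id", "pos")], by = c("gene_id", "pos"))

    n_rest <- (config$n_tracked - config$n_stop_loss) +
      config$n_background + config$n_shared
    if (nrow(a_positions) < n_rest) abort("not enough A positions to plant sites")
    picked <- a_positions[sample.int(nrow(a_positions), n_rest), ]
    classes <- rep(c("tracked", "background", "shared"),
                   c(config$n_tracked - config$n_stop_loss,
                     config$n_background, config$n_shared))
    rest_sites <- tibble(gene_id = picked$gene_id, pos = picked$pos,
                         ref = "A", alt = "G", kind = "editing",
                         class = classes)
    sites <- bind_rows(sl_sites, rest_sites)

    # per-condition editing fractions
    frac <- dplyr::case_when(
      sites$class %in% c("tracked", "stop_loss", "shared") ~
        runif(nrow(sites), config$tracked_fraction_range[1],
              config$tracked_fraction_range[2]),
      TRUE ~
        runif(nrow(sites), config$background_fraction_range[1],
              config$background_fraction_range[2])
    )
    for (cond in config$conditions) {
      col <- paste0("fraction_", cond)
      sites[[col]] <- dplyr::case_when(
        sites$class == "shared" ~ frac,
        cond == config$focal_condition ~ frac,
        TRUE ~ 0
      )
    }

    # reference errors: any base, random different alternative, fraction 1
    # everywhere, disjoint from editing sites
    all_positions <- purrr::map_dfr(seq_len(nrow(models)), function(i) {
      tibble(gene_id = models$gene_id[i], pos = seq_len(models$length[i]))
    }) |>
      anti_join(sites[, c("gene_id", "pos")], by = c("gene_id", "pos"))
    re_picked <- all_positions[sample.int(nrow(all_positions),
                                          config$n_ref_errors), ]
    re_ref <- substring(models$seq[match(re_picked$gene_id, models$gene_id)],
                        re_picked$pos, re_picked$pos)
    re_alt <- vapply(re_ref, function(r) sample(setdiff(BASES, r), 1),
                     character(1))
    ref_errors <- tibble(gene_id = re_picked$gene_id, pos = re_picked$pos,
                         ref = unname(re_ref), alt = unname(re_alt),
                         kind = "reference_error", class = NA_character_)
    for (cond in config$conditions) {
      ref_errors[[paste0("fraction_", cond)]] <- 1
    }

    truth <- bind_rows(sites, ref_errors)
    ann <- classify_sites(truth[, c("gene_id", "pos", "ref", "alt")], models)
    truth$region <- ann$region
    truth$category <- ann$category
    arrange(truth, .data$gene_id, .data$pos)
  })
}

#' Simulate per-base counts for one sample
#'
#' Per-base depth follows a negative binomial around
#' `mean_coverage * gene expression multiplier * positional profile`; the
#' expression multiplier is a condition-level gene property shared by the two
#' replicates, while depth and read draws differ between replicates only
#' through seed derivation `(seed, condition, replicate)`. At unedited
#' positions each read shows the reference with probability `1 - e` and each
#' wrong base with probability `e/3`; at a position edited with fraction `f`,
#' a read's template is the alternative base with probability `f` and the
#' same error overlay applies on top.
#'
#' @param models Gene models.
#' @param truth Truth tibble from [plant_editing()] (or `NULL` for no planted
#'   sites).
#' @param condition Condition label.
#' @param replicate Replicate index (1 or 2).
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @return Base-count tibble (`gene_id`, `pos`, `ref`, `A`, `C`, `G`, `T`,
#'   `indel_reads`).
#' @export
simulate_sample <- function(models, truth, condition, replicate,
                            config = sim_config(), seed = 1) {
  stopifnot(condition %in% config$conditions)
  n_genes <- nrow(models)
  gene_len <- models$length

  # condition-level gene expression multipliers and master-level profiles
  expr_mult <- with_seed(child_seed(seed, "expr", condition),
                         rlnorm(n_genes, 0, config$expr_sdlog))
  profile_pars <- with_seed(child_seed(seed, "profile"), {
    list(phase = runif(n_genes, 0, 2 * pi),
         cycles = sample(1:3, n_genes, replace = TRUE))
  })

  gene_idx <- rep.int(seq_len(n_genes), gene_len)
  pos <- unlist(lapply(gene_len, seq_len), use.names = FALSE)
  rel <- pos / gene_len[gene_idx]
  profile <- 1 + config$profile_amplitude *
    sin(2 * pi * profile_pars$cycles[gene_idx] * rel +
          profile_pars$phase[gene_idx])
  if (config$three_prime_bias > 0) {
    profile <- profile * (1 + config$three_prime_bias * rel)
  }
  mu <- config$mean_coverage * expr_mult[gene_idx] * profile

  ref <- unlist(strsplit(models$seq, ""), use.names = FALSE)
  n_pos <- length(pos)
  counts <- matrix(0L, nrow = n_pos, ncol = 4,
                   dimnames = list(NULL, BASES))
  e <- config$error_rate

  with_seed(child_seed(seed, "reads", condition, replicate), {
    depth <- rnbinom(n_pos, size = config$coverage_dispersion, mu = mu)

    # error-only background: split error reads uniformly over the 3 wrong bases
    n_err <- rbinom(n_pos, depth, e)
    e1 <- rbinom(n_pos, n_err, 1 / 3)
    e2 <- rbinom(n_pos, n_err - e1, 1 / 2)
    e3 <- n_err - e1 - e2
    ref_i <- match(ref, BASES)
    counts[cbind(seq_len(n_pos), ref_i)] <- depth - n_err
    others <- matrix(0L, nrow = n_pos, ncol = 3)
    others[, 1] <- e1; others[, 2] <- e2; others[, 3] <- e3
    other_base_idx <- t(vapply(ref_i, function(i) setdiff(1:4, i),
                               integer(3)))
    for (j in 1:3) {
      counts[cbind(seq_len(n_pos), other_base_idx[, j])] <-
        counts[cbind(seq_len(n_pos), other_base_idx[, j])] + others[, j]
    }

    # planted sites: redraw those positions from the editing model
    if (!is.null(truth) && nrow(truth)) {
      frac_col <- paste0("fraction_", condition)
      active <- truth[truth[[frac_col]] > 0, , drop = FALSE]
      if (nrow(active)) {
        gidx <- match(active$gene_id, models$gene_id)
        gene_offset <- cumsum(c(0L, gene_len))[seq_len(n_genes)]
        row_idx <- gene_offset[gidx] + active$pos
        for (s in seq_len(nrow(active))) {
          i <- row_idx[s]
          d <- depth[i]
          f <- active[[frac_col]][s]
          alt_templates <- rbinom(1, d, f)
          probs_for <- function(base) {
            p <- rep(e / 3, 4)
            p[match(base, BASES)] <- 1 - e
            p
          }
          from_alt <- if (alt_templates > 0) {
            rmultinom(1, alt_templates, probs_for(active$alt[s]))[, 1]
          } else {
            integer(4)
          }
          from_ref <- if (d - alt_templates > 0) {
            rmultinom(1, d - alt_templates, probs_for(active$ref[s]))[, 1]
          } else {
            integer(4)
          }
          counts[i, ] <- as.integer(from_alt + from_ref)
        }
      }
    }
  })

  tibble(gene_id = models$gene_id[gene_idx], pos = pos, ref = ref,
         A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
         T = counts[, "T"], indel_reads = 0L)
}

#' Simulate the full study: all conditions and replicates
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @return List with `models`, `truth`, and `counts` — one long base-count
#'   tibble with `condition` and `replicate` columns covering two replicates
#'   of every condition.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  models <- simulate_genes(config, seed)
  truth <- plant_editing(models, config, seed)
  counts <- purrr::map_dfr(config$conditions, function(cond) {
    purrr::map_dfr(1:2, function(rep_i) {
      simulate_sample(models, truth, cond, rep_i, config, seed) |>
        mutate(condition = cond, replicate = rep_i)
    })
  })
  list(models = models, truth = truth, counts = counts)
}

#' Simulate a sample and render it as mpileup text
#'
#' @inheritParams simulate_sample
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return mpileup lines (invisibly the path when `path` is given).
#' @export
simulate_pileup <- function(models, truth, condition, replicate,
                            config = sim_config(), seed = 1, path = NULL) {
  counts <- simulate_sample(models, truth, condition, replicate, config, seed)
  lines <- format_pileup(counts)
  if (is.null(path)) return(lines)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Simulate a clone matrix with tunable between-site dependence
#'
#' Each clone is, with probability `dependence`, driven by a single shared
#' latent uniform (site j edited iff the latent value falls below `p[j]` —
#' the comonotone, fully coupled regime) and otherwise edited independently
#' per site. Marginal frequencies equal `p` for every dependence value.
#'
#' @param p Per-site editing probabilities.
#' @param dependence Coupling strength in \[0, 1\] (0 = independent sites,
#'   1 = fully coupled).
#' @param n_clones Number of clones (rows).
#' @param seed Seed.
#' @return Integer 0/1 matrix with `n_clones` rows and named site columns.
#' @export
simulate_clone_set <- function(p, dependence = 0, n_clones = 10, seed = 1) {
  stopifnot(all(p >= 0 & p <= 1), dependence >= 0, dependence <= 1)
  k <- length(p)
  with_seed(child_seed(seed, "clones"), {
    coupled <- runif(n_clones) < dependence
    u <- runif(n_clones)
    mat <- matrix(0L, nrow = n_clones, ncol = k,
                  dimnames = list(NULL, paste0("site", seq_len(k))))
    for (j in seq_len(k)) {
      indep <- runif(n_clones) < p[j]
      mat[, j] <- as.integer(ifelse(coupled, u < p[j], indep))
    }
    mat
  })
}

#' Simulate an expression table consistent with the planted editing
#'
#' Per-gene, per-condition abundances are log-normal around a common
#' baseline; genes carrying an amino-acid-changing focal editing site with
#' fraction at least 0.10 are upshifted by `aa_expression_upshift` in the
#' focal condition, mirroring the association between recoding editing and
#' expression during sexual development.
#'
#' @param models Gene models.
#' @param truth Truth tibble from [plant_editing()].
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @return Long tibble `gene_id`, `condition`, `value`.
#' @export
simulate_expression <- function(models, truth, config = sim_config(),
                                seed = 1) {
  focal_frac <- paste0("fraction_", config$focal_condition)
  aa_genes <- truth |>
    filter(.data$kind == "editing",
           .data$category %in% c("nonsynonymous", "stop_loss"),
           .data[[focal_frac]] >= 0.10) |>
    pull(.data$gene_id) |>
    unique()
  with_seed(child_seed(seed, "expression"), {
    baseline <- rlnorm(nrow(models), meanlog = log(100), sdlog = 1)
    purrr::map_dfr(config$conditions, function(cond) {
      value <- baseline * rlnorm(nrow(models), meanlog = 0, sdlog = 0.3)
      if (cond == config$focal_condition) {
        up <- models$gene_id %in% aa_genes
        value[up] <- value[up] * config$aa_expression_upshift
      }
      tibble(gene_id = models$gene_id, condition = cond, value = value)
    })
  })
}

#' Simulate an ortholog-pair table for a second species
#'
#' Derives a diverged partner protein for each gene by substituting residues
#' at the given rate (never introducing stops), giving a pair table usable by
#' [shared_editing()].
#'
#' @param models Gene models (species a).
#' @param mutation_rate Per-residue substitution probability.
#' @param seed Seed.
#' @return Tibble `gene_id_a`, `gene_id_b`, `protein_a`, `protein_b`.
#' @export
simulate_orthologs <- function(models, mutation_rate = 0.1, seed = 1) {
  aa_alphabet <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  with_seed(child_seed(seed, "orthologs"), {
    purrr::map_dfr(seq_len(nrow(models)), function(i) {
      prot_a <- reference_protein(models[i, ])
      chars <- strsplit(prot_a, "")[[1]]
      mutate_at <- runif(length(chars)) < mutation_rate
      chars[mutate_at] <- vapply(
        chars[mutate_at],
        function(a) sample(setdiff(aa_alphabet, a), 1),
        character(1)
      )
      tibble(gene_id_a = models$gene_id[i],
             gene_id_b = paste0(models$gene_id[i], "_b"),
             protein_a = prot_a,
             protein_b = paste(chars, collapse = ""))
    })
  })
}
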