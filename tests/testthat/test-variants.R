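test_that("detection thresholds behave as published at the boundaries", {
  p <- detection_params()
  col <- function(ref, A, C, G, T, indel = 0L) {
    tibble::tibble(gene_id = "g", pos = 1L, ref = ref, A = A, C = C,
                   G = G, T = T, indel_reads = indel)
  }
  # below minimal coverage of five reads
  expect_equal(nrow(call_variants(col("A", 2L, 0L, 2L, 0L), p)), 0L)
  # 3 reads = exactly 3% of 100: emitted
  v <- call_variants(col("A", 97L, 0L, 3L, 0L), p)
  expect_equal(v$alt, "G")
  expect_equal(v$alt_fraction, 0.03)
  # two qualifying alternatives: discarded entirely
  expect_equal(nrow(call_variants(col("A", 56L, 0L, 2L, 2L), p)), 0L)
  # 2/67 = 2.985% < 3%: just under the fraction threshold
  expect_equal(nrow(call_variants(col("A", 65L, 0L, 2L, 0L), p)), 0L)
  # qualifying indel evidence vetoes the position
  expect_equal(nrow(call_variants(col("A", 90L, 0L, 10L, 0L, indel = 2L), p)),
               0L)
  expect_equal(nrow(call_variants(col("A", 90L, 0L, 10L, 0L, indel = 1L), p)),
               1L)
  # strict single-alternative mode: one stray read of a second base voids
  strict <- detection_params(strict_single_alt = TRUE)
  expect_equal(nrow(call_variants(col("A", 90L, 1L, 9L, 0L), strict)), 0L)
  expect_equal(nrow(call_variants(col("A", 90L, 1L, 9L, 0L), p)), 1L)
})

test_that("call_variants agrees with the exhaustive four-base oracle", {
  for (seed in c(3, 17)) {
    counts <- random_columns(300, seed = seed)
    for (p in list(detection_params(),
                   detection_params(min_depth = 3, min_alt_fraction = 0.1,
                                    min_alt_reads = 3),
                   detection_params(strict_single_alt = TRUE))) {
      got <- call_variants(counts, p)
      want <- oracle_call_variants(counts, p)
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
  }
})

test_that("tightening depth or fraction thresholds never adds a called site", {
  counts <- random_columns(300, seed = 5)
  base <- call_variants(counts, detection_params())
  key <- function(x) paste(x$pos, x$alt)
  tighter <- list(
    detection_params(min_depth = 10),
    detection_params(min_alt_fraction = 0.1)
  )
  for (p in tighter) {
    expect_true(all(key(call_variants(counts, p)) %in% key(base)))
  }
  # min_alt_reads is monotone only on single-alternative columns: on
  # multi-alternative columns a higher read threshold can disqualify the
  # second alternative and thereby rescue a previously discarded position
  # (a direct consequence of the single-alternative discard rule), and it
  # also relaxes the indel veto.
  single_alt <- counts |>
    dplyr::filter(indel_reads == 0) |>
    dplyr::filter({
      mat <- cbind(A, C, G, T)
      mat[cbind(seq_len(dplyr::n()), match(ref, c("A", "C", "G", "T")))] <- 0L
      rowSums(mat > 0) <= 1
    })
  base_sa <- call_variants(single_alt, detection_params())
  stricter <- call_variants(single_alt, detection_params(min_alt_reads = 4))
  expect_true(all(key(stricter) %in% key(base_sa)))

  # and the documented non-monotone rescue really exists
  rescue <- tibble::tibble(gene_id = "g", pos = 1L, ref = "A",
                           A = 50L, C = 0L, G = 6L, T = 2L, indel_reads = 0L)
  expect_equal(nrow(call_variants(rescue, detection_params())), 0L)
  expect_equal(nrow(call_variants(rescue,
                                  detection_params(min_alt_reads = 4))), 1L)
})

test_that("error-free data with no edits yields zero variant calls", {
  cfg <- sim_config(n_genes = 4, error_rate = 0, n_tracked = 0,
                    n_stop_loss = 0, n_background = 0, n_ref_errors = 0)
  sim <- simulate_study(cfg, seed = 7)
  calls <- sim$counts |>
    dplyr::group_by(condition, replicate) |>
    dplyr::group_map(~ call_variants(.x))
  expect_true(all(vapply(calls, nrow, integer(1)) == 0L))
})

test_that("covered-base counting applies the depth threshold", {
  counts <- tibble::tibble(gene_id = "g", pos = 1:3, ref = "A",
                           A = c(5L, 4L, 7L), C = 0L, G = 0L, T = 0L)
  expect_equal(count_covered_bases(counts, 5), 2L)
  expect_equal(count_covered_bases(counts[0, ], 5), 0L)
  expect_equal(count_covered_bases(dplyr::mutate(counts, A = 10L), 5), 3L)
})

test_that("the genome-error screen requires the same near-fixed base in all covered samples", {
  col <- function(sample, A, G, pos = 1L) {
    tibble::tibble(sample = sample, gene_id = "g", pos = pos, ref = "A",
                   A = A, C = 0L, G = G, T = 0L, indel_reads = 0L)
  }
  # 97% alternative in all ten samples: flagged
  all_high <- dplyr::bind_rows(lapply(1:10, function(i) col(paste0("s", i), 3L, 97L)))
  flagged <- flag_reference_discrepancies(all_high)
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$alt, "G")

  # one covered sample at 50%: the "all samples" quantifier fails
  mixed <- dplyr::bind_rows(all_high[1:9, ], col("s10", 50L, 50L))
  expect_equal(nrow(flag_reference_discrepancies(mixed)), 0L)

  # a sample below the depth threshold abstains rather than voting
  with_shallow <- dplyr::bind_rows(all_high[1:9, ], col("s10", 2L, 2L))
  expect_equal(nrow(flag_reference_discrepancies(with_shallow)), 1L)

  expect_error(flag_reference_discrepancies(list(all_high[1, ])), "2 samples")
})

test_that("a planted reference error is the one position flagged", {
  cfg <- sim_config(n_genes = 5, n_tracked = 3, n_stop_loss = 1,
                    n_background = 4, n_ref_errors = 1)
  sim <- simulate_study(cfg, seed = 3)
  flagged <- flag_reference_discrepancies(
    dplyr::mutate(sim$counts, sample = paste(condition, replicate)))
  truth_re <- dplyr::filter(sim$truth, kind == "reference_error")
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$pos, truth_re$pos)
  expect_equal(flagged$gene_id, truth_re$gene_id)
  expect_equal(flagged$alt, truth_re$alt)
})
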