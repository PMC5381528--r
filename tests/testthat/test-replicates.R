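site_row <- function(gene = "g1", pos = 100L, ref = "A", alt = "G",
                     depth = 50L, alt_count = 25L) {
  tibble::tibble(gene_id = gene, pos = pos, ref = ref, alt = alt,
                 depth = depth, alt_count = alt_count,
                 alt_fraction = alt_count / depth)
}

test_that("replicate intersection matches on the full site key", {
  both <- intersect_replicates(site_row(), site_row(depth = 40L, alt_count = 10L))
  expect_equal(nrow(both), 1L)
  expect_equal(both$depth_rep1, 50L)
  expect_equal(both$depth_rep2, 40L)
  expect_equal(both$alt_fraction_pooled, 35 / 90)

  # same position, different alternative base: not reproducible
  expect_equal(nrow(intersect_replicates(site_row(alt = "G"),
                                         site_row(alt = "T"))), 0L)
  expect_equal(nrow(intersect_replicates(site_row(), site_row(pos = 101L))), 0L)
})

test_that("condition specificity means absence from every other condition", {
  sites <- dplyr::bind_rows(
    dplyr::mutate(site_row(pos = 1L), condition = "proto"),
    dplyr::mutate(site_row(pos = 2L), condition = "proto"),
    dplyr::mutate(site_row(pos = 2L), condition = "veg"),
    dplyr::mutate(site_row(pos = 3L), condition = "veg")
  )
  out <- condition_specific(sites)
  expect_equal(out$specific, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$specific_to, c("proto", NA, NA, "veg"))

  # constructed truth: 20 proto-only and 5 shared sites -> exactly 20 specific
  proto_only <- dplyr::bind_rows(lapply(1:20, function(i) {
    dplyr::mutate(site_row(pos = i), condition = "proto")
  }))
  shared <- dplyr::bind_rows(lapply(21:25, function(i) {
    dplyr::bind_rows(dplyr::mutate(site_row(pos = i), condition = "proto"),
                     dplyr::mutate(site_row(pos = i), condition = "veg"))
  }))
  out <- condition_specific(dplyr::bind_rows(proto_only, shared))
  expect_equal(sum(out$specific & out$condition == "proto"), 20L)
  expect_equal(sum(out$specific & out$condition == "veg"), 0L)
})

test_that("strict specificity consults raw per-replicate calls", {
  sites <- dplyr::bind_rows(
    dplyr::mutate(site_row(pos = 1L), condition = "proto"))
  raw <- dplyr::bind_rows(
    dplyr::mutate(site_row(pos = 1L), condition = "proto"),
    dplyr::mutate(site_row(pos = 1L), condition = "veg")) # one-replicate hit
  expect_true(condition_specific(sites)$specific)
  expect_false(condition_specific(sites, strict = TRUE,
                                  raw_calls = raw)$specific)
})

test_that("per-million normalization and its domain errors", {
  expect_equal(normalize_per_million(103, 1e6), 103)
  expect_equal(normalize_per_million(0, 123), 0)
  # consistent with the published wt-proto covered-base denominator
  expect_equal(round(normalize_per_million(486, 4708650), 1), 103.2)
  expect_error(normalize_per_million(1, 0), "positive")
})

test_that("summarize_condition computes the replicate-reproducibility row", {
  rep1 <- dplyr::bind_rows(site_row(pos = 1L), site_row(pos = 2L),
                           site_row(pos = 3L, ref = "C", alt = "T"))
  rep2 <- dplyr::bind_rows(site_row(pos = 1L), site_row(pos = 4L),
                           site_row(pos = 3L, ref = "C", alt = "T"))
  s <- summarize_condition(rep1, rep2, 1e6, 2e6, condition = "x")
  expect_equal(s$n_rep1, 3L)
  expect_equal(s$n_both, 2L)
  expect_equal(s$covered_bases_mean, 1.5e6)
  expect_equal(s$norm_rep1, 3)
  expect_equal(s$norm_rep2, 1.5)
  expect_equal(s$norm_both, 2 / 1.5)
  expect_equal(s$pct_both, 100 * (2 / 1.5) / 2.25)

  # type filter restricts every count to that substitution type
  s_ag <- summarize_condition(rep1, rep2, 1e6, 2e6, type_filter = "AG")
  expect_equal(s_ag$n_rep1, 2L)
  expect_equal(s_ag$n_both, 1L)

  # identical call sets and equal covered bases: 100% reproducible
  s_id <- summarize_condition(rep1, rep1, 1e6, 1e6)
  expect_equal(s_id$pct_both, 100)

  # empty replicates: zero rates, undefined percentage
  s0 <- summarize_condition(rep1[0, ], rep1[0, ], 1e6, 1e6)
  expect_equal(s0$norm_both, 0)
  expect_true(is.na(s0$pct_both))
})

test_that("summaries agree with a brute-force set computation on random call sets", {
  set.seed(42)
  for (i in 1:10) {
    keys1 <- sample(1:30, sample(3:15, 1))
    keys2 <- sample(1:30, sample(3:15, 1))
    rep1 <- dplyr::bind_rows(lapply(keys1, function(k) site_row(pos = k)))
    rep2 <- dplyr::bind_rows(lapply(keys2, function(k) site_row(pos = k)))
    cov1 <- sample(1e5:1e6, 1)
    cov2 <- sample(1e5:1e6, 1)
    s <- summarize_condition(rep1, rep2, cov1, cov2)
    n_both <- length(intersect(keys1, keys2))
    expect_equal(s$n_both, n_both)
    expect_lte(s$n_both, min(length(keys1), length(keys2)))
    expect_equal(s$norm_both, 1e6 * n_both / mean(c(cov1, cov2)))
    expect_gte(s$pct_both, 0)
    expect_lte(s$pct_both, 200)
    # equal covered bases bound the percentage by 100
    s_eq <- summarize_condition(rep1, rep2, cov1, cov1)
    expect_lte(s_eq$pct_both, 100)
  }
})

test_that("specific and shared sites partition the reproducible universe", {
  set.seed(9)
  conds <- c("a", "b", "c")
  sites <- dplyr::bind_rows(lapply(conds, function(cc) {
    dplyr::bind_rows(lapply(sample(1:40, 15), function(k) {
      dplyr::mutate(site_row(pos = k), condition = cc)
    }))
  }))
  out <- condition_specific(sites)
  n_specific <- sum(out$specific)
  n_shared_records <- sum(!out$specific)
  expect_equal(n_specific + n_shared_records, nrow(sites))
  # every non-specific record's key occurs in >= 2 conditions
  shared_keys <- unique(out$pos[!out$specific])
  for (k in shared_keys) {
    expect_gte(length(unique(out$condition[out$pos == k])), 2L)
  }
})
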