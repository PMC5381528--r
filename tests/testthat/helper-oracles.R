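## Independent oracles and small fixture builders used across the suite.

bases4 <- c("A", "C", "G", "T")

## Build a one-row gene-model tibble from explicit segments.
make_model <- function(gene_id, seq, kinds, starts, ends) {
  tibble::tibble(
    gene_id = gene_id,
    length = nchar(seq),
    coding = "cds" %in% kinds,
    cds_complete = sum(ends[kinds == "cds"] - starts[kinds == "cds"] + 1) %% 3 == 0,
    seq = seq,
    segments = list(tibble::tibble(kind = kinds, start = as.integer(starts),
                                   end = as.integer(ends)))
  )
}

## Random base-count columns with a mix of depths and alternative structures.
random_columns <- function(n, seed, max_depth = 30) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    depth <- sample(0:max_depth, 1)
    ref <- sample(bases4, 1)
    # skew toward the reference but leave room for multi-alt columns
    probs <- runif(4, 0, 1)
    probs[match(ref, bases4)] <- probs[match(ref, bases4)] + runif(1, 1, 6)
    cnt <- as.vector(rmultinom(1, depth, probs / sum(probs)))
    tibble::tibble(gene_id = "g", pos = i, ref = ref,
                   A = cnt[1], C = cnt[2], G = cnt[3], T = cnt[4],
                   indel_reads = sample(0:3, 1, prob = c(0.7, 0.1, 0.1, 0.1)))
  })
  dplyr::bind_rows(rows)
}

## Exhaustive re-implementation of the detection thresholds: tries all four
## alternative bases for every column, no vectorization shared with the
## package path.
oracle_call_variants <- function(counts, p) {
  res <- list()
  for (i in seq_len(nrow(counts))) {
    r <- counts[i, ]
    depth <- r$A + r$C + r$G + r$T
    if (depth < p$min_depth) next
    ir <- if ("indel_reads" %in% names(r)) r$indel_reads else 0
    if (ir >= p$min_alt_reads) next
    alts <- setdiff(bases4, r$ref)
    cnt <- c(r$A, r$C, r$G, r$T)[match(alts, bases4)]
    qualifying <- alts[cnt >= p$min_alt_reads]
    ok <- if (p$strict_single_alt) {
      length(qualifying) == 1 && sum(cnt > 0) == 1
    } else {
      length(qualifying) == 1
    }
    if (!ok) next
    ac <- cnt[match(qualifying, alts)]
    if (ac / depth < p$min_alt_fraction) next
    res[[length(res) + 1]] <- tibble::tibble(
      gene_id = r$gene_id, pos = r$pos, ref = r$ref, alt = qualifying,
      depth = as.integer(depth), alt_count = as.integer(ac),
      alt_fraction = ac / depth)
  }
  if (length(res)) {
    dplyr::bind_rows(res)
  } else {
    tibble::tibble(gene_id = character(), pos = integer(), ref = character(),
                   alt = character(), depth = integer(),
                   alt_count = integer(), alt_fraction = numeric())
  }
}

## Brute-force global alignment score by enumerating every monotone
## alignment path, scoring gap runs with affine costs (a run of length L
## costs open + L * extend). Exponential; only for tiny strings.
brute_align_score <- function(a, b, submat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, submat[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- gap_extend + if (identical(last, "GB")) 0 else gap_open
      best <- max(best, -cost + rec(i + 1, j, "GB"))
    }
    if (j <= m) {
      cost <- gap_extend + if (identical(last, "GA")) 0 else gap_open
      best <- max(best, -cost + rec(i, j + 1, "GA"))
    }
    best
  }
  rec(1, 1, "start")
}

## Poisson-binomial pmf by explicit enumeration over all 2^k outcome patterns.
enum_poisbinom <- function(p) {
  k <- length(p)
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  pattern_prob <- apply(grid, 1, function(z) prod(ifelse(z == 1, p, 1 - p)))
  sums <- rowSums(grid)
  vapply(0:k, function(s) sum(pattern_prob[sums == s]), numeric(1))
}

## Type-7 quantile by direct order-statistic interpolation.
quantile7_oracle <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

## Random small gene model (single- or two-segment CDS) for classifier checks.
random_small_model <- function(gene_id, n_codons = 25, with_intron = FALSE) {
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  codons <- c("ATG", sample(non_stop, n_codons - 2, replace = TRUE),
              sample(c("TAA", "TAG", "TGA"), 1))
  cds <- paste(codons, collapse = "")
  u5 <- paste(sample(bases4, 12, TRUE), collapse = "")
  u3 <- paste(sample(bases4, 30, TRUE), collapse = "")
  if (with_intron) {
    cut <- 3 * sample(5:(n_codons - 5), 1)
    intron <- paste(sample(bases4, 20, TRUE), collapse = "")
    seqs <- paste0(u5, substring(cds, 1, cut), intron,
                   substring(cds, cut + 1, nchar(cds)), u3)
    make_model(gene_id, seqs,
               c("five_utr", "cds", "intron", "cds", "three_utr"),
               c(1, 13, 13 + cut, 33 + cut, 13 + nchar(cds) + 20),
               c(12, 12 + cut, 32 + cut, 12 + nchar(cds) + 20,
                 nchar(seqs)))
  } else {
    seqs <- paste0(u5, cds, u3)
    make_model(gene_id, seqs, c("five_utr", "cds", "three_utr"),
               c(1, 13, 13 + nchar(cds)),
               c(12, 12 + nchar(cds), nchar(seqs)))
  }
}

## Translate a DNA string codon-wise up to (not including) the first stop.
translate_to_stop <- function(cds) {
  n <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aa == "*")[1]
  if (is.na(stop_at)) paste(aa, collapse = "") else
    paste(aa[seq_len(stop_at - 1)], collapse = "")
}
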