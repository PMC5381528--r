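simple_model <- function() {
  # 5'UTR 1-3, CDS 4-9 (ATG TGA), 3'UTR 10-15 (AAA TAA)
  make_model("t1", "GGGATGTGAAAATAA",
             c("five_utr", "cds", "three_utr"), c(1, 4, 10), c(3, 9, 15))
}

test_that("locate_site maps gene-space positions through spliced CDS arithmetic", {
  m <- make_model("g", "GGGATGAAATGAXX", c("five_utr", "cds", "three_utr"),
                  c(1, 4, 12), c(3, 11, 14))
  m$seq <- "GGGATGAAATGACC" # fix placeholder
  expect_equal(locate_site(m, 5)$cds_offset, 2L)
  expect_equal(locate_site(m, 2)$region, "five_utr")

  # split CDS 4-6 and 10-12 with intron 7-9: position 11 is spliced offset 5
  m2 <- make_model("g2", "GGGATGTTTTGA",
                   c("five_utr", "cds", "intron", "cds"),
                   c(1, 4, 7, 10), c(3, 6, 9, 12))
  loc <- locate_site(m2, 11)
  expect_equal(loc$region, "cds")
  expect_equal(loc$cds_offset, 5L)
  expect_equal(locate_site(m2, 8)$region, "intron")
  expect_error(locate_site(m2, 13), "outside")

  noncod <- make_model("g3", "ACGTACGT", "three_utr", 1, 8)
  expect_equal(locate_site(noncod, 4)$region, "noncoding_gene")
})

test_that("codon consequences follow the standard genetic code", {
  m <- simple_model()
  # TGA stop edited at codon position 3 -> TGG (Trp): stop loss
  s <- classify_sites(tibble::tibble(gene_id = "t1", pos = 9L,
                                     ref = "A", alt = "G"), m)
  expect_equal(s$category, "stop_loss")
  expect_equal(s$ref_codon, "TGA")
  expect_equal(s$alt_codon, "TGG")
  expect_equal(s$alt_aa, "W")
  expect_equal(s$codon_position, 3L)
  expect_equal(s$extension_aa, 1L) # reads through AAA then hits TAA

  # GCA -> GCG at position 3: synonymous alanine
  m_syn <- make_model("s", "ATGGCATAG", "cds", 1, 9)
  s <- classify_sites(tibble::tibble(gene_id = "s", pos = 6L,
                                     ref = "A", alt = "G"), m_syn)
  expect_equal(s$category, "synonymous")
  expect_equal(s$ref_aa, "A")

  # AAA -> AGA at position 2: Lys to Arg
  m_ns <- make_model("n", "ATGAAATAG", "cds", 1, 9)
  s <- classify_sites(tibble::tibble(gene_id = "n", pos = 5L,
                                     ref = "A", alt = "G"), m_ns)
  expect_equal(s$category, "nonsynonymous")
  expect_equal(paste0(s$ref_aa, s$alt_aa), "KR")

  # TAA -> TAG: still a stop
  m_sr <- make_model("r", "ATGAAATAA", "cds", 1, 9)
  s <- classify_sites(tibble::tibble(gene_id = "r", pos = 9L,
                                     ref = "A", alt = "G"), m_sr)
  expect_equal(s$category, "stop_retained")

  # intron site: region only, no codon fields
  m2 <- make_model("g2", "GGGATGTTTTGA",
                   c("five_utr", "cds", "intron", "cds"),
                   c(1, 4, 7, 10), c(3, 6, 9, 12))
  s <- classify_sites(tibble::tibble(gene_id = "g2", pos = 8L,
                                     ref = "T", alt = "C"), m2)
  expect_equal(s$region, "intron")
  expect_true(is.na(s$category))

  # reference mismatch signals annotation/sequence desync
  expect_error(
    classify_sites(tibble::tibble(gene_id = "t1", pos = 9L,
                                  ref = "C", alt = "G"), simple_model()),
    "mismatch")
})

test_that("edited_protein reads through lost stops on the unspliced transcript", {
  m <- simple_model()
  ep <- edited_protein(m, tibble::tibble(pos = 9L, ref = "A", alt = "G"))
  expect_equal(ep$protein, "MWK")
  expect_equal(ep$extension_aa, 1L)
  expect_false(ep$overran)

  # no edits: the reference translation
  expect_equal(edited_protein(m)$protein, "M")
  expect_equal(reference_protein(m), "M")
  expect_equal(edited_protein(m)$extension_aa, 0L)

  # TAG -> TGG via the position-2 A
  m_tag <- make_model("t2", "ATGTAGAAATAA", c("cds", "three_utr"),
                      c(1, 7), c(6, 12))
  ep <- edited_protein(m_tag, tibble::tibble(pos = 5L, ref = "A", alt = "G"))
  expect_equal(ep$protein, "MWK")

  # downstream intron annotation is NOT excised during read-through
  m_int <- make_model("t3", "ATGTGACCCTAA", c("cds", "intron", "three_utr"),
                      c(1, 7, 10), c(6, 9, 12))
  ep <- edited_protein(m_int, tibble::tibble(pos = 6L, ref = "A", alt = "G"))
  expect_equal(ep$protein, "MWP") # CCC read literally despite intron label

  # no downstream stop: overrun flagged
  m_run <- make_model("t4", "ATGTGAAAAAAA", c("cds", "three_utr"),
                      c(1, 7), c(6, 12))
  ep <- edited_protein(m_run, tibble::tibble(pos = 6L, ref = "A", alt = "G"))
  expect_true(ep$overran)
  expect_equal(ep$extension_aa, 2L)

  expect_error(
    edited_protein(m, tibble::tibble(pos = 3L, ref = "G", alt = "A")),
    "A-to-G")
})

test_that("A-to-G edits can never create a stop codon", {
  stops <- c("TAA", "TAG", "TGA")
  codons <- names(Biostrings::GENETIC_CODE)
  for (codon in setdiff(codons, stops)) {
    for (cp in which(strsplit(codon, "")[[1]] == "A")) {
      edited <- codon
      substring(edited, cp, cp) <- "G"
      expect_false(edited %in% stops)
    }
  }
})

test_that("classify_sites agrees with a full-CDS translation diff", {
  set.seed(123)
  for (i in 1:120) {
    m <- random_small_model(paste0("m", i), n_codons = sample(10:30, 1),
                            with_intron = i %% 3 == 0)
    # random A position inside the CDS
    seg <- m$segments[[1]]
    cds_pos <- unlist(lapply(which(seg$kind == "cds"),
                             function(j) seg$start[j]:seg$end[j]))
    a_pos <- cds_pos[substring(m$seq, cds_pos, cds_pos) == "A"]
    if (!length(a_pos)) next
    pos <- sample(a_pos, 1)
    got <- classify_sites(tibble::tibble(gene_id = m$gene_id, pos = pos,
                                         ref = "A", alt = "G"), m)

    # oracle: translate full reference and edited spliced CDS and diff
    splice <- function(s) {
      paste(substring(s, seg$start[seg$kind == "cds"],
                      seg$end[seg$kind == "cds"]), collapse = "")
    }
    edited_seq <- m$seq
    substring(edited_seq, pos, pos) <- "G"
    p_ref <- translate_to_stop(splice(m$seq))
    p_alt <- translate_to_stop(splice(edited_seq))
    want <- if (nchar(p_alt) > nchar(p_ref)) {
      "stop_loss" # translation extends: the stop was edited away
    } else if (p_ref == p_alt) {
      c("synonymous", "stop_retained")
    } else {
      "nonsynonymous"
    }
    expect_true(got$category %in% want)
  }
})

test_that("consequence accounting sums its categories", {
  set.seed(7)
  m <- random_small_model("acc", n_codons = 40)
  seg <- m$segments[[1]]
  a_pos <- which(strsplit(m$seq, "")[[1]] == "A")
  sites <- classify_sites(
    tibble::tibble(gene_id = "acc", pos = sample(a_pos, 15),
                   ref = "A", alt = "G"), m)
  summ <- consequence_summary(sites)
  expect_equal(summ$n_cds,
               summ$n_synonymous + summ$n_nonsynonymous +
                 summ$n_stop_loss + summ$n_stop_retained)
  expect_equal(summ$pct_product_changed,
               100 * (summ$n_nonsynonymous + summ$n_stop_loss) / summ$n_sites)
})
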