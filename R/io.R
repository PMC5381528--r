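#' Read a FASTA file of gene-space sequences
#'
#' Reads unspliced, sense-strand gene sequences (UTRs + exons + introns) into a
#' named character vector. Sequences are uppercased; record order is preserved.
#' Mapping RNA-seq reads to these gene-space sequences (rather than the genome)
#' is what lets A-to-I editing show up directly as A-to-G, without reverse
#' strand aliasing as T-to-C.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, `gene_id -> sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate FASTA id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(set))
  if (any(grepl("[^ACGTN]", seqs))) {
    abort("FASTA sequences contain characters outside {A,C,G,T,N}")
  }
  setNames(seqs, ids)
}

#' Read gene structure annotation into gene models
#'
#' Builds per-gene transcript models from a segment annotation plus the
#' gene-space sequences. Each gene is described by an ordered set of segments
#' (`five_utr`, `cds`, `intron`, `three_utr`) in 1-based inclusive gene-space
#' coordinates that must tile the whole sequence without gaps or overlaps.
#'
#' The canonical annotation format is a 4-column TSV
#' (`gene_id`, `kind`, `start`, `end`); a GFF3 subset using feature types
#' `five_prime_UTR` / `CDS` / `intron` / `three_prime_UTR` with the gene id in
#' the seqid column is also accepted, as is an in-memory data frame with the
#' TSV columns.
#'
#' @param annotation Path to a TSV or GFF3 file, or a data frame with columns
#'   `gene_id`, `kind`, `start`, `end`.
#' @param sequences Named character vector from [read_fasta()].
#' @return A tibble with one row per gene: `gene_id`, `length`, `coding`
#'   (has at least one CDS segment), `cds_complete` (spliced CDS length is a
#'   multiple of 3), `seq`, and a `segments` list-column of per-gene segment
#'   tibbles sorted by `start`.
#' @export
read_gene_models <- function(annotation, sequences) {
  seg <- if (is.data.frame(annotation)) {
    as_tibble(annotation)
  } else if (grepl("\\.gff3?$", annotation, ignore.case = TRUE)) {
    read_gff_segments(annotation)
  } else {
    readr::read_tsv(annotation, show_col_types = FALSE,
                    col_types = readr::cols(
                      gene_id = readr::col_character(),
                      kind = readr::col_character(),
                      start = readr::col_integer(),
                      end = readr::col_integer()
                    ))
  }
  required <- c("gene_id", "kind", "start", "end")
  if (!all(required %in% names(seg))) {
    abort("annotation must have columns gene_id, kind, start, end")
  }
  bad_kind <- setdiff(unique(seg$kind), SEGMENT_KINDS)
  if (length(bad_kind)) {
    abort(paste0("unknown segment kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  missing_seq <- setdiff(unique(seg$gene_id), names(sequences))
  if (length(missing_seq)) {
    abort(paste0("no sequence for annotated gene(s): ",
                 paste(missing_seq, collapse = ", ")))
  }

  seg |>
    group_by(.data$gene_id) |>
    tidyr::nest(segments = c("kind", "start", "end")) |>
    ungroup() |>
    mutate(
      seq = unname(sequences[.data$gene_id]),
      length = nchar(.data$seq),
      segments = purrr::pmap(
        list(.data$segments, .data$length, .data$gene_id), validate_segments
      ),
      coding = purrr::map_lgl(.data$segments, ~ any(.x$kind == "cds")),
      cds_complete = purrr::map_lgl(
        .data$segments,
        ~ any(.x$kind == "cds") &&
          sum(.x$end[.x$kind == "cds"] - .x$start[.x$kind == "cds"] + 1L) %% 3L == 0L
      )
    ) |>
    select("gene_id", "length", "coding", "cds_complete", "seq", "segments")
}

read_gff_segments <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  kind_map <- c(
    five_prime_UTR = "five_utr", CDS = "cds",
    intron = "intron", three_prime_UTR = "three_utr"
  )
  keep <- as.character(gff$type) %in% names(kind_map)
  gff <- gff[keep]
  tibble(
    gene_id = as.character(GenomicRanges::seqnames(gff)),
    kind = unname(kind_map[as.character(gff$type)]),
    start = BiocGenerics::start(gff),
    end = BiocGenerics::end(gff)
  )
}

## Check that one gene's segments tile [1, len] without overlap or gap.
validate_segments <- function(segments, len, gene_id) {
  segments <- arrange(segments, .data$start)
  if (any(segments$start > segments$end)) {
    abort(paste0("gene ", gene_id, ": segment with start > end"))
  }
  expected_start <- c(1L, segments$end[-nrow(segments)] + 1L)
  if (any(segments$start < expected_start)) {
    abort(paste0("gene ", gene_id, ": overlapping segments"))
  }
  if (any(segments$start > expected_start) ||
      segments$end[nrow(segments)] != len) {
    abort(paste0("gene ", gene_id,
                 ": segments do not tile positions 1-", len, " (gap)"))
  }
  segments
}

#' Parse samtools mpileup text into per-base counts
#'
#' Decodes the 6-column `samtools mpileup` dialect (reference name, 1-based
#' position, reference base, depth, read-bases string, base qualities) into a
#' per-position base-count table. In the read-bases string, `.` and `,` count
#' toward the reference base and letter calls toward their base (case-folded);
#' `+N`/`-N` indel runs are consumed and tallied into `indel_reads`; read
#' starts (`^` with its mapping-quality byte), read ends (`$`), deletion
#' placeholders (`*`) and reference skips (`>`, `<`) are excluded from base
#' counts, as are `N` calls.
#'
#' @param x Path to an mpileup file, or a character vector of mpileup lines.
#' @return A base-count tibble with columns `gene_id`, `pos`, `ref`,
#'   `A`, `C`, `G`, `T`, `indel_reads`. Depth for thresholding is always
#'   recomputed as `A + C + G + T`.
#' @export
parse_mpileup <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readr::read_lines(x)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(gene_id = character(), pos = integer(), ref = character(),
                  A = integer(), C = integer(), G = integer(), T = integer(),
                  indel_reads = integer()))
  }
  parsed <- purrr::imap(lines, parse_mpileup_line)
  bind_rows(parsed)
}

parse_mpileup_line <- function(line, line_no) {
  f <- strsplit(trimws(line), "[ \t]+")[[1]]
  if (length(f) < 5) {
    abort(paste0("mpileup line ", line_no, ": fewer than 5 columns"))
  }
  ref <- toupper(f[3])
  s <- f[5]
  # read starts carry a mapping-quality byte that must not be read as a call
  s <- gsub("\\^.", "", s)
  s <- gsub("$", "", s, fixed = TRUE)

  indel_reads <- 0L
  repeat {
    m <- regexpr("[+-][0-9]+", s)
    if (m == -1) break
    run_start <- as.integer(m)
    digits <- regmatches(s, m)
    ins_len <- as.integer(substring(digits, 2))
    consumed_end <- run_start + attr(m, "match.length") - 1L + ins_len
    if (consumed_end > nchar(s)) {
      abort(paste0("mpileup line ", line_no, ": truncated indel run"))
    }
    s <- paste0(substring(s, 1, run_start - 1L),
                substring(s, consumed_end + 1L))
    indel_reads <- indel_reads + 1L
  }
  if (grepl("[+-]", s)) {
    abort(paste0("mpileup line ", line_no,
                 ": malformed indel run (non-numeric length)"))
  }

  chars <- toupper(strsplit(s, "", fixed = TRUE)[[1]])
  chars[chars %in% c(".", ",")] <- ref
  excluded <- chars %in% c("*", ">", "<", "N")
  unknown <- !excluded & !(chars %in% BASES)
  if (any(unknown)) {
    abort(paste0("mpileup line ", line_no, ": unexpected character(s) '",
                 paste(unique(chars[unknown]), collapse = ""),
                 "' in read-bases string"))
  }
  counts <- vapply(BASES, function(b) sum(chars == b), integer(1))
  tibble(gene_id = f[1], pos = as.integer(f[2]), ref = ref,
         A = counts[["A"]], C = counts[["C"]], G = counts[["G"]],
         T = counts[["T"]], indel_reads = indel_reads)
}

#' Render per-base counts as mpileup text
#'
#' Inverse of [parse_mpileup()] for synthetic data: writes one 6-column
#' mpileup line per position, using `.` for reference-matching calls, upper
#' case letters for alternative calls and a constant placeholder base quality.
#' Zero-depth columns are written as `* *`, as samtools does.
#'
#' @param counts Base-count tibble (see [parse_mpileup()]).
#' @param qual Single character used for every base quality.
#' @return Character vector of mpileup lines.
#' @export
format_pileup <- function(counts, qual = "I") {
  stopifnot(all(c("gene_id", "pos", "ref", BASES) %in% names(counts)))
  mat <- as.matrix(counts[, BASES])
  depth <- rowSums(mat)
  bases <- character(nrow(counts))
  quals <- character(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    ref <- counts$ref[i]
    calls <- c(
      strrep(".", mat[i, ref]),
      purrr::map_chr(setdiff(BASES, ref), ~ strrep(.x, mat[i, .x]))
    )
    bases[i] <- paste(calls, collapse = "")
    quals[i] <- strrep(qual, depth[i])
    if (depth[i] == 0) {
      bases[i] <- "*"
      quals[i] <- "*"
    }
  }
  paste(counts$gene_id, counts$pos, counts$ref, depth, bases, quals,
        sep = "\t")
}

#' @rdname format_pileup
#' @param path Output file path.
#' @export
write_pileup <- function(counts, path, qual = "I") {
  readr::write_lines(format_pileup(counts, qual), path)
  invisible(path)
}

#' Write an editing-site table to TSV
#'
#' Writes sites with a stable on-disk contract: rows ordered by `gene_id` then
#' `pos`, header always present, and every column whose name contains
#' `fraction` formatted with 4 decimals.
#'
#' @param sites Site tibble (any column set including `gene_id` and `pos`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_site_table <- function(sites, path) {
  sites <- as_tibble(sites)
  if (nrow(sites)) sites <- arrange(sites, .data$gene_id, .data$pos)
  frac_cols <- grep("fraction", names(sites), value = TRUE)
  for (col in frac_cols) {
    sites[[col]] <- ifelse(is.na(sites[[col]]), NA_character_,
                           sprintf("%.4f", sites[[col]]))
  }
  readr::write_tsv(sites, path, na = "NA")
  invisible(path)
}

#' Read an editing-site table written by [write_site_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble; `*fraction*` columns converted back to numeric.
#' @export
read_site_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  for (col in grep("fraction", names(tab), value = TRUE)) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab
}

#' Export sites as a minimal VCF 4.2 file
#'
#' Coordinates are gene-space (gene id as CHROM, 1-based position along the
#' unspliced gene), not genomic; the header says so.
#'
#' @param sites Site tibble with `gene_id`, `pos`, `ref`, `alt`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(sites, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=gene-space (unspliced sense-strand gene sequences; POS is not genomic)",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  sites <- arrange(as_tibble(sites), .data$gene_id, .data$pos)
  body <- if (nrow(sites)) {
    paste(sites$gene_id, sites$pos, ".", sites$ref, sites$alt, ".", "PASS",
          ".", sep = "\t")
  } else {
    character(0)
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}
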