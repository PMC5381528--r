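#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gap costs, used to decide
#' whether edited residues in two orthologous proteins fall at the same
#' alignment position. Scoring defaults to BLOSUM62 with gap open 10 and gap
#' extend 1 (a gap of length L costs `gap_open + L * gap_extend`).
#'
#' @param a,b Non-empty amino-acid strings (20 residues plus `*`).
#' @param matrix Either the name of a Biostrings scoring matrix
#'   (e.g. `"BLOSUM62"`) or a named square numeric matrix.
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return An object of class `protein_alignment`: list with `a`, `b`,
#'   `aligned_a`, `aligned_b` (gapped strings of equal length) and `score`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  submat <- if (is.character(matrix)) {
    get(data(list = matrix, package = "Biostrings",
             envir = environment()))
  } else {
    matrix
  }
  alphabet <- rownames(submat)
  residues <- unique(strsplit(paste0(a, b), "")[[1]])
  bad <- setdiff(residues, alphabet)
  if (length(bad)) {
    abort(paste0("residue(s) not in scoring alphabet: ",
                 paste(bad, collapse = ", ")))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  structure(
    list(a = a, b = b,
         aligned_a = as.character(Biostrings::alignedPattern(pa)),
         aligned_b = as.character(Biostrings::alignedSubject(pa)),
         score = Biostrings::score(pa)),
    class = "protein_alignment"
  )
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("Global protein alignment (score ", x$score, ")\n", sep = "")
  cat("  a: ", x$aligned_a, "\n  b: ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Map a residue position through an alignment
#'
#' Given a global alignment and a 1-based residue index in sequence `a`,
#' returns the index of the residue of `b` aligned to it, or `NA` when it is
#' aligned to a gap.
#'
#' @param alignment A `protein_alignment` from [global_align()].
#' @param pos_a Residue index in the unaligned `a` (vectorized).
#' @return Integer vector of residue indices in `b` (`NA` = gap).
#' @export
map_aligned_position <- function(alignment, pos_a) {
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  cum_a <- cumsum(ca != "-")
  cum_b <- cumsum(cb != "-")
  n_a <- cum_a[length(cum_a)]
  if (any(pos_a < 1 | pos_a > n_a)) {
    abort("pos_a outside sequence a")
  }
  col <- match(pos_a, cum_a) # first column where cum_a reaches pos_a = its column
  out <- ifelse(cb[col] == "-", NA_integer_, cum_b[col])
  as.integer(out)
}
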