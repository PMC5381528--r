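#' Classify a substitution into one of the 12 ordered types
#'
#' Returns the ordered `ref -> alt` pair label ("AG", "TC", ...). Because
#' sites live in gene space on the sense strand, no strand collapsing is
#' applied: "AG" is the direct A-to-I editing candidate and "TC" stays a
#' distinct type.
#'
#' @param ref,alt Character vectors of single bases (A/C/G/T); `ref != alt`
#'   elementwise.
#' @return Character vector of type labels.
#' @export
substitution_type <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (!all(ref %in% BASES) || !all(alt %in% BASES)) {
    abort("ref and alt must be single bases A/C/G/T")
  }
  if (any(ref == alt)) {
    abort("ref and alt must differ")
  }
  paste0(ref, alt)
}

#' Substitution spectrum of a site set
#'
#' Counts sites in each of the 12 ordered substitution types (all types
#' always present, zero-filled) and attaches the per-million-covered-bases
#' rate and the within-spectrum fraction of each type.
#'
#' @param sites Site tibble with `ref` and `alt` columns (typically
#'   reproducible sites; pass per-replicate calls for a single-replicate
#'   spectrum).
#' @param covered_bases Covered-base denominator; must be positive when there
#'   are sites.
#' @param condition Optional condition label carried into the output.
#' @return Tibble with 12 rows: `condition`, `type`, `count`, `per_million`,
#'   `fraction`. Fractions are `NA` when the spectrum is empty.
#' @export
spectrum <- function(sites, covered_bases, condition = NA_character_) {
  total <- nrow(sites)
  if (total > 0 && covered_bases <= 0) {
    abort("covered_bases must be positive when sites are present")
  }
  counts <- if (total) {
    tab <- table(factor(substitution_type(sites$ref, sites$alt),
                        levels = SUBSTITUTION_TYPES))
    as.integer(tab)
  } else {
    integer(12)
  }
  tibble(
    condition = condition,
    type = SUBSTITUTION_TYPES,
    count = counts,
    per_million = if (covered_bases > 0) 1e6 * counts / covered_bases
                  else rep(NA_real_, 12),
    fraction = if (total > 0) counts / total else rep(NA_real_, 12)
  )
}
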