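## Coerce a clone table (data frame or matrix, one row per sequenced cDNA
## clone, one 0/1 column per editing site) to a binary matrix.
as_clone_matrix <- function(m) {
  mat <- as.matrix(m)
  storage.mode(mat) <- "integer"
  if (!nrow(mat)) abort("clone matrix needs at least one clone")
  if (!all(mat %in% c(0L, 1L))) abort("clone matrix must be 0/1")
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0("site", seq_len(ncol(mat)))
  }
  mat
}

#' Per-site editing frequencies across cDNA clones
#'
#' @param m Clone table: one row per sequenced cDNA clone, one 0/1 column per
#'   site (data frame or matrix).
#' @return Tibble with `site` and `frequency` (fraction of clones edited).
#' @export
site_frequencies <- function(m) {
  mat <- as_clone_matrix(m)
  tibble(site = colnames(mat), frequency = unname(colMeans(mat)))
}

#' Distribution of the number of edited sites per clone
#'
#' @param m Clone table (see [site_frequencies()]).
#' @return Tibble over `n_edited = 0..n_sites` with `count` and `fraction`
#'   (fractions of clones; sums to 1).
#' @export
edits_per_clone <- function(m) {
  mat <- as_clone_matrix(m)
  k <- ncol(mat)
  tab <- tabulate(rowSums(mat) + 1L, nbins = k + 1L)
  tibble(n_edited = 0:k, count = tab, fraction = tab / nrow(mat))
}

#' Poisson-binomial distribution of a sum of independent Bernoulli trials
#'
#' Exact probability mass of the number of successes across independent
#' trials with per-trial probabilities `p`, by the standard convolution
#' dynamic program.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @return Numeric vector of length `length(p) + 1` with the probabilities of
#'   0, 1, ..., length(p) successes.
#' @export
dpoisbinom <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  pmf <- 1
  for (pj in p) {
    pmf <- c(pmf * (1 - pj), 0) + c(0, pmf * pj)
  }
  pmf
}

#' Test edits-per-clone counts against an independence null
#'
#' Under the null that sites within a transcript are edited independently,
#' the number of edited sites per clone follows a Poisson-binomial
#' distribution with the observed per-site marginal frequencies. The
#' discrepancy statistic is the total-variation distance between the observed
#' edits-per-clone histogram and that expectation; its null distribution is
#' estimated by Monte Carlo, resampling matrices with independent sites at
#' the observed marginals. The p-value uses the `(r + 1) / (n_mc + 1)`
#' estimator, so it is never exactly zero. With `method = "patterns"` the
#' same machinery runs on the full joint 0/1 pattern distribution instead of
#' the histogram (only advisable when clones are plentiful).
#'
#' @param m Clone table (one row per clone, 0/1 per site; at least 2 sites).
#' @param n_mc Number of Monte-Carlo replicates (default 999).
#' @param seed Integer seed for the Monte-Carlo resampling.
#' @param method `"histogram"` (default; matches how clone co-editing is
#'   usually presented, and is the only defensible statistic at the 8-14
#'   clones of a typical experiment) or `"patterns"`.
#' @return An object of class `indep_fit`: observed and expected histograms,
#'   per-site marginals, the TV-distance statistic and the Monte-Carlo
#'   p-value. Methods: [tidy.indep_fit()], [glance.indep_fit()],
#'   [autoplot.indep_fit()].
#' @export
independence_fit <- function(m, n_mc = 999, seed = 1,
                             method = c("histogram", "patterns")) {
  method <- match.arg(method)
  if (n_mc < 1) abort("n_mc must be at least 1")
  mat <- as_clone_matrix(m)
  if (ncol(mat) < 2) abort("independence_fit needs at least 2 sites")
  n <- nrow(mat)
  k <- ncol(mat)
  marginals <- colMeans(mat)

  observed_stat <- function(mat) {
    if (method == "histogram") {
      obs <- tabulate(rowSums(mat) + 1L, nbins = k + 1L) / nrow(mat)
      sum(abs(obs - expected)) / 2
    } else {
      pat <- apply(mat, 1, paste, collapse = "")
      obs <- table(factor(pat, levels = all_patterns)) / nrow(mat)
      sum(abs(as.numeric(obs) - expected)) / 2
    }
  }

  if (method == "histogram") {
    expected <- dpoisbinom(marginals)
    all_patterns <- NULL
  } else {
    if (k > 16) abort("patterns method limited to 16 sites")
    grid <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
    all_patterns <- apply(grid, 1, paste, collapse = "")
    expected <- apply(grid, 1, function(z) {
      prod(ifelse(z == 1, marginals, 1 - marginals))
    })
  }

  stat <- observed_stat(mat)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  sim_stats <- vapply(seq_len(n_mc), function(i) {
    sim <- matrix(rbinom(n * k, 1L, rep(marginals, each = n)), nrow = n)
    observed_stat(sim)
  }, numeric(1))
  p_value <- (sum(sim_stats >= stat) + 1) / (n_mc + 1)

  obs_hist <- edits_per_clone(mat)
  structure(
    list(
      observed = obs_hist,
      expected = tibble(n_edited = 0:k, fraction = dpoisbinom(marginals)),
      marginals = site_frequencies(mat),
      n_clones = n, n_sites = k,
      method = method, statistic = stat, n_mc = n_mc, p_value = p_value
    ),
    class = "indep_fit"
  )
}

#' @export
print.indep_fit <- function(x, ...) {
  cat("Independence fit (", x$method, "): ", x$n_clones, " clones, ",
      x$n_sites, " sites\n", sep = "")
  cat("  TV distance = ", signif(x$statistic, 4),
      ", Monte-Carlo p = ", signif(x$p_value, 4),
      " (", x$n_mc, " replicates)\n", sep = "")
  invisible(x)
}

#' Tidy the observed vs expected edits-per-clone distributions
#'
#' @param x An `indep_fit` object.
#' @param ... Unused.
#' @return Long tibble: `n_edited`, `distribution` (observed/expected),
#'   `fraction`.
#' @export
tidy.indep_fit <- function(x, ...) {
  bind_rows(
    x$observed |> select("n_edited", "fraction") |>
      mutate(distribution = "observed"),
    x$expected |> mutate(distribution = "expected")
  ) |>
    select("n_edited", "distribution", "fraction")
}

#' One-row summary of an independence fit
#'
#' @param x An `indep_fit` object.
#' @param ... Unused.
#' @return Tibble: `n_clones`, `n_sites`, `method`, `statistic`, `n_mc`,
#'   `p_value`.
#' @export
glance.indep_fit <- function(x, ...) {
  tibble(n_clones = x$n_clones, n_sites = x$n_sites, method = x$method,
         statistic = x$statistic, n_mc = x$n_mc, p_value = x$p_value)
}

#' Compare clone editing between two timepoints
#'
#' Per-site difference of editing frequency (late minus early) plus the
#' difference in mean number of edited sites per clone; the rise of these
#' deltas across development is the penetrance signal.
#'
#' @param early,late Clone tables for the same gene with identical site
#'   columns.
#' @return Tibble with `site`, `freq_early`, `freq_late`, `delta`; the
#'   difference in mean edits per clone is attached as attribute
#'   `mean_edits_delta`.
#' @export
compare_timepoints <- function(early, late) {
  me <- as_clone_matrix(early)
  ml <- as_clone_matrix(late)
  if (ncol(me) != ncol(ml) || !all(colnames(me) == colnames(ml))) {
    abort("early and late clone tables must have identical site lists")
  }
  out <- tibble(
    site = colnames(me),
    freq_early = unname(colMeans(me)),
    freq_late = unname(colMeans(ml)),
    delta = unname(colMeans(ml) - colMeans(me))
  )
  attr(out, "mean_edits_delta") <- mean(rowSums(ml)) - mean(rowSums(me))
  out
}
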