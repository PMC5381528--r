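---
title: "Discovering A-to-I RNA editing from gene-space pileups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering A-to-I RNA editing from gene-space pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
library(dplyr)
```

## The problem and the coordinate system

A-to-I RNA editing deaminates adenosine to inosine in transcripts; reverse
transcription and sequencing read inosine as guanosine, so edited positions
appear as A→G mismatches between RNA-seq reads and the genomic template. In
several filamentous ascomycetes this editing is concentrated in sexual
structures (young fruiting bodies, sexually developing mycelium) and recodes
proteins, most dramatically by converting stop codons into amino-acid codons
so that translation reads through into sequence beyond the annotated stop.

`editscan` implements the discovery side of such a study: starting from
per-base pileups of RNA-seq reads mapped onto *gene-space* sequences — each
gene's unspliced, sense-strand sequence comprising its UTRs, exons and
introns — it detects candidate variant positions, keeps those reproducible in
two biological replicates, classifies the 12 possible substitution types and
their coding consequences, and provides the downstream comparative analyses
(cross-species conservation, per-transcript co-editing, expression
association).

Gene space rather than genome space is deliberate: mapping to the genome
would report A→G edits on reverse-strand genes as T→C, aliasing the one
substitution type the analysis cares about. All coordinates in the package
are 1-based and inclusive along the gene's sense strand.

## Detection model and thresholds

Variant detection is threshold-based, not likelihood-based, mirroring how
such screens are run in practice. For a single sample, a position is reported
by `call_variants()` when all of the following hold
(defaults in `detection_params()`):

* depth ≥ `min_depth` (default **5**; a value of 3 is appropriate for
  low-coverage data sets). Depth counts A/C/G/T calls only — `N` calls,
  deletion placeholders and reference skips in the pileup are excluded;
* exactly one alternative base reaches `min_alt_reads` (default **2**);
* that base accounts for at least `min_alt_fraction` of the depth
  (default **3%**);
* indel evidence at the position stays below `min_alt_reads` (positions with
  qualifying insertion/deletion support are vetoed);
* positions where two or more distinct alternative bases each reach
  `min_alt_reads` are discarded outright.

Two readings of "a single alternative base" are possible. The default
requires a *second* alternative to reach `min_alt_reads` before it voids the
position, so one stray error read does not disqualify a deeply covered site;
`strict_single_alt = TRUE` switches to the literal reading where any second
alternative read voids the position. A consequence worth knowing: the
`min_alt_reads` threshold is *not* monotone on multi-alternative columns —
raising it can disqualify the second alternative and thereby rescue a
position that was previously discarded, and it simultaneously relaxes the
indel veto. Depth and fraction thresholds are monotone in the expected
direction; the test suite pins all three behaviours.

Base qualities are ignored throughout: the pileup parser counts every call.
This is a documented deviation knob — quality-aware filtering would happen
upstream, inside the pileup generator.

### Replicates, normalization, specificity

Each condition has exactly two biological replicates. A site is
*reproducible* when the identical key (gene, position, reference base,
alternative base) passes detection in both (`intersect_replicates()`). Counts
are normalized to events per million *covered bases* — positions with depth
at or above the coverage threshold — with each replicate normalized by its
own covered bases and the intersection normalized by the mean of the two
(`summarize_condition()`). The reproducibility percentage is
`100 · both / mean(rep1, rep2)` on the normalized values; tables round to one
decimal for display while internal arithmetic stays unrounded.

A reproducible site is *condition-specific* when its key appears in no other
condition's reproducible set (`condition_specific()`). A stricter mode
(absent even from every other condition's single-replicate raw calls) is
available behind the `strict` flag.

Positions where one and the same alternative base is at ≥95% in **every**
sample that covers the position are flagged by
`flag_reference_discrepancies()` as likely genome-sequence errors or strain
differences and excluded from editing calls. Samples below the depth
threshold abstain rather than vote; this is the only testable reading of an
"all samples" rule when coverage varies.

## Coding consequences and stop-loss read-through

`classify_sites()` maps a site through its gene model: UTR, intron, or CDS
with the 1-based offset in the spliced CDS (introns excised, CDS segments
concatenated). CDS sites substitute the alternative base into the codon and
compare translations under the standard nuclear genetic code:
`synonymous`, `nonsynonymous`, `stop_loss` (a stop becomes an amino-acid
codon), `stop_retained` (a stop stays a stop, e.g. TAA→TAG), and
`stop_gain` — which A→G edits can never produce, a fact the suite proves by
exhaustive codon enumeration. `stop_retained` is counted among coding sites
but with the unchanged-product side of the binary product-change summary;
`consequence_summary()` exposes both conventions.

After a stop loss, `edited_protein()` continues translation in frame through
the *literal, unspliced* downstream gene sequence until the next stop or the
transcript end (flagged as an overrun). Annotation downstream of an annotated
stop is deliberately distrusted: the known fungal read-through cases sit in
regions mis-annotated as introns, so excising annotated introns there would
assume exactly what is in question.

## Cross-species comparison

`shared_editing()` takes an ortholog-pair table (with protein sequences) as
input — orthology inference itself is out of scope — and asks whether genes
edited in both species, filtered to amino-acid-changing sites edited in at
least 10% of observed transcripts (pooled over the two replicates: summed
alternative reads over summed depth), carry the *same* amino-acid change at
an *orthologous alignment position*. Position mapping uses optimal global
(Needleman–Wunsch) protein alignment with BLOSUM62 and affine gaps
(open 10, extend 1; a gap of length L costs `open + L·extend`), delegated to
`Biostrings::pairwiseAlignment()`. When several alignments tie for the
optimum the aligner's own tie-breaking is used; the package asserts score
optimality against brute-force enumeration rather than a particular
tie-break, since the shared-site verdict depends only on residue-to-residue
mapping at matched columns.

## Per-transcript co-editing

Sequencing 8–14 cDNA clones per sample turns each clone into a binary
editing-state vector over a gene's sites. Under the null that sites are
edited independently within a molecule, the number of edited sites per clone
follows a Poisson-binomial distribution at the observed per-site marginals,
computed exactly by convolution (`dpoisbinom()`, verified against `2^k`
enumeration). `independence_fit()` measures the total-variation distance
between the observed edits-per-clone histogram and that expectation and
calibrates it by Monte Carlo at the observed marginals, using the
`(r+1)/(n_mc+1)` estimator so p-values are never exactly zero. The histogram
(not the full joint pattern table) is the default statistic because clone
counts are tiny; the full-pattern variant exists behind `method = "patterns"`.
Two caveats are inherent and documented rather than hidden: the statistic is
discrete, so ties between simulated and observed TV values make the p-value
mildly conservative (null p-value means around 0.55–0.62 rather than 0.50 at
typical clone counts); and the experiment sizes the test is meant for have
little power — it formalizes a visual comparison, it does not replace one.

`compare_timepoints()` reports per-site and mean-edits-per-clone differences
between early and late developmental samples, the penetrance signal.

## Expression association

`assign_groups()` builds three nested gene groups: *any* putative editing
site; A-to-G sites *specific* to the focal condition; and *aa* —
focal-specific, amino-acid-changing, edited in ≥10% of transcripts.
`group_ratio_summary()` then summarizes per-gene expression ratios between
two conditions by group with type-7 quantiles (linear interpolation between
order statistics — a fixed, testable convention). Ratios are linear by
default with a pseudocount (default 1 abundance unit) guarding zero
denominators; `log2_ratio = TRUE` is available since either axis choice is
defensible. Expression values are taken as provided; upstream quantification
and normalization are out of scope.

## The synthetic study generator

`simulate_study()` produces every input the pipeline consumes, with known
ground truth, and is itself first-class, tested code. Its defaults *are* the
validation conditions used throughout the package:

* **50 genes** with 5′UTR (60–140 bases), CDS of 150–350 codons starting ATG
  and ending TAA/TAG/TGA with no internal stop, 0–2 introns of 50–90 bases at
  codon boundaries away from the CDS ends, and a 3′UTR (120–260 bases) so
  read-through has somewhere to go;
* three conditions (`veg`, `sex`, `proto`) × two replicates; per-base depth
  negative-binomial around **50×** (`size = 15`) modulated by a smooth
  sinusoidal positional profile (±20%), log-normal per-gene expression
  multipliers (sdlog 0.25) shared between replicates of a condition, and an
  optional 3′-bias ramp (off by default) emulating linearly amplified
  libraries;
* per-base sequencing error **0.5%**, strand-symmetric and uniform over the
  three wrong bases; no quality strings beyond a constant placeholder;
* **100 planted A-to-G sites**, all edited only in the focal condition —
  mirroring the empirical situation in which the large majority of A-to-G
  sites are specific to the sexually developing sample: 20 *tracked* sites at
  editing fractions 0.25–0.9, of which 5 sit on TGA/TAG stop codons to
  guarantee stop-loss cases, plus 80 *background* sites with fractions from
  0.03 (straddling the detection threshold — low-penetrance sites) to 0.7;
* **3 reference errors** at fixed alternative base in every sample, disjoint
  from the editing sites.

Randomness follows a single master seed with deterministic child seeds per
`(purpose, condition, replicate)`, so replicates differ only by seed
derivation and any sub-result is reproducible in isolation.

End-to-end validation on these defaults asks that the pipeline recover at
least 95% of planted sites whose focal editing fraction is ≥0.10 as
focal-specific reproducible sites, with at most 5% false discoveries among
the focal condition's reproducible calls after reference-error exclusion,
all reference errors flagged, planted consequence categories reproduced
exactly, and an A→G-dominated spectrum only in the edited condition. The
false-discovery denominator is the focal call set: at 0.5% error and 50×
coverage, error doublets reproduce in both replicates a handful of times
across half a million sampled positions, which is exactly the background the
screen is designed to tolerate. A second, editing-free configuration
(20 genes, 100×, 3% error) checks calibration: reproducible background calls
distribute across the 12 substitution types in proportion to the
reference-base composition (chi-square goodness of fit), and
independence-test p-values on independent clone sets are approximately
uniform.

What the generator does **not** emulate — and what passing these checks
therefore cannot certify — includes mapping and alignment artifacts
(multi-mapping, splice-junction errors, soft-clipping), base-quality
structure, PCR duplicates, strand-specific error profiles, real 3′-bias of
amplified libraries (available but off by default), and genuine biological
co-editing dependence along transcripts. Results on real pileups depend on
the upstream mapper in ways no pileup-level simulation can capture.

## Numerical and degenerate-input conventions

* Depth for thresholding and coverage is always recomputed as the sum of the
  four base counts; the pileup's own depth column is ignored.
* Zero-depth pileup columns (`* *`) parse to all-zero counts.
* Empty replicate call sets give zero normalized rates and an undefined
  (`NA`) reproducibility percentage; empty spectra have `NA` fractions.
* `pct_both` is bounded by 200 by construction and by 100 whenever the two
  replicates share a covered-base denominator.
* Site tables are written sorted by gene then position with fractions fixed
  to 4 decimals, so on-disk output is bit-stable.
* Monte-Carlo p-values use `(r+1)/(n_mc+1)`; quantiles are type 7; the
  genetic code is translation table 1.

## Problem sizes used in validation

The shipped test suite and the acceptance script run the generator at its
default scale (50 genes, ~60k gene-space positions, six samples) for the
recovery check, a 20-gene/100× configuration for null calibration, 1,000
random small gene models for the consequence-classifier cross-check, and
brute-force alignment enumeration on peptides of length ≤6. These sizes were
chosen so that every stochastic check has comfortable statistical margin
while the whole suite stays interactive.
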