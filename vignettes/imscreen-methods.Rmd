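---
title: "Methods: clonality-aware analysis of insertional mutagenesis screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality-aware analysis of insertional mutagenesis screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imscreen)
```

## The problem

Slow-transforming retroviruses such as the mouse mammary tumor virus (MMTV)
cause cancer by integrating into the host genome and deregulating nearby
genes. Sequencing the virus–host junctions of a tumor cohort gives, per
tumor, a catalog of insertion coordinates; regions hit in more tumors than
chance allows — common insertion sites (CIS) — mark selected driver loci.

Shear-ligation junction protocols add a second, quantitative layer. Tumor
DNA is sheared randomly to 100–1000 bp before adapter ligation, so every
cell contributes a junction fragment with its own shear coordinate, the
*ligation point* (LP). An insertion supported by *n* distinct LPs was
present in at least *n* independent cells. Within a tumor, the LP count is
therefore a relative clonality measure: insertions acquired early (or under
strong selection) are carried by most tumor cells and accumulate many LPs,
late or passenger insertions few. `imscreen` implements the analysis chain
that exploits this: background filtering by LP count, CIS detection,
CIS–CIS association testing, and clonality-based ordering of driver events
into a tumor-progression model.

## Insertion calling and the single-LP filter

Fragments from the same tumor, chromosome and proviral orientation whose
junction coordinates lie within `merge_window` of each other (default 5 bp,
absorbing alignment jitter; junctions are nominally base-exact) are
clustered into one insertion by single linkage. The LP count is the number
of distinct ligation points in the cluster; the read count is the cluster
size; the representative coordinate is the modal junction position, ties
broken toward the smaller coordinate. Orientation is part of the clustering
key because sense and antisense insertions at one locus are distinct
biological events.

Single-LP insertions cannot be distinguished from insertions present in a
single cell and are overwhelmingly background; `filter_single_lp()` removes
them. In a large MMTV screen this filter removes about three quarters of
insertion *sites* but only about a fifth of *reads*, which is the signature
of a background-dominated site list: `cohort_summary()` reports both
percentages. Headline reductions are reported as truncated integer
percentages (a 78.65% reduction prints as 78%), with exact values retained
in the same object; coverage-style percentages elsewhere in the package use
standard rounding. Tumors whose insertions are all single-LP drop out of
the post-filter cohort and are flagged; all downstream denominators use the
post-filter tumor set.

An optional cross-contamination filter (`filter_cross_contamination()`)
removes identical (chromosome, position, ligation point) triples that
appear in several tumors of one sequencing pool, keeping the
best-supported tumor — a standard barcode-bleed control for pooled runs. It
is an extension beyond the stated filtering chain and is off by default.

## CIS detection by Gaussian kernel convolution

Insertion coordinates, pooled across tumors and orientations, are smoothed
with an unnormalized Gaussian kernel of width $h$:
$$f(g) \;=\; \sum_i \exp\!\left(-\frac{(g - x_i)^2}{2h^2}\right),$$
evaluated on a regular grid with spacing $h/10$ (resolving peak positions
to within 5% of $h$) and hard-truncated at $|g - x_i| > 4h$. An isolated
insertion contributes exactly 1.0 at its own coordinate, so peak heights
read as effective insertion counts. Per-tumor multiplicity is *not*
collapsed: a tumor with three insertions in a window contributes three
kernels. This choice is configurable in spirit — the framework's original
handling is not fully specified — and its consequence (a single highly
re-hit tumor can inflate a peak) is mitigated by the tumor-support column
reported per CIS.

Significance is calibrated by permutation, per chromosome and scale: the
observed number of insertions is placed uniformly on the chromosome, the
maximum of the density track recorded, and the threshold set to the
empirical $1-\alpha$ quantile of the max-peak distribution over `n_perm`
permutations (default 1000). This controls the family-wise error of
reporting any CIS on a background-only chromosome at level $\alpha$ per
chromosome/scale, makes no distributional assumption, and is self-contained.
It is a re-implementation choice: no claim is made of bit-equivalence with
the original kernel-convolution tooling's calibration.

Detection runs at three scales by default (10 kb, 30 kb, 100 kb), spanning
the empirical width range of CISs (roughly 15–270 kb); regions from
different scales that overlap are merged into one CIS covering their union,
reporting the smallest contributing scale and its peak. Region boundaries
are the outermost grid points above threshold; peaks break ties toward the
smaller coordinate. Target genes are attached by an explicit
nearest-to-peak heuristic (`assign_target()`), recorded as such and never
presented as curation; distance ties break toward the gene with the smaller
start coordinate.

## Co-occurrence, mutual exclusivity and genotype association

The tumor × CIS incidence matrix stores, per cell, the maximum LP count of
the tumor's insertions in that CIS (0 = absent; presence is equivalent to a
score of at least 2 because only post-filter insertions enter). Each CIS
pair is tested with both one-sided Fisher exact tests on the 2×2 presence
table — enrichment (co-occurrence) and depletion (mutual exclusivity) — and
the smaller tail names the direction. The exact pairwise procedure of the
original analysis is not published in detail; one-sided Fisher testing is
the standard assumption-free reconstruction, and it reproduces the expected
power asymmetry (co-occurrence is detectable for rare insertions, mutual
exclusivity needs frequent ones). Benjamini–Hochberg correction runs across
the pooled set of both one-sided families, after excluding degenerate
margins, and edges with $q \le \alpha$ are kept with weight $-\log_{10} q$.

Family-level exclusivity (`family_pattern()`) compares the number of tumors
hitting two or more members of a gene family against a permutation null
that shuffles each member's presence column independently, preserving
marginal frequencies; the p-value is the add-one estimate of
$P(\text{overlap}_{\text{null}} \le \text{overlap}_{\text{obs}})$, slightly
conservative by construction.

Genotype/strain association (`genotype_association()`) compares matched
cohort arms (wild-type vs. mutant within a strain; wild-type vs. wild-type
across strains) per CIS with a two-sided Fisher exact test and BH
correction across CISs.

## Ordering driver events: the binomial progression model

CISs are pooled into gene families (plus singletons), and groups hit in
fewer than 10 tumors are dropped. For two groups and every tumor carrying
both, the group with the higher within-tumor clonality score (maximum LP
over member CISs; a sum variant is available) "wins". Ties are excluded, as
in a sign test; tie handling is not specified by the source analyses and
exclusion is the standard choice. Under the null that either group is
equally likely to be the more clonal one, the win count is
Binomial$(n, 1/2)$, and the reported p-value is the exact two-sided tail
$\min(1,\, 2\,P(X \ge \max(w_a, w_b)))$ — symmetric in the two groups, and
equal to the familiar doubling of the one-sided tail. A one-sided mode
exists, since whether the original test was one- or two-sided is not
stated; two-sided is the conservative default. Comparisons with
$p \le 0.05$ become directed edges from the more frequently clonal (earlier)
group; no multiple-testing correction is applied by default, matching the
displayed-significance convention of this analysis style (a BH option
exists). The resulting graph's acyclicity is checked and reported, not
enforced. LP scores are only ever compared within a tumor — clonality is a
relative, per-tumor quantity, and copy-number effects on LP counts are
acknowledged but not modeled.

## The synthetic cohort: a stated world

`simulate_cohort()` generates fragment-level screens with planted ground
truth so every stage is testable without external sequencing data. The
default configuration emulates a large MMTV mammary-tumor screen:

* **604 tumors** in four genotype/strain arms (FVB wild-type 265, FVB
  *Pten*-mutant 200, BALB/c wild-type 80, BALB/c *Trp53*-mutant 59 —
  expected counts, drawn multinomially).
* **30 planted loci** on a 6 × 100 Mb genome: five gene families (Wnt,
  Fgf, Fgfr, Rspo, Pdgfr) whose member hit probabilities span ~45% down to
  ~1% of tumors, plus 13 singleton loci, mirroring the frequency spectrum
  of published CIS tables. Insertions scatter around each locus center
  with a Gaussian spread (2.5–34 kb, wider for hotter loci); the truth
  window is center ± 4 spreads.
* **Family exclusivity**: a family is hit with the summed member
  probability and contributes exactly one member per tumor, giving the
  within-family mutually exclusive pattern; the per-locus marginal equals
  its configured hit probability.
* **Planted order**: hit families are ranked by a fixed early→late order
  (Wnt and Fgf first); the event at rank $r$ has clonal fraction
  $c_r = 1, 0.5, 0.25, 0.125, 0.0625$ (later ranks reuse the last value)
  and LP count $1 + \mathrm{Poisson}(D\,c_r - 1)$ with full-clonality depth
  $D = 40$. The 2× gap between consecutive ranks is what makes direction
  recovery testable.
* **Background**: Poisson(49) insertions per tumor, uniform on the genome,
  with LP $\sim 1 + \mathrm{Geometric}(0.8)$, so ~80% are single-LP — this
  reproduces the observed asymmetry that the single-LP filter removes
  ~78% of sites but a much smaller share of reads.
* **Fragments**: an insertion with LP count $k$ emits $k$ fragments with
  one junction coordinate and $k$ distinct shear offsets drawn without
  replacement from 100–1000 bp, on the side opposite the viral junction
  (flipped near chromosome ends). One global seed drives every draw;
  identical configurations are byte-identical.

The per-tumor number of driver events is the Poisson–binomial total implied
by the per-locus hit probabilities (mean ≈ 1.8 with the defaults) rather
than an independent dial; the invariant that each locus's hit frequency
converges to its configured probability forces this parametrization.
The empirical LP-count distributions of real screens are not published;
the Poisson/geometric choices above are documented stand-ins, configurable
through `lp_depth`, `clonal_fraction_by_rank` and the background model.

What the generator does *not* emulate: read-level duplication (reads equal
LPs here, so read-reduction percentages run higher than in real data, where
clonal insertions carry many duplicate reads per LP), mapping noise and
multi-mapping artifacts, chromatin-driven integration bias, copy-number
alteration of LP counts, and barcode bleed between pooled tumors (available
separately through the contamination filter). A green planted-recovery test
therefore establishes correctness of the *inference chain*, not robustness
to every artifact of real sequencing data.

## Numerical choices and degenerate inputs

* Coordinates are 1-based throughout; CIS intervals are inclusive; BED
  exports convert to 0-based half-open.
* The kernel is truncated at $4h$ exactly; the brute-force oracle in the
  test suite uses the same definition, and the truncation error
  (≈ $3 \times 10^{-4}$ per kernel at the cut) is irrelevant at the
  thresholds involved.
* Threshold quantiles use the empirical (type-1) quantile, making the
  $\alpha \to 1$ limit the minimum observed max-peak and the threshold
  monotone in $\alpha$.
* Per-chromosome/scale permutation seeds derive deterministically from the
  top-level seed and stay below $2^{31}$.
* Degenerate cases: empty fragment sets call to empty insertion tables;
  empty insertion sets yield empty CIS tables; association margins of 0 or
  all tumors are reported untestable and excluded before BH; group pairs
  never co-mutated are untestable in the progression model; an empty
  pre-filter cohort reports `NA` reduction percentages.
* The density hot loop (track accumulation and the permutation null) is
  the package's only compiled code.

## Limitations

The permutation null assumes uniform background integration within a
chromosome; real integration bias (e.g. toward transcription start sites)
would inflate CIS calls near generally-favored regions. The nearest-gene
heuristic is a stand-in for curation and can mis-assign targets in dense
or nested loci. The progression model orders groups by within-tumor
clonality and cannot distinguish "earlier" from "equally early but more
strongly selected"; both produce consistently higher clonality.
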