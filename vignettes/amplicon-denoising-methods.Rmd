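---
title: "Methods: long-read amplicon denoising with ampdenoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read amplicon denoising with ampdenoise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A PCR-amplified region is sequenced with long circular-consensus (CCS)
reads. The sample contains a small number of true *templates* — closely
related variants, possibly one substitution apart — at unknown
frequencies, and every read is a corrupted copy of one template.
Denoising means recovering the template sequences and their frequencies
from the reads alone.

Two regimes call for two different strategies:

* **Short/accurate** (e.g. 2–3 kb CCS at Q20+): an appreciable fraction
  of reads is error free, so true templates literally appear among the
  reads. The right move is to *select* reads, never to average them —
  `fad_denoise()`.
* **Long/inaccurate** (longer amplicons, ~1% error): essentially no
  read is error free. Templates must be reconstructed by *clustering
  reads and computing consensus sequences* — `rad_denoise()`.

`ampdenoise` implements both, plus the Sequence Mutation Distance
(`smd()`) for scoring a reconstruction against a known truth, and a
CCS-style read simulator (`simulate_reads()`, `mvc_fixture()`) so every
claim in this vignette is checkable without external data.

## The kmer representation

All clustering and neighbour detection happens on kmer count vectors
(`kmer_vector()`, default k = 6), not on alignments. The *corrected
kmer distance* between sequences A and B is

> D(A, B) = (1/2k) · Σᵢ (Aᵢ − Bᵢ)²

where the sum runs over all 4ᵏ kmer counts. The 1/(2k) factor makes the
distance read in *base equivalents*: one substitution in non-repetitive
context destroys k windows and creates k new ones, changing 2k counts by
one each, so D = 1. For well-spaced substitutions D tracks the edit
distance within a few percent while costing a fraction of an alignment;
for indels it is a lower bound (a one-base indel shifts frames and
typically perturbs fewer unique windows). `scaled_distance()` divides by
the mean sequence length, giving a per-base quantity comparable to an
error *rate* — this is the metric the coarse clustering uses.

## Fast denoising (read selection)

`fad_denoise()`:

1. **Filter** reads by expected error rate (`filter_by_error_rate()`,
   threshold 0.01 by default at the CLI). Expected errors are the sum of
   Phred-implied per-base error probabilities.
2. **Dereplicate** (`dereplicate()`) and drop sequences seen fewer than
   `min_count = 2` times: a sequence seen once carries no evidence of
   being error free.
3. **Abundance correction.** The observed count of an error-free
   sequence under-reports its template's true abundance by the
   *error-free fraction* f₀ = mean over reads of exp(−E)
   (`error_free_fraction()`); dividing by f₀ undoes this.
4. **Walk candidates by decreasing abundance.** A candidate at corrected
   kmer distance ≥ 1 base equivalent from every accepted template is a
   new template. A candidate *within* that radius of an accepted
   template is kept only if the Poisson test (`offspring_pvalue()`)
   rejects the hypothesis that its count is explained by reads of the
   (corrected-abundance) parent all hitting one error site: with mean
   per-read errors Ē over mean length L̄, the one-site expectation is
   μ = (parent/f₀)·Ē/L̄, and the upper-tail p-value is
   Bonferroni-corrected by the L̄ sites at which such an offspring could
   arise. Significance level `alpha = 0.01`.
5. **Assign** every read to its nearest accepted template
   (`assign_to_templates()`) and report frequencies.

The output templates are verbatim input reads — selection, not
averaging — which is what makes single-substitution variants
recoverable at this regime's error rates.

## Robust denoising (cluster and average)

`rad_denoise()` is a three-stage pipeline.

**Coarse clustering.** `coarse_cluster()` runs DP-means over the scaled
kmer distance. DP-means (`dp_means()`) is the deterministic
small-variance limit of a Dirichlet-process mixture: a point farther
than the radius λ from every centroid seeds a new cluster, so λ — not a
preset k — controls cluster count. The default `coarse_radius = 0.01`
matches 1%-expected-error filtered reads. **The radius must exceed the
per-read noise level**: at a raw per-base error rate ε, a read sits
about 0.8·ε scaled distance from its own template (indel errors perturb
fewer counts than substitutions), so for unfiltered ~1%-error data the
coarse radius should be raised to about 2ε (0.02) or the clustering
shatters into per-read fragments. `dp_means_pruned()` is an exact
drop-in that uses meta-centroids and the triangle inequality in the
Euclidean kmer domain to skip provably useless distance evaluations; the
test suite asserts bitwise-identical assignments.

**Fine splitting.** Coarse clusters can still mix templates a few bases
apart. `split_once()` projects a cluster onto its `N = 6`
highest-variance kmer columns (out of a pool of `M = 20`;
`top_variance_kmers()`), runs Euclidean DP-means with
`split_radius = 1` there, and keeps a candidate sub-cluster only when
the same Poisson test (with f₀ = 1 — cluster sizes already count every
noisy read, so no error-free correction applies) says it is too big to
be error fallout from the largest sub-cluster. Non-significant
fragments are reabsorbed into the nearest significant sub-cluster, so a
good split is never vetoed by stray noise fragments, and error-driven
shattering never survives. `refine()` recurses until no split is
accepted.

Two filters protect the projection from the dominant CCS error mode,
homopolymer-length indels: pooled kmer pairs related by a one-unit
homopolymer length change are both dropped
(`homopolymer_length_edit_pair()`), and any pooled kmer *containing* a
run of identical bases is dropped outright, because the
anti-correlated partner column of an indel-perturbed kmer frequently
falls outside the top-M pool where the pairwise rule cannot see it. The
cost of this robustness is a documented blind spot: a substitution
whose entire kmer neighbourhood is homopolymeric is indistinguishable
from a homopolymer length error at the kmer level, and the splitter
will not separate it.

Clusters smaller than `min_cluster = 5` are dropped before consensus:
in the long/inaccurate regime individual reads can drift beyond the
coarse radius from every centroid, and reporting such strays would
fabricate low-frequency templates.

**Consensus.** `cluster_consensus()` picks the member read nearest the
cluster's mean kmer vector as a draft (`draft_consensus()`), aligns
every member to it with a seeded aligner (`seeded_align()`: unique
shared 30-mers chained by longest increasing subsequence, exact
unit-cost alignment only in the short inter-anchor gaps — linear time in
practice), and polishes the draft in 15-column blocks by replacing each
block with the modal aligned read subsequence (`polish()`), re-aligning
between sweeps, up to 3 rounds. With independent errors and coverage of
a few dozen, the modal vote recovers the template essentially always;
the acceptance suite demands ≥ 99 exact recoveries in 100 seeded
50-read clusters at ~1% error.

## Scoring reconstructions

`smd(truth, inferred)` solves the transportation problem over the
pairwise edit distance matrix of two weighted populations: the minimum
frequency-weighted number of edits per sequence needed to turn the truth
into the reconstruction (an earth mover's distance). It reads directly
as "average bases wrong per reported sequence". The one-sided
relaxations `smd_fp` (truth marginal dropped; grows with spurious
templates) and `smd_fn` (inferred marginal dropped; grows with missed
templates) localise the failure mode and have closed forms — each
sequence's mass goes to its nearest counterpart. The solver is an exact
successive-shortest-path min-cost flow; tests pin it against a dense
simplex oracle.

## The simulator

`simulate_reads()` models the two CCS error channels separately:
uniform per-base substitutions at `sub_rate`, and homopolymer-length
indels — each run of r ≥ 2 identical bases gains or loses one unit with
probability min(1, `indel_base_rate` · r). Isolated bases receive no
indels: a uniform indel model would place errors where no homopolymer
filter can be expected to absorb them, which mismatches the error
process those filters are built for. Quality strings are constant-Q per
read, with Q matched to the profile's expected per-base error rate, so
quality-derived expected errors agree with the realised edit distances
(tested to within 15%). `mvc_fixture()` packages three canned
communities — `low_error` (20 templates, read-selection regime),
`high_error` (10 diverged templates at ~1% error, clustering regime),
and `single_base_pair` (two templates one substitution apart, variant
placed in homopolymer-free context for the reason given above).

## Limitations

* Kmer distances undercount indels; all radii are calibrated for
  substitution-dominated divergence between *templates* (indel noise is
  handled by the homopolymer filters instead).
* The splitter cannot separate variants that differ only inside
  homopolymer context, by construction.
* DP-means is order-dependent; reproducibility comes from fixed read
  order, and frequencies of near-tied assignments can shift under
  permutation.
* The coarse radius must be chosen against the post-filter error rate;
  there is no auto-calibration.
* The simulator draws one candidate indel per run and constant-Q
  qualities; it is a model of the error *structure*, not of any
  instrument's full noise spectrum.
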