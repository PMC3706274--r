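---
title: "Consensus differential expression across replicate pairs and TF profile comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus differential expression across replicate pairs and TF profile comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repcons)
```

## The problem

Recombinant *S. cerevisiae* strains engineered with a fungal xylose
pathway (XR/XDH/XKS) show host dependence: the same pathway performs
differently in different host strains. Characterizing the transcriptional
side of that effect from bulk RNA-seq runs into a practical obstacle:
when biological replicates are extremely well correlated overall but a
count-model caller is run on pooled replicates, genuine but modest
condition effects can vanish entirely — no transcript is called. The
design implemented here sidesteps pooled dispersion estimation by going
qualitative: run the pairwise caller on **every** control-replicate ×
experiment-replicate combination (nine comparisons for a 3 vs 3 design)
and keep only features whose call is consistent in at least *n* of those
comparisons.

`repcons` implements that consensus criterion, plus the downstream
interpretation layers: transcription-factor (TF) profiles of the selected
gene sets, unit-normalized profile comparison by Euclidean distance
against reference profiles, conserved-TF intersection across conditions,
GO-slim summarization, and percent/fold-change arithmetic over strain
physiology tables.

## The consensus model

Let the control condition have replicates $c_1,\dots,c_{R_c}$ and the
experimental condition $e_1,\dots,e_{R_e}$. Each ordered pair
$(c_i, e_j)$ is passed to a pairwise caller that emits, per feature, a
log2 fold change, a significance decision, and a direction ("up" always
means increased in the experimental group). For feature $g$,

$$ n_{up}(g) = \#\{(i,j): \text{called up}\},\quad
   n_{down}(g) = \#\{(i,j): \text{called down}\},\quad
   \mathrm{support}(g) = n_{up} + n_{down}. $$

Under the default **unanimous** rule, $g$ is selected at cut-off $n$ iff
one direction has at least $n$ calls *and the opposite direction has
none*. This is the strictest reading of "consistent behavior across
comparisons", and at the default $n = R_cR_e = 9$ it coincides with the
looser reading (a single direction reaching $n$). For smaller cut-offs
the two readings differ; the looser count-based rule is available as
`direction_rule = "count"`. Selected sets are non-increasing in $n$ —
lower cut-offs always pick more transcripts.

Two caller routes exist:

* `read_cuffdiff_diff()` ingests real Cuffdiff 2.x `.diff` tables; a
  record is significant iff the file's `significant == yes` **and**
  `p_value <= alpha` (default 0.05). Whether significance should come
  from the p-value, the q-value, or the flag alone is not determined by
  convention, so the conjunction is an explicit, configurable choice.
* `fold_change_caller()` is the built-in, deliberately simple
  deterministic stand-in: per feature it thresholds the pseudocounted
  fold change $\log_2\!\frac{v_e + \varepsilon}{v_c + \varepsilon}$ at
  `min_abs_log2fc` (default 1). The pseudocount $\varepsilon$ (default
  1 FPKM) shrinks fold changes of barely expressed features toward zero.
  Its p-values are placeholders (0/1); it is documented as a
  simplification, not a statistical model — the consensus logic is
  caller-agnostic, and users reproducing a Cuffdiff-based analysis feed
  nine `.diff` files instead.

## TF profiles and distances

For a selected gene set $D$ and a regulation table of documented
TF→target edges, each TF's score is $|targets(TF) \cap D|$ and its
fraction is that count divided by $|D|$ — the **full** differential set,
including genes no TF regulates. The profile keeps the top $K = 20$ TFs
by count (ties broken lexicographically so output is deterministic); TFs
regulating no selected gene never appear. Only documented (direct or
indirect) evidence is used by default, which avoids profiles dominated by
general TFs predicted to touch most of the genome.

To compare two profiles they are placed on the lexicographically sorted
union of their TF names (absent TFs get 0) and each vector is rescaled to
unit Euclidean length. The distance is then plain Euclidean:
$d = \sqrt{\sum_i (s_i - r_i)^2}$. For nonnegative unit vectors
$d \in [0, \sqrt2]$, with 0 iff the profiles are identical and $\sqrt2$
iff their supports are disjoint. Two choices here were genuinely open:

* **The norm.** The normalization formula in the source methods text is
  typographically garbled, so the norm had to be chosen. L2 is the
  default because the downstream comparison is Euclidean distance — unit
  L2 vectors make $d$ scale-free and bounded by $\sqrt2$. L1 is
  available (`norm = "l1"`).
* **The axis.** Nothing fixes how profiles over different TF sets are
  aligned. The union-of-top-K axis, zero-filled, is the default because
  it uses exactly the reported profile content and needs no external TF
  universe; distances over a fixed axis can be had by building both
  profiles from the same regulation table with a large $K$.

Conserved regulators across comparisons are simply the intersection of
the top-$K$ TF name sets — order-independent and idempotent. Reference
profiles are built identically from the first `n_ref_genes = 250` genes
of an externally ranked differential list.

## GO summarization and physiology arithmetic

`summarize_go()` groups each comparison's selected genes under every GO
slim term they map to: a gene with $m$ terms is listed under all $m$
rows but contributes once to the per-direction totals; unmapped genes go
to an explicit "un-identified" bucket. The mapping is a flat user-supplied
file — no ontology traversal, which keeps the stage deterministic and
offline. No enrichment statistics are computed: the readout is membership
lists and counts.

`percent_change()` reports $100\,(new - ref)/ref$ both unrounded and
rounded to whole percents with halves away from zero, matching how such
changes are conventionally reported; `fold_change()` is the plain ratio.
The packaged strain physiology table stores printed point values with
their ± uncertainties verbatim; uncertainties are carried but not
propagated. Note that changes recomputed from rounded table values can
differ by a point or two from values quoted from unrounded data — e.g.
the table's uptake-rate changes of +96% and −20% for the INV-host
optimization and the INVp pathway switch.

## The synthetic generator

No raw sequencing data accompanies the original study, so the generator
is a first-class module that emulates the statistical structure the
analysis assumes, with ground truth for recovery testing:

* **Expression** (`simulate_expression()`): per gene, log2 FPKM =
  baseline + condition shift + replicate noise, all normal on the log2
  scale (lognormal multiplicative noise on FPKM — the pipeline consumes
  FPKM, not counts, so no count-level model is attempted). Defaults are
  the study conditions: 6000 genes, 3 replicates per condition, baseline
  $\log_2 \mathrm{FPKM} \sim N(5, 2)$, noise sd 0.12, 100 planted DE
  genes at $|\log_2 FC| = 2$ with random sign. The noise sd was
  calibrated analytically to the reported inter-replicate correlation:
  with baseline variance $\sigma_b^2 = 4$ the expected within-condition
  log2 correlation is $\sigma_b^2/(\sigma_b^2 + \sigma_n^2) =
  4/4.0144 \approx 0.9964$, matching the ~0.996 that carefully
  controlled replicate cultures reach.
* **Regulation** (`simulate_regulation()`): each of `n_tfs = 50` TFs
  gets a uniformly sized random target set (20–80 genes); the planted
  conserved TFs additionally target a fraction `enrichment = 0.5` of the
  planted DE genes, with their random targets drawn outside that planted
  set so edge counts are exact. All edges are `documented-direct`.
* **Reference ranking** (`simulate_reference_ranking()`): gene score =
  effect × 1{planted} + $N(0, 0.5)$, ranked descending. The noise sd
  0.5 comes from a normal-tail calculation: with a 2-unit planted bonus,
  essentially all 100 planted genes sit above the ~250th score among
  6000, so the head is DE-dominated yet noisily ordered. At sd 0 the
  planted genes sort strictly first; with no planted genes the ranking
  is a uniform permutation.

One integer seed drives everything; `simulate_study()` derives per-stage
sub-seeds deterministically, so identical seeds give bit-identical
bundles. The planted effect size is a free parameter, not an estimate —
no effect-size distribution for real DE genes is available to fit.

**What passing recovery tests do and do not show.** The generator
reproduces the features the consensus criterion is sensitive to —
replicate correlation, planted direction-consistent shifts, a bipartite
regulation structure with planted conserved regulators. It deliberately
omits read-level noise, GC/length bias, library-size variation,
isoform ambiguity, and correlated (batch) replicate structure. Recovery
of planted truth therefore validates the *logic* of the pipeline, not
the error rates to expect on real libraries.

## Numerical and degenerate-input choices

* FPKM values must be nonnegative; p-values in $[0, 1]$; violations are
  classed errors (`repcons_value_error`, `repcons_format_error`,
  `repcons_design_error`, `repcons_config_error`, `repcons_input_error`)
  so callers can discriminate.
* A zero log2 fold change never carries a direction, even if flagged
  significant upstream; direction is "none" iff not significant.
* An empty differential set has undefined profile fractions and is an
  input error; pairs whose consensus selects nothing are skipped in the
  conserved intersection and the distance table rather than aborting the
  run.
* Normalized-profile construction asserts a nonzero vector (guaranteed
  for nonempty profiles) and unit norm to 1e-9.
* Consensus output is sorted by support descending then feature id;
  profile ties break lexicographically — all reports are byte-stable
  under rerun.

## Problem sizes used in the shipped checks

The test suite exercises the full study conditions (6000 genes, 3 vs 3,
cut-off 9) for the recovery checks and smaller instances elsewhere:
consensus-versus-enumeration equivalence on 200 randomized instances of
up to 5 features and 3+3 replicates, monotonicity on 50 random
9-table instances, profile geometry on 1000 random profile pairs (300
triples for the triangle inequality), and a 600-gene, 2-pair pipeline
smoke/determinism run. These sizes were chosen as the smallest that
exercise every code path convincingly.

## Limitations

* The built-in caller is a threshold on shrunken fold change, not a
  count model; its consensus behavior matches a statistical caller only
  insofar as per-pair decisions do.
* Transcript→gene collapsing is the user's responsibility (feature ids
  are opaque strings); apply a mapping before the TF/GO stages or the
  ids are treated as gene ids.
* No TF-enrichment p-values: profiles rank by raw regulated-gene counts,
  so heavily annotated TFs are favored — mitigated only by the
  documented-evidence filter.
* GO summaries are membership tables, not enrichment tests.
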