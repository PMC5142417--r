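---
title: "Methods: decay-curve classification and termination-codon feature screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decay-curve classification and termination-codon feature screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nmdscreen)
```

This vignette is the package's own account of its models and of the
design choices that were genuinely open. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The measurement model

The input is a replicated pulse-chase experiment: labelled RNA abundance
per transcript in two conditions (control, decay-factor knockdown), two
biological replicates each, at 0, 4, 8 and 12 hours. Abundances are on
a normalized expression scale (FPKM-like), conventionally rescaled to a
stable housekeeping transcript per sample
(`normalize_to_reference()`); the simulator reserves the id
`REF_STABLE` for that anchor.

With only two replicates no proper per-transcript variance can be
estimated. The package follows the error-propagation approximation:
a replicate pair is a mean with standard error $|x_1 - x_2|/\sqrt 2$,
and each contrast $d$ (decay contrast $\tau$ or $\varphi$: time $t$
versus 4 h within a condition; condition contrast $\delta$: control
minus knockdown at $t$) carries the propagated error
$\Delta d = \sqrt{(a_1-a_2)^2 + (b_1-b_2)^2}/\sqrt 2$, with normal-tail
p-values of $z = d/\Delta d$. The 0 h point is ingested for curve
inspection but enters no statistic: labelling and immunoprecipitation
artefacts make the earliest interval the least comparable, and all
contrasts are anchored at 4 h.

**The z statistic is approximate.** Under a Gaussian replicate model
$z$ is a ratio of a normal to an independent scaled chi with two
degrees of freedom ($z \sim t_2/\sqrt 2$), not standard normal. The raw
p-values therefore deviate from exact uniformity under the null by a
bounded amount (Kolmogorov distance about 0.05, slightly
anti-conservative in the far tails). The test suite asserts this bound
rather than exact uniformity. In practice the classification does not
rest on the p-value alone: the replicate-separation clause below and
the per-time-point Benjamini–Hochberg correction keep false affected
calls at or below 1% under the simulator's study conditions
(measured, not assumed — see `test-acceptance.R`).

**Degenerate errors.** When $\Delta d = 0$ (identical replicates),
$z$ is defined as $\pm\infty$ for $d \gtrless 0$ and 0 for $d = 0$, the
limit behaviour of the normal tail; noise-free simulations thus remain
classifiable.

## Classification

Transcripts whose curves fail to decay (corrected one-sided p of
$\tau$ or $\varphi$ below alpha at 8 or 12 h) are removed before
classification. A transcript is stabilized when, at *every* evaluated
time point (8 and 12 h; the strict criterion adds 4 h), the corrected
left-tail p of $\delta$ is at most alpha *and* all knockdown replicates
exceed all control replicates; destabilized is the mirror; unaffected
requires both tails non-significant everywhere; the remainder —
transcripts with inconsistent behaviour across time points — is
unclassified, defined simply as the complement of the three classes.
The min/max separation clause is quantified over all evaluated times,
and we apply the same quantification to the p-value clause for
symmetry. FDR correction is Benjamini–Hochberg, applied separately per
statistic family and per time point across transcripts — the standard
reading of an otherwise unspecified "FDR-corrected".

The two-sided structure of the rules makes the procedure exactly
antisymmetric: relabelling the conditions maps every stabilized call to
a destabilized one and vice versa, bit for bit. This is asserted
exactly in the tests (the implementation computes both tails as
`pnorm(z)` and `pnorm(-z)` so the swap is numerically exact).

**Stability change.** $S_i$ is the median over 4/8/12 h of the
per-time condition contrast. The underlying $\delta$ is
control-minus-knockdown, under which stabilized transcripts would have
*negative* values while the tertile language ("larger change") suggests
the opposite ordering; we therefore report $S$ with the
knockdown-minus-control sign (positive = stabilized) and form tertiles
on $|S|$. Tertile bounds use linear-interpolation percentiles at 0.33
and 0.66 with both boundary rules inclusive; under heavy ties the two
inclusive rules can overlap, and the *small* rule takes precedence (a
degenerate cohort is then all-small rather than all-large — the
conservative direction for "large stability change" claims).

## The feature catalog

63 features per transcript; the accounting is
$4\ \text{binary} + 2\ \text{lengths} + 1\ \text{ALU density} +
2 \times (4 + 16 + 4 + 4)$ over the two sequence windows. Choices the
definitions leave open:

- **CDS-end window.** "Last 20 bases of the CDS" includes the stop
  codon, following the RefSeq convention that a CDS ends with it; a CDS
  shorter than 20 bases contributes its whole sequence.
- **Dinucleotides** are counted over overlapping windows with
  denominator $L - 1$.
- **Run binning.** Maximal runs of length ≥ 3 are binned at their exact
  length up to 7; longer runs fall into the 7-bin so no observed run is
  discarded. The expectation model $E_m = \delta^m(1-\delta)^2 l$ keeps
  exact-length probabilities also at the boundary — a knowing
  approximation for the top bin.
- **Run chi-square.** The statistic weights observed and expected
  counts by $n_O/n_E$; it is defined as 0 when either total vanishes,
  and zero-denominator terms are skipped.
- **ALU density** is the fraction of 3'UTR bases covered by ALU
  intervals.
- **Undefined cells** (empty 3'UTR; one-base windows for
  dinucleotides) are `NA`, never 0, and are excluded pairwise from
  correlations and rank tests rather than imputed.

Pruning ranks non-binary features by $|A - 0.5|$ between stabilized and
unaffected transcripts and greedily eliminates, from each highly
correlated pair (Spearman $|R| \ge 0.7$), the lower-ranked feature.
Constant features receive $A = 0.5$ and correlate with nothing, so they
can be eliminated but never eliminate others. Binary features are
always retained. uORFs are split into strictly-5'UTR (tuORF) and
ORF-overlapping (tovORF): only the former permits re-initiation at the
main ORF, so the two may act differently on decay.

## Screens and three-group comparisons

Non-binary features use the two-sided Mann–Whitney test — exact
enumeration for tie-free samples up to n = 20 per group, otherwise the
normal approximation with tie and continuity correction — and binaries
the two-sided Fisher exact test, each family BH-corrected separately.
The discrimination flag requires corrected $q < 0.05$ (the conservative
reading where plain "P" alternates with FDR language) *and*
$|A - 0.5| \ge 0.1$ for non-binary features; binaries are flagged on
$q$ alone. The common-language effect size is computed by midranks,
which equals exhaustive pair enumeration including ties (asserted
exactly against a brute-force oracle).

Three-group comparisons (absolute MFE across classes, and across
stability tertiles within the stabilized class) use tie-corrected
Kruskal–Wallis followed by Dunn's mean-rank Q statistics. The critical
Q's provenance (one- vs two-sided, correction method) is exposed as
configuration rather than hard-coded: two-sided Šidák (default,
critical Q ≈ 2.39 for three groups at $\alpha = 0.05$), Bonferroni, or
none.

## RNA structure

Both stop-codon-proximal regions — the final `upstream_window` bases of
the CDS and the whole 3'UTR — are folded independently and summarized
by $|MFE|$ and by its per-base density. Two open choices:

- **Upstream window.** No canonical width exists for "upstream of the
  TC"; the default is 60 bases (about two ribosome footprints), always
  logged in the output, and configurable.
- **Whole-region folding.** Local stable structures could also be
  found by windowed scanning; the package folds each region as one
  sequence and reports the global optimum. For region lengths of a few
  hundred bases the two agree in ranking; the ambiguity is noted here
  and windowed scanning is out of scope.

The default engine is a maximum base-pairing dynamic program (minimum
hairpin loop 3; G:C scored −2, A:U and G:U −1) whose output is a
pseudo-energy — deliberately self-contained, deterministic, and
verified against exhaustive structure enumeration for all sampled
sequences up to length 12. An `RNAfold` binding is provided for
thermodynamic energies; results carry the engine name precisely so that
values from different engines are never compared.

## The synthetic-data generator

The generator emulates the *post-quantification* data of such a study,
never reads:

- **Decay.** Single-exponential curves, $a(t) = a_0 e^{-\lambda t}
  \varepsilon$, with multiplicative lognormal noise of unit median —
  abundances are positive ratio-scale quantities, so noise is
  multiplicative. Defaults: $\lambda = 0.15\,h^{-1}$ (half-life
  ≈ 4.6 h, the middle of the mammalian mRNA range), replicate CV 5%
  (tight technical replicates), knockdown rate ratios 0.3 / 3.0 for the
  planted stabilized / destabilized classes. Real NMD-target curves
  often deviate from single exponentials; since the classifier never
  fits a rate, this simplification biases none of its contrasts.
- **Sequences.** Background composition A 0.27, C 0.24, G 0.18, T 0.31
  — an AU-rich, slightly C-over-G 3'UTR background. The C > G skew is
  deliberate: it makes G the limiting partner for stem formation, so
  that planting additional G raises the base-pairing potential — the
  mechanistic coupling between G enrichment and secondary-structure
  stability the analysis is designed to detect. G enrichment adds the
  requested amount to the G probability inside the last 20 CDS bases
  and the whole 3'UTR (the stop codon itself stays fixed), scaling the
  other bases proportionally, so the realized density boost is additive
  in expectation.
- **Annotations.** uORFs, 3'UTR introns and ALUs are planted as
  *interval annotations* with known truth flags, not discovered from
  sequence — matching a workflow in which tuORF evidence comes from
  ribosome profiling and repeats from annotation tracks. An empty 3'UTR
  is rejected at parameter time because every 3'UTR feature would be
  undefined.

What passing tests on this generator do **not** show: robustness to
non-exponential decay mixtures, to correlated replicates, to
composition heterogeneity along real 3'UTRs, or to annotation errors —
real-data properties the generator intentionally omits. The synthetic
cohorts establish that the *procedures* are correct and calibrated, not
that any biological conclusion transfers.

## Problem sizes and reproducibility

The shipped analyses use cohorts of 600–900 transcripts with 150–300
base 3'UTRs, sizes at which every stage (including folding with the
dynamic program) runs in seconds to a couple of minutes on one core
while leaving all statistical claims testable. A single integer seed
drives every random draw; stage outputs are pure functions of
(configuration, seed), and the pipeline's report and files reproduce
bit for bit under a repeated seed (asserted in the tests).

## Known limitations

- The propagated-error p-values are approximations (see above); with
  more replicates a proper t or moderated test would replace them.
- The expected-run model assumes positional independence; dinucleotide
  structure in real UTRs inflates the chi-square statistic's null
  values.
- The fallback fold engine ignores stacking, loop entropies and
  non-canonical pairs; it orders sequences by pairing potential, not by
  free energy.
- Unclassified transcripts are a residual category; no attempt is made
  to model why a curve is inconsistent.
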