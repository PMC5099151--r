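---
title: "Methods: disagreement-filtered emotion networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disagreement-filtered emotion networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emonet)
```

## The measurement model

`emonet` treats perceived character emotion as a directed, weighted
relational measurement. M judges each fill one square matrix per emotion;
rows index the sender, columns the receiver, and a cell is a Likert
intensity in [1, 10]. Two modelling commitments shape everything
downstream:

* **Additive accumulation.** A judge who re-annotates a pair adds to the
  cell rather than replacing it; a repeated interaction is a stronger link.
  Consequently accumulated cell values may exceed 10 even though each
  individual annotation cannot. Accumulation is a sum, so it is invariant
  to annotation order — `accumulate_events()` exploits this and the test
  suite asserts it as a property.
* **Zero means absence.** The Likert floor is 1, so 0 unambiguously encodes
  "no perceived emotional interaction", whether the judge actively saw
  nothing or never visited the cell. The two situations are
  indistinguishable in the matrix representation and are deliberately not
  distinguished anywhere in the package; this makes disagreement computable
  on every cell, at the cost described under *Limitations*.

Self-directed emotion (a diagonal cell) is semantically plausible — a
character can be sad about themselves — so self-loops are accepted with a
validation warning, flow through the pipeline, and count toward both in- and
outdegree. The character roster is fixed a priori and supplied explicitly;
an annotation naming an unknown character is an error rather than a silent
roster extension, because silent growth hides typos in names.

## Inter-observer disagreement and the retention filter

The per-cell disagreement score is the information-based measure of
disagreement. For observers a and b the pair term is

$$\log_2\!\left(\frac{|x_a-x_b|}{\max(x_a,x_b)}+1\right),$$

and the multi-observer score is the mean over all $\binom{M}{2}$ pairs,
with a both-zero pair defined as 0 (perfect agreement on absence, matching
the zero-means-absence commitment). The score is 0 iff all observers agree
and approaches 1 as relative distances grow; it is scale-relative, so a
1-vs-2 split is as serious as a 5-vs-10 split. Two spot values anchor the
implementation and its tests: observers (1, 10) give
$\log_2 1.9 \approx 0.9260$, and (2, 2, 4) give
$\tfrac{1}{3}(0 + 2\log_2 1.5) \approx 0.3900$.

Uncertainty is quantified by a **percentile bootstrap over observers**:
judges are resampled with replacement, the score recomputed per resample,
and the 2.5%/97.5% quantiles (R's default type-7 quantile) reported. The
bootstrap is assumption-free at M = 11 where normal approximations for a
bounded, skewed statistic would be dubious, and it is fully seeded: every
cell uses a deterministic sub-stream derived from the run seed, so a fit is
bit-reproducible and independent of cell evaluation order. A constant
observer vector short-circuits to the exact interval (0, 0), which is also
what resampling would produce.

A cell is retained when its CI **upper bound is strictly below the
threshold**, default 0.15; a tie at exactly 0.15 is dropped ("lower than"
read strictly). Raising the threshold populates the networks more densely
but admits cells the judges genuinely disagree on. Filtering is per cell,
because only a per-cell score can drive per-cell retention; a whole-matrix
IBMD would conflate well-agreed and contested pairs.

The complementary judge-level statistic is the pairwise intraclass
correlation, ICC(A,1) in McGraw–Wong terms (two-way random effects,
absolute agreement, single measure), computed from the ANOVA mean squares
over the vector of all cell values — all emotions pooled by default, per
emotion on request. Absolute agreement is the right variant because a judge
who systematically scores two points higher *is* disagreeing about
intensity, not merely about ranking. Judges with no variance at all yield
NA with a warning rather than a fabricated 0. No dedicated ICC package is
assumed; the closed form is implemented directly and cross-checked in the
tests against variance components extracted from base R's `aov()`.

## Networks and degree indices

Each retained cell with at least one nonzero judge value becomes an edge
whose weight aggregates the M values — **mean by default, zeros included**.
The mean is stable in the number of judges (a study with 22 judges is
comparable to one with 11), which a sum is not; median and sum remain
available and the choice is recorded in every output file. Zeros are
included because a retained cell with some zero values passed the
disagreement screen as a whole; excluding zeros would bias weights upward.

Unweighted indegree counts distinct senders, $d_i(g) = \#\{j : g_{ji}=1\}$;
weighted in/outdegree sum incoming/outgoing weights; weighted degree is
their sum. Descriptive statistics use the n−1 standard deviation,
SE = SD/√n, and the midpoint median, over the full roster including
isolated characters — the roster is the population of characters, and a
character nobody annotated has genuinely zero degree. Two identities hold
on any directed network and are asserted on every network the tests
construct: total weighted indegree = total weighted outdegree = total edge
weight, hence mean in = mean out and mean weighted degree is twice either.
They are a useful integrity check precisely because they are
data-independent.

Ranked top-k tables (default k = 10) break ties by roster order, making
output deterministic. Visual exports encode node size as min–max-scaled
weighted indegree, node darkness as scaled weighted outdegree (an all-equal
vector pins both at 0.5), and edge thickness proportional to weight;
rendering is left to standard graph viewers (GraphML/GEXF/DOT), since exact
colour maps and layouts are presentation, not measurement.

## The synthetic generator and what it does (not) show

`ground_truth()` defines a latent weighted digraph per emotion (entries 0
or in [1, 10]) plus a rater model; `simulate()` draws annotation events and
pushes them through the same accumulation code real data use. The rater
model is deliberately minimal: a rater annotates a true-nonzero cell with
probability `annotate_prob`, reports
`clamp(round(W + N(0, noise_sd)), 1, 10)`, and with probability
`repeat_prob` enters it as two additive events. Raters never hallucinate
edges (the false-positive rate is an extension hook fixed at 0).

Defaults mirror the intended study design: **M = 11 raters**, the four
emotions, Likert 1–10 with additive repeats, and a 19-character example
roster. The remaining knobs were fixed once at values a rating study of
this kind would find realistic — edge density 0.25 (a quarter of directed
character pairs emotionally active), `noise_sd` 0.5 (judges mostly within
±1 Likert point), `annotate_prob` 0.9 (occasional missed cells),
`repeat_prob` 0.1 — and are not tuned per experiment.

The generator validates the *statistics*, not the *psychology*: Gaussian
noise around a shared latent value contains no halo effects, no drift, no
systematic rater bias, and no context-dependent reinterpretation of the
same expression. Passing recovery tests therefore show that the pipeline
faithfully reconstructs whatever structure survives its own filter — with
zero noise and full annotation the recovery is exact by construction, and
the tests assert it — but they cannot certify that 0.15 is the right
threshold for human raters.

One property of the method that the generator makes visible deserves
emphasis: under annotation sparsity (`annotate_prob` < 1), a cell where
some judges report a value and others report 0 has a large IBMD (a
zero/nonzero pair contributes the maximal term 1), so such cells are
usually rejected. The filter treats a missing annotation as an active
"no emotion" vote. Retention fractions and edge recall under the default
conditions are therefore modest — the values `scripts/acceptance.R`
computes — and edge *precision* stays at 1: what the filter keeps is
reliable, what it drops is mostly incomplete rather than wrong. Analysts
wanting denser networks should ensure complete annotation rather than raise
the threshold.

## Numerical and design choices

* Bootstrap: percentile method, default `n_boot = 2000`, mandatory explicit
  seed; per-cell seeds derived via a fixed affine map into 32-bit range.
  RNG state of the calling session is saved and restored around every
  stochastic step.
* Quantiles: R default type 7 throughout; medians are midpoints for even n.
* Degenerate cases: a single-character roster reports SD 0 with a warning;
  zero-variance correlations and ICCs are NA with a warning, never 0; an
  empty truth yields empty networks and trivially perfect recovery metrics
  with a warning.
* Long-format export splits accumulated cell values above 10 into chunks of
  10 plus a remainder so every emitted event respects the Likert bounds;
  integer-valued cells (the only kind integer Likert annotation produces)
  round-trip exactly.
* Canonical CSV dialect: roster order, zeros as empty cells, integers
  without decimal point — read-then-write is byte-stable, which is what
  makes whole-pipeline byte-determinism testable.
* ICC pooled across emotions by default (one agreement summary per judge
  pair); per-emotion matrices on request.

## Problem sizes

The test suite and the acceptance script are sized to run comfortably on a
single CPU: property loops use 200–1000 random cases; retention-degradation
experiments use 50 replicates of a 6-character, single-emotion design with
200 bootstrap resamples; the acceptance run uses the full default
conditions (19 characters, 4 emotions, 11 raters, 2000 resamples). These
sizes are the package's own choices and can be scaled up freely.

## Limitations

* The IBMD confidence interval resamples observers, so with few judges
  (M < ~5) the interval is coarse and retention decisions unstable.
* Zero conflates "saw nothing" with "did not look"; the filter consequently
  penalises incomplete annotation (see above). A missing-data-aware variant
  would need a richer input format than the square matrix.
* Cross-judge aggregation by mean assumes judges are exchangeable; a judge
  ICC matrix with a clear outlier row is the diagnostic to consult before
  trusting the networks.
* No alternative agreement statistics (Krippendorff's α, Kendall's W) and
  no centralities beyond degree are provided; both are deliberate
  non-goals.
```{r session}
sessionInfo()
```
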