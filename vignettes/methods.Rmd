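---
title: "Differential ncRNA–mRNA coexpression networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential ncRNA–mRNA coexpression networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncxnet)
```

## The problem and the model

Non-coding RNAs — miRNAs, snoRNAs (H/ACA-box "SNORA", C/D-box "SNORD") and
snoRNA-derived small RNAs — can repress mRNA expression. Across a cohort,
a repressive regulatory relation leaves a footprint as a *negative* Pearson
correlation between the ncRNA and its target mRNA. `ncxnet` infers bipartite
ncRNA–mRNA networks from that footprint and compares them across clinical
conditions (here: relapsing-remitting multiple sclerosis relapse, remission,
and healthy controls, in peripheral blood leukocytes).

The model is deliberately minimal: after per-gene z-scoring, an edge is
drawn between ncRNA $i$ and mRNA $j$ whenever their sample Pearson
correlation $r_{ij}$ falls below a significance-derived cutoff,

$$ r_{ij} < -r^*(n, \alpha), \qquad
   r^*= \frac{t^*}{\sqrt{n - 2 + t^{*2}}}, \qquad
   t^* = t_{1-\alpha/2,\; n-2}, $$

the inversion of the usual t-transform $t = r\sqrt{(n-2)/(1-r^2)}$ at a
two-sided level $\alpha$. Only inter-class (ncRNA–mRNA) pairs are ever
tested; mRNA–mRNA and ncRNA–ncRNA correlations are discarded by
construction. The two-sided convention was adopted because it — and not the
one-sided one — reproduces the printed cutoffs this analysis is anchored to
(0.42 at $n=65,\alpha=5\times10^{-4}$; 0.537 at $n=22$ and 0.549 at
$n=21$, $\alpha=0.01$). Ties at exactly $-r^*$ are excluded (strict
inequality).

Because $r^*$ grows as $n$ shrinks, condition-specific networks (built from
one condition's samples) automatically use more stringent cutoffs than the
global network built from all samples. That coupling of threshold to sample
size is the load-bearing design: it keeps the per-edge false-positive rate
nominally equal across networks of different size, which is what makes the
edge-by-edge comparison between conditions meaningful.

## Topology characterization

- **Degree distribution and power law.** The integer-degree histogram is
  fit by ordinary least squares of $\log_{10}(\text{count})$ on
  $\log_{10}(\text{degree})$ over nonzero bins, reported as $y = a x^b$
  with the regression's $|R|$ as fit quality. This is the classic
  reporting style for coexpression networks (whose exponents typically lie
  in $(-2, -1)$), not a maximum-likelihood tail estimator; it is exact on
  exactly-generated histograms and biased like any log–log fit on noisy
  tails — which is precisely the estimator the descriptive claims refer to.
- **Betweenness** is undirected shortest-path betweenness normalized per
  connected component by $(n_c-1)(n_c-2)/2$ (the NetworkAnalyzer /
  Cytoscape convention), so values lie in $[0,1]$ and a star's center
  scores exactly 1. The published combined-centrality magnitudes
  presuppose this normalization.
- **Combined centrality** of an ncRNA is betweenness × outdegree, where
  outdegree is its incident edge count; mRNAs get outdegree 0 and hence
  never rank. It rewards regulators that both target many genes and sit on
  many shortest paths.
- **Hubs** are ncRNAs whose combined centrality *strictly* exceeds the
  97.5th percentile of the combined centralities of the network's ncRNA
  nodes. The percentile is taken over ncRNAs only: 2.5% of ncRNAs is the
  arithmetic that matches the motivating analysis (15 hubs among 612
  ncRNAs); over all nodes it would predict ~7× more. Percentiles use
  linear interpolation between order statistics (type 7).
- **Core subnetwork** = hubs plus first neighbors, keeping only
  hub-incident edges. The neighborhood union defines the core; including
  edges between two non-hub members would inflate it arbitrarily.
- **Descriptors** for network comparison: component count, centralization
  $\frac{n}{n-2}\left(\frac{k_{max}}{n-1} - \text{density}\right)$,
  characteristic path length (mean over connected pairs), average degree
  $2E/n$, heterogeneity $\sqrt{\operatorname{Var}_{pop}(k)}/\bar k$, and
  the power-law exponent. On a fully regular graph the power-law fit is
  undefined (one distinct degree); `descriptors()` reports `NA` with a
  warning there rather than failing, so the other five descriptors remain
  available — the fit function itself still errors, because silently
  fitting two points would be worse.

## Differential networks

Edge identity is the unordered (ncRNA, mRNA) pair; correlation magnitudes
are ignored when intersecting, so two networks share an edge iff the same
pair passes both thresholds with the same (negative) sign. From the three
condition networks the package derives

- the exact 7-region Venn partition of nodes and of edges, with the
  triple-shared percentage of the union, and pairwise shared proportions
  in both conventions (Jaccard and fraction-of-smaller-network), since the
  reporting convention for pairwise sharing is genuinely ambiguous;
- the **status-independent core**: the triple-intersection edges;
- the **disease-specific network**: (relapse ∩ remission) \ controls,
  asserted on every run to share zero edges with the controls network;
- largest components with deterministic tie-breaks (nodes, then edges,
  then smallest node id);
- a PCA of the six descriptors across networks on the correlation
  (standardized) scale — the descriptors have incommensurate units — and
  Pearson correlations between aligned degree / path-length histograms
  (union of bins, missing bins zero).

## Rank Products

Differential expression uses the Rank Products statistic: per comparison
column (a within-patient relapse−remission difference in the paired
design; a cross-group sample pairing, all pairs up to a 500-pairing cap,
in the unpaired one) genes are ranked by change score, separately per
direction, and $RP_g$ is the geometric mean of $g$'s ranks. Significance
is by within-column rank shuffles: $E_g$ = mean count of permuted $RP$
values $\le RP_g$, and $\text{pfp}_g = E_g / \text{rank}(RP_g)$. One
permutation pool serves both directions because shuffled ranks are
direction-free. Defaults — 1000 permutations, pfp < 0.05 — are declared
configuration, not inferred values.

Two calibration facts the tests pin down, and users should know:

- pfp is an FDR-type quantity. Under a global null the *expected number*
  of pfp < 0.05 calls per direction is ≈ 0.05 — not 0.05 per gene. Its
  per-gene false-positive rate is far below $\alpha$.
- In the presence of strong up-shifted genes, down-direction pfp values
  become anti-conservative (true positives displace null genes' ranks
  while the shuffle null does not know that). This is a property of the
  permutation scheme itself; treat lone down-calls accompanying massive
  up-shifts with suspicion.

## Candidate selection

Candidates are ncRNA nodes of the disease-specific network that are DE in
either comparison, ranked by disease-network outdegree (ties by id). The
caution logic is two-level because the motivating analysis treats the two
situations differently with an informal argument: a **hard caution** when
the candidate is simultaneously a global-network hub and a
status-independent-core member (manipulating it would perturb wiring that
healthy tissue also relies on), and an **informational note** carrying the
control-hub rank and/or core outdegree when it appears in only one of
those contexts, letting a low core connectivity argue for, rather than
against, the candidate. No numeric exclusion rule is imposed; the flags
record the evidence.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` defaults state the emulated design: 22 paired
relapse/remission patients, 21 controls, 1113 ncRNAs, 6451 mRNAs. The
generative process is the pipeline's own distributional assumption run
forward — linear repression with Gaussian noise:

- regulator ncRNAs (default 100) receive target counts from a truncated
  discrete power law $P(k)\propto k^{-2}$ on $[1, 100]$, giving the
  planted graph a scale-free outdegree distribution;
- target mRNAs equal $-\beta \sum_{\text{regulators}} x + \varepsilon$
  with $\beta = 1$, $\sigma_\varepsilon = 0.5$ (planted pair correlation
  $\approx -0.89$ for single-regulator targets); non-targets are standard
  normal noise;
- per condition, a fraction (default 0.6) of each regulator's targets is
  replaced by uniform non-targets — the single knob that produces massive
  edge rewiring atop stable node membership and topology, the phenotype
  the differential analysis is built to detect;
- a patient's relapse and remission samples share a scalar baseline shift
  (sd 0.2, a mild within-subject correlation typical of repeated blood
  draws); controls carry none — which is why null-calibration tests read
  the control network;
- DE is injected as mean shifts (+2) on disjoint regulator subsets: one
  shifted in relapse only (altered relapse vs remission), one shifted in
  both patient states (altered remission vs controls).

Where the motivating study stated no value (coupling strength, noise,
rewiring fraction, shift size, patient effect), values were chosen once as
plausible for standardized expression data and are not revisited by tests.

A green simulation test therefore establishes that the pipeline recovers
*linear, stationary, unconfounded* planted structure at the stated sizes.
It does not establish robustness to what the generator omits: probe-level
artifacts, batch or treatment effects, non-Gaussian intensity
distributions, indirect correlations through unmodeled common causes, or
regulatory effects that are nonlinear or condition-dependent in strength.
Test-suite runs use smaller panels (tens of ncRNAs, hundreds of mRNAs)
than the defaults for runtime; the thresholds under test adapt to sample
size by construction, not to panel size.

## Numerical choices and degenerate inputs

- z-scores use the sample sd ($n-1$); Pearson correlations are invariant
  to this choice, so it is recorded, not material. Zero-variance genes
  are a hard error at standardization (named in the message); inside a
  condition subset they yield flagged-`NA` correlations that thresholding
  drops with a warning — they cannot be meaningfully imputed.
- Standardization happens once, after merging classes; per-platform
  standardization before merging is equivalent because it is per gene.
- The intensity filter removes mRNAs whose 90th-percentile intensity is
  *strictly below* the user-supplied threshold (the motivating value 55.7
  was that platform's mean negative-control intensity and is not a
  default here).
- Determinism: every stochastic stage takes a seed and restores the
  caller's RNG state; identical configs give byte-identical artifacts.
- The positive-correlation network is supported (`sign = "positive"`) but
  sits on no default path.

## Known limitations

- No multiple-testing correction on edges: thresholds control the
  per-edge, not family-wise, error — by design, since the comparison
  logic depends on equal per-edge calibration, but absolute edge counts
  should not be read as discoveries.
- The log–log least-squares power-law fit is descriptive; it is not a
  statistical test of scale-freeness.
- Rank Products' unpaired design caps pairings at 500 (seeded subsample
  beyond), trading a little permutation resolution for tractability.
- The caution flags encode membership evidence only; they are not a
  druggability or safety score.
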