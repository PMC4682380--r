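---
title: "DMR detection from bisulfite-seq counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DMR detection from bisulfite-seq counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
emission models, the mixture and transition learning, the segment
extraction, the simulator the tests rely on, and the design decisions
taken where more than one reasonable choice existed.

## Data and notation

The input is an ordered per-CpG table of read counts for two samples:
at CpG site $i$, sample $s \in \{1,2\}$ contributes $m_{si}$ reads
supporting methylation and $u_{si}$ reads not supporting it, with
$n_{si} = m_{si} + u_{si}$. Coordinates are 0-based half-open
throughout; counts from the two strands of one CpG dinucleotide may be
merged upstream with `merge_strands()`. Each CpG carries one latent
differential methylation state: Up (hypermethylated in sample 1), Down,
or NoCh (no change).

## Emission models

### Legacy plug-in binomials

The older design plugs fixed, state-dependent methylation levels into
binomial likelihoods, using an empirical pseudocount added to the counts
a state expects to be large:
$\theta^{U}_{1i} = (m_{1i}+pseudo)/(n_{1i}+pseudo)$,
$\theta^{U}_{2i} = m_{2i}/(n_{2i}+pseudo)$, mirrored for Down, and the
pooled $\theta^{N}_{0i} = (m_{1i}+m_{2i})/(n_{1i}+n_{2i})$ for NoCh.
With $pseudo = 0$ the Up and Down emissions coincide at every site, so
the parameter is essential, yet its useful range depends on sequencing
depth and there is no principled way to set it. `compute_legacy_emissions()`
implements this model behind the `--emissions legacy` flag; the pooled
NoCh level is clamped to $[10^{-12}, 1-10^{-12}]$ before the log.

### Beta-mixture emissions

The replacement models the *distribution* of methylation levels instead
of a point estimate. Genome-wide levels are bimodal; each sample's
distribution is a constrained three-component mixture

$$p(\theta) = w_H\,\mathrm{Beta}(\theta\,|\,\alpha_H, 1)
            + w_L\,\mathrm{Beta}(\theta\,|\,1, \beta_L)
            + w_{unif},$$

with $\alpha_H, \beta_L \ge 1$. Fixing the off shapes to 1 makes each
beta component cover exactly one mode (the H mean $\alpha_H/(\alpha_H+1)$
is always above $1/2$, the L mean below), and keeps every integral below
in closed form. The state emissions integrate the binomial likelihoods
against state-specific level priors: Up uses
$p_H(\theta_1)\,p_L(\theta_2)$, Down the mirror image, and NoCh a single
shared level drawn from the normalized product of the two samples'
full mixtures. The closed forms are products and 3x3 sums of beta
functions; the NoCh normalizer $Z$ is the same sum evaluated at zero
counts. Under the shape constraints every beta-function argument in the
NoCh sum is at least 1, which `compute_emissions()` asserts at entry.
All computation is in log space via `lbeta`/`lchoose` with log-sum-exp,
so counts in the thousands are safe. A site with no reads in either
sample emits probability 1 in all three states: it stays in the chain
for distance modelling but does not inform the state.

### Fitting the mixtures

`fit_beta_mixture()` maximizes the likelihood of read counts, not of
ratios $m/n$ — counts retain depth information, which is what lets the
model adapt where the legacy pseudocount had to be re-tuned per depth.
The EM is standard for a three-component beta-binomial mixture with one
free shape per beta component:

* E-step: posterior responsibilities from the weighted beta-binomial
  marginals.
* M-step: weights are responsibility means; each free shape maximizes
  its weighted profile likelihood by Brent search on $\log\alpha$
  (`stats::optimize`), projected onto $[1, \infty)$. Exact coordinate
  maximization keeps the generalized-EM monotonicity guarantee; a
  damped Newton step would find the same optimum with more bookkeeping.
* Initialization: method of moments after splitting sites at level
  $1/2$; $w_{unif}$ starts at 0.05. The bimodality of real and
  simulated level distributions makes this robust.
* Convergence: relative log-likelihood change below $10^{-6}$, at most
  500 iterations.

Fitting uses 10000 randomly subsampled covered sites (`subsample_sites()`);
five free parameters per sample need no more, and the fit is insensitive
to the subsample beyond that size. `fit_model()` draws one shared site
set for both samples from sites covered in both — a symmetric criterion,
so that exchanging the two samples transforms the whole learned model by
exactly the Up/Down relabelling (see *Symmetry* below). Zero-coverage
sites carry no likelihood information and are excluded.

## The hidden Markov model

### State space and distance modelling

Twelve states: $\{$CpG, gap$\} \times \{$Up, Down, NoCh$\} \times
\{$basic, second$\}$. CpG states emit the count likelihoods; gap states
are silent and occupy the interval positions between consecutive CpGs.
Each CpG state moves deterministically into its own gap state; a gap
state self-loops with probability $a$ and otherwise exits to any of the
six CpG states. Direction and unit switches therefore happen only at
gap-to-CpG boundaries. The dwell of a gap run is geometric, so the
probability that the next CpG lies $d$ interval positions away and lands
in state $y$ is $a^{d-1} e_{xy}$ — each direction gets its own distance
distribution, and the duplicated unit upgrades it to a mixture of two
geometrics, which fits the empirically heavy-tailed spacing of
differentially methylated cytosines better than a single geometric.

Because gap states cannot change identity inside a run, the gap block of
the transition matrix is diagonal and the collapsed CpG-to-CpG kernel is
available in the scalar closed form $(d-1)\log a_x + \log e_{xy}$; no
matrix powers or distance caps are needed, and log-space arithmetic is
exact for arbitrarily large $d$. The general silent-chain machinery of
cached matrix powers reduces here to two vectors and a 6x6 matrix.

### Learning transitions

`fit_transitions()` runs Baum–Welch over the collapsed chain with
emissions fixed (the mixtures are learned separately, as above).
The expected number of self-loops inside a gap run is exactly $(d-1)$
times the posterior probability of the transition using it — the
distance determines the dwell — so the E-step needs no per-base pass.
Chromosomes are independent chains sharing one parameter set; the
initial distribution over CpG states is re-estimated from first-site
posteriors. Forward/backward run in compiled code (Rcpp) in log space;
the backward total is returned alongside the forward total so their
agreement can be asserted. Convergence: absolute log-likelihood change
below $10^{-4}$, at most 100 iterations.

`default_hmm()` starts from near-uniform allowed transitions with a
small seeded jitter that differs *between units* (so EM can break the
unit symmetry) but is *shared between Up and Down* (so the model stays
exactly equivariant under swapping the samples). The initial
distribution puts 0.9 on NoCh.

## Scoring and extracting DMRs

A candidate region $[s, e]$ with direction $dir$ is scored by the
log-likelihood ratio of two constrained paths over the whole chromosome:
$dir$ on $s..e$ with NoCh elsewhere, versus all-NoCh, each maximized
exactly over the unit sequence (a two-state Viterbi). This is
`score_region()`, and every reported DMR's score is recomputed by it.

To locate candidate regions, the score is decomposed into additive
per-site increments: the emission log-ratio
$\log e^{dir}_i - \log e^{N}_i$, plus transition log-ratios where the
unit pair of each step is collapsed by maximization, plus the
NoCh$\to$dir entry and exit penalties at the boundaries. On this additive
sequence `extract_dmrs()` performs iterated best-segment extraction per
direction: take the globally best-scoring segment, remove its sites,
recurse into the flanks, stop when nothing exceeds the score threshold
(default 0). Up/Down candidates that overlap — rare, since each
direction's segments are disjoint — are resolved by keeping the higher
score.

The maximality rule matters. A segmentation that instead maximized the
*total* score over disjoint segments would cut a region at every
interior dip of the increment sequence, because removing a
negative-scoring stretch always raises the total; the output would be
shards of densely supported sites. Iterated best-segment extraction
bridges an interior dip whenever the flanking evidence on both sides
outweighs it — the same maximality notion that keeps BLAST's
high-scoring pairs intact — which is what lets a DMR whose interior
contains uninformative CpGs emerge as one region. The per-step unit
collapse by maximization can differ from the exact unit-path maximum in
contrived cases; reported scores always come from the exact
`score_region()`, and segments whose exact score fails the threshold are
dropped.

### Symmetry

Exchanging the two samples maps every Up DMR to an identical Down DMR
with the same score. This holds exactly (to floating-point noise, below
$10^{-9}$ in the tests) because every stage is equivariant: the emission
formulas mirror U and D, the shared subsample is drawn by a
sample-symmetric criterion, and the transition initialization shares its
jitter across directions. The acceptance suite asserts it on the full
benchmark dataset.

## The simulator

`simulate_dataset()` emulates a two-sample experiment at the count
level:

* CpG positions from a mixture of two geometric spacings (means ~20 bp
  within islands, ~150 bp outside, island fraction 0.6) — echoing the
  short-range clustering of real CpGs without modelling sequence.
* Baseline level $\theta_i$ per site, i.i.d. from the bimodal mixture
  ($w_H = 0.5$, $w_L = 0.45$, $w_{unif} = 0.05$,
  $\alpha_H = \beta_L = 8$), chosen to mimic the sharp bimodality of
  real methylomes.
* Planted DMRs: non-overlapping intervals anchored at CpGs (a 10-site
  buffer keeps neighbours from abutting), direction Up or Down with
  probability $1/2$ each; inside a region sample 2's level is set to
  the minimum (Up) or maximum (Down), the "full methylation switch".
* Counts: $n \sim$ Poisson(depth) per site and sample,
  $m \sim$ Binomial$(n, \theta')$ with
  $\theta' = \theta(1-\varepsilon) + (1-\theta)\varepsilon$ and
  bisulfite conversion error $\varepsilon = 0.005$.

Everything is reproducible from one seed. What the simulator does *not*
emulate: read-level artifacts (alignment, quality, mapping bias) and —
deliberately, because it is the simplest defensible null — spatial
correlation of baseline levels. Real methylomes are regionally coherent;
i.i.d. baselines are the harsher condition for region-level detection,
as discussed next.

## What the benchmark shows, and its limits

The benchmark (20000 CpGs, 50 planted DMRs of ~50 CpGs, depth 10)
measures top-50 accuracy under 50/90/99% reciprocal overlap with
direction matching, where a truth region is correct if a top-ranked
prediction reciprocally overlaps it at the required fraction (greedy
one-to-one matching by rank). Accuracy is monotone non-increasing in the
overlap fraction by construction.

Under i.i.d. bimodal baselines, roughly half the CpGs inside a planted
region carry no differential signal: an Up region's site whose baseline
was already low stays low in both samples and genuinely favors NoCh
(about $-6$ nats per site at depth 10, against $+13$ at signal sites).
Interior runs of such sites form score dips; a region splits when a dip
exceeds the flanking signal mass on one side. At depth 10 this affects
a minority of regions — predominantly of the direction whose signal
sites are the scarcer baseline mode — and caps top-50 accuracy at 50%
reciprocal overlap in the mid-0.8s rather than near 1. This is a
property of the simulation's independence assumption, not of the
detector: with regionally coherent baselines (as in real methylomes)
planted regions are internally homogeneous and recovery is limited only
by depth. The acceptance suite states the near-perfect target and is
allowed to fail it under these conditions; the number it actually
achieves is computed fresh by `scripts/acceptance.R` on every run.

## Numerical choices and edge cases

* All likelihood work in log space; `lbeta`, `lchoose`, log-sum-exp.
* Gap lengths $d = pos_{i+1} - pos_i - 1 \ge 1$ after validation
  (positions strictly increasing, CpGs at least 2 bp apart). The
  degenerate $d = 0$ "direct CpG block" is structurally zero in this
  topology and never reached from valid tables.
* EM monotonicity is asserted to slack $10^{-10}$ in the tests; both EM
  loops use exact M-steps, so violations would indicate numeric trouble.
* Ties in ranked output are broken by `(chrom, start)`; ties between
  overlapping Up/Down candidates keep Up (deterministic, measure-zero).
* Degenerate mixtures (a component weight driven to 0) are legal;
  responsibilities then ignore that component. Degenerate input (all
  sites fully methylated) drives $w_H \to 1$ without error.
* Problem sizes in the test suite: oracle checks enumerate chains up to
  5 sites ($6^5$ paths) and segmentations up to 8 sites; recovery
  experiments use 4000–10000 sites; the end-to-end benchmark uses the
  full 20000-site configuration. The whole suite runs in a few minutes
  on one core.

## Known limitations

* Two samples only; no replicates, covariates, or FDR calibration of
  scores — the ranked list with explicit scores is the contract.
* One emission table per run; the mixture fit assumes a genome-wide
  stationary level distribution and will blur datasets with strong
  per-chromosome composition differences.
* The simulator's i.i.d. baseline assumption understates real-data
  detectability of long regions (see above) and its depth parameter maps
  to real read-level experiments only qualitatively (counts are drawn
  directly, reads are never emulated).
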