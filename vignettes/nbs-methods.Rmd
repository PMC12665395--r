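---
title: "Net Bootstrap Support: model, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net Bootstrap Support: model, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Concatenated ("superalignment") phylogenomics routinely produces trees in
which nearly every clade carries 95–100% Felsenstein bootstrap support
(FBS).  With hundreds of genes, sampling variance all but vanishes, so the
standard bootstrap certifies whatever the concatenated estimate happens to
be — including clades that are artefacts of phylogenetic heterogeneity
across the genome (incomplete lineage sorting, a handful of problematic
loci, gene-tree estimation error).  The bootstrap is answering the question
"would I get this clade again from the same data-generating process?",
which is not the question "is this clade supported consistently across the
genome?".

`nbsupport` implements the little-bootstrap route to the second question.

## The little-bootstrap machinery

From a superalignment with $L$ sites:

1. draw a **subsample** of $l < L$ sites *without* replacement, with
   $l = \lfloor L^g \rfloor$ and $g = 0.7$ by default
   (`subsample_size()`);
2. build $R$ **upsampled replicates** per subsample, each of $L$ sites
   drawn *with* replacement from the subsample (`upsample_replicate()`).
   Every subsampled site is expected to appear $L/l$ times, so each
   replicate carries as many substitutions as the full alignment while
   containing at most $l/L$ of its distinct sites (about 1.6% at
   $L = 10^6$, versus ~63% for a standard bootstrap replicate);
3. infer a tree per replicate and record, per subsample, the percentage of
   replicate trees containing each clade — the subsample **bcl**
   (bootstrap confidence limit), on a $100/R$ grid;
4. aggregate the per-subsample bcl values over $S$ subsamples into a
   **bcl distribution** per clade.

The estimators are then, per clade:

* **NBS** $= \frac{1}{S}\sum_i \mathrm{bcl}_i$ — the net frequency of
  support across the genome.  This is the algebraic consequence of
  defining the overconfidence as the mean signed gap between the
  superalignment FBS and the subsample bcls.
* **fbs** $= \operatorname{median}\{\mathrm{bcl}\}$ — an estimate of the
  superalignment FBS, obtained from the same distribution so no standard
  bootstrap of the full alignment is ever needed.
* **OC** $= \mathrm{FBS} - \mathrm{NBS}$ — how much the standard bootstrap
  overstates genome-wide support.  Zero when the bcl distribution is
  symmetric around FBS; large when a clade is carried by a fraction of the
  data.  By default `overconfidence()` uses the median estimate as the FBS
  reference; an externally computed FBS can be supplied.

A clade supported by (say) half the genome and contradicted by the other
half shows a *bimodal* bcl distribution — a mass near 100 and a mass near
0 — with NBS near 50 even though its FBS may be 100.

## Adaptive stopping

`adaptive_nbs_run()` starts at $S_0 = 5$ subsamples with $R = 20$
replicates each (5-point bcl resolution), then adds one subsample per
iteration.  After each addition the root mean squared deviation of
per-clade NBS between successive iterations is computed over the union
clade set (clades not yet seen fill in as 0), on the proportion scale, and
the run stops once the RMSD is below 0.05 on two consecutive iterations
(or at `s_max`, flagged non-converged).  Choices worth stating:

* **Proportion scale.** The 0.05 threshold is interpreted on $[0,1]$, i.e.
  five support points.  On the percent scale a 0.05-point threshold would
  be unattainable at 5-point bcl resolution.  The scale is recorded in the
  run manifest.
* **Single additions, two-hit rule.** Subsamples are added one at a time
  and two consecutive sub-threshold RMSDs are required; this is the most
  conservative stabilisation reading that still terminates, and the
  one-at-a-time schedule makes the trace informative.
* **Absence is evidence.** A clade absent from a subsample's replicate
  trees scores bcl = 0 there; support is a frequency.
* **Data-poor taxa.** A subsample in which some taxon retains no
  informative site is skipped with a warning and redrawn (up to 20
  attempts).  Upstream, `enforce_sparsity_policy()` warns at 50% missing
  per taxon and can drop taxa at ≥95%, refusing to go below four taxa.
* **Validation mode.** `nbs_validation()` repeats the analysis at twice
  the subsample size and reports per-clade NBS deltas.

NBS with constant $R$ equals the clade's frequency among the pooled
$S \times R$ replicate trees; this identity makes the >50% NBS clades
mutually compatible, so the greedy majority-rule consensus
(`consensus_with_nbs()`) is always well defined: majority clades first,
then remaining clades by descending NBS when compatible (ties broken by
clade key for determinism).

## Tree inference engines

The NBS statistics are engine-agnostic.  The bundled engine computes
site-weighted p or Jukes–Cantor distances (pairwise deletion for
missing/ambiguous residues; saturated pairs capped at a configurable
distance of 5.0 with a warning rather than failing, because upsampled
replicates of small subsamples can saturate by chance) and runs neighbor
joining via `ape::nj()` with negative branch estimates clamped to zero.
Weight vectors are consumed directly — replicates are never materialised —
which is where the memory economy of the scheme comes from.  External
maximum-likelihood programs are wrapped through a command template
(`{aln}`, `{out}`, `{seed}` placeholders); failed replicates are dropped
and counted, and a subsample with a majority of failures aborts the run.

All randomness derives from one master seed hashed per (subsample,
replicate) stream (`derive_seed()`), so results are bit-reproducible and
independent of evaluation order.

Coordinates are 1-based and inclusive throughout, matching R and the
ape/Biostrings ecosystem; partition maps on disk are 1-based inclusive as
well.

## Modality testing

The unimodality screen runs per clade once $S \ge 4$:

1. **Dip test.**  The dip statistic is the sup-norm distance from the
   empirical CDF to the nearest unimodal CDF.  We compute it exactly over
   unimodal CDFs whose mode lies at an observed value or a gap midpoint (a
   finite candidate grid), by bisection on the band half-width with
   greatest-convex-minorant feasibility checks plus a convex-extrapolation
   bound that enforces the connection between the convex and concave
   flanks at the mode (src/dip.cpp).  On this class the computation is
   exact (it was validated against an independent linear-programming
   minimisation during development); restricting the mode to the candidate
   grid can only overstate the dip by a vanishing amount and is immaterial
   for grid-valued bcl data.  The p-value is Monte Carlo against
   uniform(0,1) samples of equal size, 2,000 replicates by default, with
   the add-one correction $(b+1)/(n_{mc}+1)$.  A precomputed null table
   (`dip_null_table()`) can be shared across tests of equal sample size —
   the same idea as published dip quantile tables — which makes large
   calibration studies affordable.
2. **Silverman mode count**, consulted only when the dip rejects: for
   $k = 1, 2, \ldots$ the critical bandwidth $h_k$ (smallest Gaussian KDE
   bandwidth with ≤ *k* modes, found by bisection — mode counts are
   monotone in bandwidth) is stress-tested by a smoothed, variance-rescaled
   bootstrap (500 draws by default); the reported count is the smallest
   non-rejected $k$.
3. The verdict is **multimodal** iff the dip rejects at $\alpha$ *and* at
   least two modes are found.

Numerical choices in this stage:

* bcl values are rescaled to $[0,1]$ and tied grid values are jittered by
  uniform noise of amplitude $(100/R)/20$ — far below the grid spacing —
  under a fixed derived seed before the dip test, avoiding ECDF
  degeneracy on heavily tied samples;
* KDE mode counting uses a grid of at least 10 points per bandwidth and
  ignores maxima below $10^{-9}$ of the peak density (floating-point
  wiggles in density-underflow valleys are not modes);
* Silverman bandwidths are floored at half the bcl grid spacing: two peaks
  separated by less than the measurement resolution $100/R$ are an
  artefact of the grid, not genome heterogeneity.  In particular a clade
  whose bcls alternate between adjacent grid values (95 and 100) is
  reported unimodal, while a 0-versus-100 split is genuinely bimodal.  If
  the floor bandwidth already shows ≤ *k* modes, *k* is accepted without
  the (then degenerate) bootstrap;
* an all-equal bcl distribution is unimodal by definition and is not
  tested.

`wilcoxon_signed_rank()` (paired differences) and `wilcoxon_rank_sum()`
(unpaired groups) are provided for evaluation-style comparisons, e.g. OC
of correct versus incorrect clades; both wrap `stats::wilcox.test`
two-sided (exact enumeration for small untied samples, normal
approximation with tie and continuity corrections otherwise).  Which one
applies depends on whether the two clade sets are paired; for unpaired
correct-versus-incorrect comparisons the rank-sum form is the defensible
choice, and the functions report nothing beyond the p-value so the caller
states what was compared.

## The simulator, and what passing tests do (not) show

`ils_like_dataset()` emulates gene-tree heterogeneity as a *finite
topology mixture*: each gene draws its topology from weighted classes
(e.g. a species tree and its nearest-neighbour-interchange variant at
50/50), evolves under Jukes–Cantor, and the genes are concatenated with a
partition map and a truth record.  Discordance frequency — the operative
property for NBS — is thereby controlled exactly, but the simulator is
*not* a multispecies-coalescent sampler: branch-length variation among
gene histories, rate heterogeneity across sites and lineages, indels, and
alignment error are all absent.  Passing tests therefore demonstrate that
the estimators behave as designed when heterogeneity takes the form of
topology mixtures with JC substitution; they do not certify performance
on real alignments with model misspecification.

Gene-tree estimation error regimes are produced by uniform branch scaling
(`gtee_dataset()`, scales such as 0.1/0.07/0.05 leaving each gene 1–2
substitutions per site-lineage), skewed gene lengths by a lognormal
sampler whose σ is solved numerically for a target skewness
(`skewed_gene_lengths()`; empirical phylogenomic length distributions have
skewness around 3), and data-poor taxa by `inject_missing()`.  Gene
boundaries are recorded but deliberately ignored by the NBS pipeline —
sites are sampled without regard to annotation — and serve only
diagnostics and evaluation.

Default study conditions used in the test-suite experiments: homogeneous
recovery uses 20 taxa and $L = 50{,}000$ (25 genes × 2,000 sites);
heterogeneity detection uses a 16-taxon 50/50 NNI mixture of 100 genes ×
400 sites with $S_0 = 40$ subsamples (the modality screen needs a few
dozen bcl values for power, matching the exploratory 100-subsample usage
at reduced desk scale); simulator conservation uses the canonical 100
genes × 1,600 sites.  The dip calibration check runs 500 uniform samples
of $n = 100$ in five blocks, each block against its own 2,000-replicate
null table, so no single table draw dominates the estimated type-I error.

## Known limitations

* The subsample-size exponent $g = 0.7$ reproduces the megabase-scale
  anchor (18,086 sites from 1,207,638) but is not a universal optimum;
  published automatic protocols differ across datasets, so $g$ (or $l$
  directly) is exposed everywhere.
* The bundled engine is distance-based; for publication analyses an
  external ML engine should be wrapped via the adapter, and sensitivity of
  NBS to the engine/model choice is not quantified here.
* The double bootstrap is implemented for comparison
  (`double_bootstrap()`); its measured distinct-site fraction (~47% for
  large $L$, the Poisson-thinning value) is reported rather than the
  0.63² ≈ 39% heuristic sometimes quoted.
* Transfer bootstrap, branch-length aggregation across replicates, and
  Bayesian supports are out of scope.
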