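---
title: "Upstream kinase activity inference from peptide-array kinomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upstream kinase activity inference from peptide-array kinomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinact)
library(dplyr)
```

## The measurement and the model

A kinome peptide array carries 144 phosphorylatable 12–15-mer peptide
targets in a 12 × 12 grid. Cell lysate is pumped through the porous array;
kinases in the lysate phosphorylate their substrate peptides, and bound
phospho-specific fluorescent antibody is imaged at increasing camera
exposures (10, 20, 50, 100 and 200 ms). Under non-saturating conditions
fluorescence is linear in exposure time, so the per-spot information is the
*exposure slope*. `kinact` reduces each (sample, peptide) series to

\[ v = \log_2(100 \times \text{slope}) \]

via ordinary least squares of signal on exposure. The fit includes an
intercept by default: the instrument pipeline that produced the published
values is proprietary, and an intercept absorbs constant optical background
without biasing the slope. A through-origin fit is available
(`model = "through_origin"`). Non-positive slopes have no defined value and
become missing; they fail QC rather than being clamped.

**QC** ("acceptable curve fit and signal") is quantified as: a peptide
passes only if in *every* sample `r2 >= r2_min` (default 0.90) and
`slope > min_slope` (default 0, strict). The per-peptide rule — one peptide
is analysed in all samples or in none — keeps every retained peptide's
group means and variances balanced, which the kinase statistic below
requires. The thresholds are configurable because the source procedure
names the rule but not its cutoffs.

## From peptides to kinases

Candidate upstream kinases per peptide come from a homology-score table
(PhosphoNET-style score and per-peptide rank) plus in-vitro-confirmed
kinase–substrate pairs, which carry rank 0. Retention is

> in-vitro, **or** score > 300 **and** 1 ≤ rank ≤ 12,

with both inequalities strict at the boundary (a score of exactly 300 or a
rank of 13 is excluded). "Top 12" is read per peptide, matching how scores
are queried per phosphorylatable residue; ranks are taken as given, never
recomputed. The upstream >90%-homology sequence matching that builds the
candidate table queries a proprietary database and is an input here, not
re-implemented.

For kinase $K$ with retained peptides $i = 1..n$, the **Mean Kinase
Statistic** is

\[ \tau_K = \frac{1}{n} \sum_{i=1}^{n}
   \frac{\bar P_{i1} - \bar P_{i2}}{\sqrt{s_{i1}^2 + s_{i2}^2}} \]

with group 1 the condition of interest, so $\tau_K > 0$ means higher
activity in the condition. Group variances use the unbiased ($n-1$)
denominator. A peptide with $s_{i1}^2 + s_{i2}^2 = 0$ has no defined term
and is dropped from the average (an explicit choice; the source gives no
rule). A group of size one contributes variance 0; a 1-vs-1 design is fully
degenerate and yields a missing statistic.

Two permutation summaries qualify $\tau_K$:

* **significance** — permute sample labels, recompute $\tau$; measures
  dependence on the experimental grouping. When the number of distinct
  label assignments is ≤ `n_perm` (e.g. 70 for 4 vs 4), exhaustive
  enumeration replaces sampling and the p-value is an exact proportion.
  Sampled p-values use the add-one correction so $p = 0$ is impossible.
* **specificity** — keep the true labels, redraw same-size peptide sets
  from the whole QC-passing pool; measures dependence on the particular
  peptide→kinase mapping, i.e. distinguishes a kinase-specific shift from
  an array-wide one.

Comparisons are two-sided on $|\tau|$; directionality is enforced
separately by the MKS > 0 requirement. The numeric form of the published
"scores" is not defined in the source; we use $-\log_{10}(p)$, chosen so
that the published decision threshold (Mean Final Score > 0.5) is
expressible on the same scale. The **MFS** is the specificity score alone
for singlicate designs (sample permutation carries no information there)
and significance + specificity otherwise. A kinase is **activated** when
MKS > 0 and MFS > 0.5, both strict. No multiple-testing correction enters
the call (none is applied in the source); a BH-adjusted significance p is
reported for information.

Each kinase's permutation stream is seeded from the master seed plus the
kinase id, so batch results are independent of kinase order and per-kinase
calls reproduce them exactly.

## Seed-network expansion

Activated kinases seed a sub-network on a user-supplied (SIF-style)
interaction edge list. Nodes outside the network are admitted one at a
time, preferring the candidate with the most edges to current members,
then most edges to the seed set, then the lexicographically smallest id.
("Connectivity to the initial seed nodes" is ambiguous between
edges-to-members and edges-to-seeds; both orderings are provided via
`tiebreak`, with members-first the default.) Sub-networks sharing a member
merge; expansion halts when all per-seed sub-networks have merged
(*intersected*), when one more admission would reach `max_nodes = 50`
members (*size_limit*; the cap is exclusive, so finished networks always
have < 50 nodes), or when no outside node touches a member (*exhausted*).
The network is named by its most interconnected member (highest degree in
the induced subgraph; ties favour seeds, then lexicographic id). Candidate
nodes are not restricted to kinases: literature interaction networks
include adaptors and substrates, and the expansion rule is agnostic to
node type. Interaction-type labels (positive / negative /
context-dependent) are carried through for reporting and never affect
expansion.

## Phosphosites and pathway ranking

Site-level corrected reporter-ion intensities (log2) are compared between
groups per site. The source does not name its test; the default is Welch's
t with BH adjustment at FDR < 0.05, with Student's pooled t and raw-p mode
available — neither variant is claimed to be the original criterion.
"Increased" means significant with a higher condition mean. Pathways are
then ranked by the number of *distinct* differential sites catalyzed by at
least one member kinase — a transparent substrate count, not an enrichment
statistic; a site whose kinases span several pathways supports each once,
and sites with no experimentally defined catalyzing kinase support none.

## The synthetic generator

All of the above is exercised on generated data with known truth, because
the original raw array signals are not deposited in reusable tabular form.
The generator's defaults *are* the study design: 144 peptides, exposures
{10, 20, 50, 100, 200} ms, 4 vs 4 samples, 50 kinases with 6–12 candidate
peptides each drawn from the shared pool, planted effects of 1.5 pooled SD.

The signal model is `intercept + slope·t + N(0, noise_sd·t)`: noise SD
proportional to exposure, so that long exposures are not artificially
over-weighted and the implied slope noise is exposure-free. No public
distributional description of spot signals exists; this linear-plus-noise
model is a stand-in and is labelled as such. Saturation is not simulated.
Baseline slopes are uniform on 0.05–0.5 signal units/ms (reduced values
≈ 2.3–5.6, a plausible log2 range), and `noise_sd = 0.005` puts most
peptides above the default QC r² threshold while letting a few fail —
realistic attrition. Planted kinases have the slopes of *all their
retained peptides* multiplied in the condition group so that the reduced
value shifts by `effect_size ×` the per-peptide value SD (delta method on
`log2(100·slope)`); with `noise_sd = 0`, the value SD is 0 and a planted
"effect in SD units" is correctly zero. Each generator op draws from its
own RNG stream derived from the master seed and a stage key, so adding a
generator never perturbs another's output.

Candidate tables spread scores across the 300 boundary and ranks over
1–20, with ~10% in-vitro (rank 0) rows; every kinase is guaranteed at
least one retained candidate so that all 50 kinases are scoreable in every
run. Interaction graphs are spanning-tree-plus-random-edges, hence
connected by construction. Phosphosite tables plant a positive shift on
every site catalyzed by a kinase of a planted pathway.

What the generator does **not** emulate: spatial artefacts and saturation,
correlated peptide families, heavy-tailed signal noise, missing spots, and
TMT reporter-level effects (site-level intensities only). Tests passing on
this generator validate the *procedure* — its algebra, calibration and
determinism — not the biology of any particular dataset.

## Numerical and design choices

* Exposure-slope r² of a zero-variance series is reported as 0 (undefined
  ratio), which fails any positive QC threshold.
* Permutation comparisons use `|τ_perm| ≥ |τ_obs| − 10⁻¹²` so the identity
  assignment always counts as at least as extreme.
* An observed statistic that is undefined (all peptide terms dropped)
  yields permutation p = 1 — no evidence — while the kinase's MKS is
  reported missing and it is never called activated.
* Replicate spots of one peptide on an array are fitted separately and
  averaged, with a message.
* Problem sizes in the test-suite calibration runs: 200 replicate
  null datasets and 50 planted datasets at full design scale (144
  peptides, 50 kinases, 1000 permutations — exhaustive mode engages at
  70 assignments for 4 vs 4); these sizes give standard errors well below
  the asserted margins.

## Calibration results and a known limitation

Under the null (no planted effect) the exhaustive significance p-values
are uniform (KS test over 200 kinase-replicates; note that exact 4 vs 4
p-values live on a 35-point grid, so a KS test pooled over tens of
thousands of dependent, discrete p-values would reject on discreteness
alone — the calibration claim is per kinase-replicate). The fraction of
kinases called activated under the null is ≈ 0.28, consistent with — and
below — the rate the −log10 scale implies for the published rule:
$P(\text{MKS}>0) \cdot P(p_{\text{sig}} p_{\text{spec}} < 10^{-0.5})
\approx 0.34$ for independent uniform p-values.

This is the important caveat: **MFS > 0.5 is a permissive threshold.** At
planted effects of 1.5 pooled SD the activated call recovers essentially
all planted kinases (recall ≈ 0.98 over 50 replicates), but precision is
low (≈ 0.2): null kinases pass the 0.5 cut at the substantial base rate
above, and kinases sharing shifted peptides with a planted kinase inherit
part of its signal — with 50 kinases drawing 6–12 candidates from a shared
144-peptide pool, overlap is unavoidable, exactly as on the real array
where one peptide maps to many candidate kinases. Users who need a
precise list should raise `mfs_min` (e.g. 1.3 ≈ joint p < 0.05) or filter
on the BH-adjusted significance column; the default reproduces the
published rule, not a high-precision one.

The phosphosite arm is exactly calibrated under the generator's
equal-variance normal null with the pooled t (empirical call rate 0.049 at
α = 0.05, raw p). Welch's test — the safer default for real, possibly
heteroscedastic data — is mildly conservative at n = 4 vs 4 (empirical
0.041), a known property of the Welch–Satterthwaite approximation at tiny
sample sizes.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(planted_kinases = 5, seed = 42)
run <- run_pipeline(cfg, n_perm = 1000)
run
tidy(run$scores) %>% head(6)
autoplot(run$scores)
run$truth$planted_kinases
glance(run$network)
run$ranking
```

The activated list puts the five planted kinases at the top (highest MFS);
the seed network reports its naming node and halt reason; the pathway
table counts differential phosphosites per pathway, top-ranked first.
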