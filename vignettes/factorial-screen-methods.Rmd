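---
title: "Methods: factorial screening of differentiation conditions with digital mRNA counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial screening of differentiation conditions with digital mRNA counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factoscreen)
```

# The problem

Chondrogenic differentiation of mesenchymal stromal cells (MSCs) in 3D
culture is driven by soluble factors — TGFβ superfamily ligands,
dexamethasone (DEX), and sometimes FGF2 or IGF1 — that are usually studied
one at a time. A two-level full factorial ("quality-by-design") screen
instead tests every on/off combination of k factors simultaneously, which
makes main effects *and* interactions estimable without confounding. Read
out with a digital mRNA counting panel (NanoString nCounter-style), a
single screen yields a gene × condition count matrix from which the
quality of each differentiation cocktail can be scored.

`factoscreen` implements that analysis end to end: design construction,
count normalization, marker-panel scoring, factorial inference, moderated
differential expression, condition-level gene-set enrichment, and PCA —
plus a negative-binomial simulator that generates screens with known
ground truth, so that every stage has a parameter-recovery test surface.

# The screening design

Five factors (TGFβ1, DEX, BMP2, IGF1, FGF2) form a full 2^5 factorial arm:
32 conditions, one per factor subset, each run in three donors at days 1
and 7, with untreated day-0 cells as a reserved pseudo-condition. The
registry numbers the factorial conditions by the rule

    id = 32 − (16·TGFβ1 + 8·FGF2 + 4·DEX + 2·IGF1 + 1·BMP2)

so condition 32 is the factor-free basal medium (bCDM), 16 is TGFβ1 alone,
12 is TGFβ1+DEX, 11 is TGFβ1+DEX+BMP2, and so on. This weighting is the
unique one consistent with every numbered condition pair used in the
screen's key contrasts (11 vs 12 and 15 vs 16 differ only in BMP2; 12 vs
16 and 11 vs 15 only in DEX; 9 vs 11, 2 vs 4 and 25 vs 27 only in IGF1).
Because the assignment of ids 33–48 to the secondary arms is a layout
convention rather than a derivable fact, the registry fixes a deterministic
order — TGFβ2/TGFβ3 isoform conditions (each alone, +DEX, +DEX+BMP2), then
BMP4/BMP6 isoform conditions (each alone, +TGFβ1, +TGFβ1+DEX), then four
seeding densities (1.25, 2.5, 5, 20 ×10^6 cells/mL under TGFβ1+DEX+BMP2,
completing a log2-spaced series around the factorial arm's 10^7) — and
accepts a user override (`build_condition_registry(extra_conditions = )`,
or `registry_file` in the run configuration).

The coded model matrix uses ±1 factor columns with interaction columns as
element-wise products; over a complete replicate all effect columns are
mutually orthogonal and sum to zero, which is what makes the Yates
contrast and least-squares routes exactly interchangeable (a property the
test suite checks to 1e-10).

# The synthetic data generator

No public raw data accompanies screens of this design, so the simulator is
a first-class module, not a fixture. Counts are drawn as

    count ~ NB(mean = lane × donor × 2^(baseline + Σ planted effects), size = 1/dispersion)

* **Lane factors** are lognormal per sample (default sd 0.2 on the log
  scale) and multiply *all* probe classes, including spike-ins — which is
  exactly what makes them identifiable from the positive-control series
  alone.
* **Donor effects** are per-(gene, donor) log2 offsets (default sd 0.15),
  the biological replicate variation that donor blocking later removes.
* **Dispersion** defaults to 0.05 for measured genes, a typical
  overdispersion for digital counting of biological replicates;
  `dispersion = 0` is the deterministic `round(mean)` limit used by exact
  tests. Spike-in controls carry only technical dispersion (default 0.005,
  ~7% CV — synthetic RNA has no biological variance). Negative controls
  have a small constant mean (default 2 counts).
* **Housekeeping candidates** get zero planted effects and a reduced
  variance multiplier (default 0.25 on dispersion and donor sd), making
  reference-gene recovery a testable claim rather than an assumption.
* **Planted effects** add log2 shifts to target genes in all samples whose
  condition activates a term — a factor, an interaction such as
  `TGFB:DEX` (active when both are present), or `day`. Isoform-level terms
  (`TGFB1`, `BMP4`, ...) and family-level terms (`TGFB`, `BMP`) are both
  supported; the paper-like preset uses family terms so the isoform arm
  behaves like the factorial arm, matching the observation that isoforms
  act similarly.

The **paper-like preset** plants the qualitative structure this kind of
screen reports: positive TGFβ/DEX/BMP effects on the 14 wanted
hyaline-cartilage markers with a positive TGFβ×DEX synergy and a damping
TGFβ×BMP interaction; TGFβ- and BMP-driven induction of the 11 unwanted
hypertrophy/bone/fat markers that DEX and the TGFβ×BMP interaction cancel
in the combined conditions; a negative FGF2 effect; an exactly null IGF1;
a strong TGFβ-specific COL10A1 induction; a BGLAP-like filler gene shut
down by DEX everywhere; blocks of filler genes responding to single
factors (many for TGFβ and DEX, few for BMP — so that adding BMP2 on top
of TGFβ1+DEX changes little); and a shared time-in-culture program with
day-7 effects twice the day-1 effects. Effect sizes within a marker set
are spread by deterministic per-gene multipliers (0.6–1.4× the nominal
value) so that rank-based statistics do not saturate identically across
conditions. Per-gene baselines are lognormal around 400 counts (sd 1.5
log2 units).

What the generator does **not** emulate: probe-level chemistry
(cross-hybridization, binding density), per-gene dispersion heterogeneity
(a single global dispersion is used), batch structure beyond lanes and
donors, and density-arm dose–response (density conditions inherit only
their factor composition). Passing tests therefore demonstrate that the
pipeline recovers the generative structure of this model — not that real
screens satisfy the model.

# Normalization

The chain is: spike-in lane scaling → reference-gene selection →
geometric-mean reference normalization → generalized log.

1. **Lane scaling.** Each sample is multiplied by
   (grand geometric mean of positive-control geometric means) / (its own
   positive-control geometric mean), equalizing spike-in levels across
   lanes. Geometric means are the platform convention; zeros are an error
   unless a pseudo-count is configured (the pipeline default adds 0.5 only
   when zeros occur, and records the choice in the provenance).
2. **Reference selection** uses a NormFinder-style variance decomposition
   on log-scale candidate expression: within each sample group the
   intra-group variation σ̂ comes from the residuals of the additive
   gene + sample model with the multi-candidate correction k/(k−1); the
   inter-group variation d̂ is the group-specific deviation of the
   candidate's centered mean, shrunk toward zero by its sampling variance;
   stability is ρ = mean over groups of (|d̂| + σ̂), lower = more stable.
   The default grouping variable is day — the only grouping present in
   all arms — and the default is the five most stable candidates, ties
   broken lexicographically so selection is deterministic.
3. **Reference normalization** rescales each sample so the geometric mean
   of the chosen references equals its across-sample grand geometric mean.
4. **Generalized log.** h(x) = log2((x + √(x² + c²))/2): strictly
   increasing, asymptotically log2(x) for x ≫ c, bounded variance near
   zero. The offset c defaults to the mean of the negative-control counts
   (policies: `negctrl`, `quantile`, `fixed`). This reproduces the
   defining behavior of variance-stabilizing log transforms for count
   panels without binding the pipeline to any specific fitted
   transformation; the offset policy is configuration, and the chosen c is
   recorded. Genes whose median count falls below mean + 2 sd of the
   negative controls are flagged `below_background` but never filtered —
   background subtraction is deliberately not performed.

The whole chain is equivariant to rescaling any single sample: lane
scaling undoes the rescaling exactly, leaving only the global
grand-geometric-mean shift shared by every entry (checked to 1e-8).

# Marker scoring

The wanted set (ACAN, BGN, COL11A1/2, COL2A1, COL9A1/2/3, COMP, DCN,
FMOD, HAPLN1, LUM, MATN3) marks hyaline-cartilage ECM; the unwanted set
(ALPL, COL10A1, COL1A1/2, COL3A1, OGN, PPARG, RUNX2, SP7, SPP1, VCAN)
marks hypertrophy, bone, fat and fibrocartilage. For display and ranking,
replicate samples are first collapsed to condition means, then each gene
is studentized (z-scored) across conditions; a condition's wanted
(unwanted) score is the mean studentized value over the set. Conditions
are ranked by descending wanted score with a documented deterministic
tie-break (ascending unwanted score, then condition id). Studentization
is per day — day-1 and day-7 panels are standardized separately, each
being its own comparison set — with pooling available by passing both
days. sd-degenerate genes map to zero rows with an audit flag rather than
NaN so set means stay defined. Day-1 vs day-7 ranking agreement is
Spearman's rho with average-rank ties (exact permutation p for n ≤ 9,
t approximation otherwise); lysate-vs-RNA style profile agreement is
Pearson r with r².

For factorial inference the response is the *per-sample* (condition ×
donor) marker-set mean on the normalized log2 scale — one observation per
replicate, unlike the collapsed display scores.

# Factorial inference

Effects are estimated on the complete 2^5 arm with donor as a fixed
block: the effect of a term is the high-level mean minus the low-level
mean, computed both as twice the least-squares coefficient of the ±1
column and as the Yates contrast divided by 2^(k−1)·replicates (the two
must agree to numerical precision). Inference is univariate per response
(wanted, unwanted): this matches the displayed outputs of such screens —
normal plots and effect tables per response — and four- and five-way
interactions are pooled into the error, giving 67 residual df at three
donors. The standardized effect t = effect/SE uses the blocked residual
mean square; normal-plot coordinates pair ordered standardized effects
with normal quantiles at (i − 0.375)/(n + 0.25). α defaults to 0.05 with
no multiplicity correction across the 25 terms, mirroring standard
factorial-screening practice. A Box-Cox profile-likelihood transform
(grid [−2, 2], step 0.01) is available when residual normality needs
repair, and 2×2 interaction summaries report cell means and the synergy
index (both − a − b + neither).

# Differential expression

Gene-wise contrasts fit normalized log2 expression on donor + condition
indicator for the two conditions of interest (day 7 by default, since the
key published contrasts are late-timepoint). Variances are moderated by
the empirical-Bayes scheme of the moderated-t literature: s² ~ s0²·F(df,
d0) with (d0, s0²) estimated by matching moments of log s² via
digamma/trigamma inversion; the posterior variance (d0·s0² + df·s²)/(d0 +
df) yields a moderated t on df + d0 degrees of freedom. The
implementation is authored here and is verified in the test suite against
`limma::squeezeVar` to 1e-8 — the installed package serves as the
independent oracle, never as the implementation. Benjamini–Hochberg
adjustment is applied per contrast across genes (screens report
per-comparison gene counts), and a gene is called significant iff
|log2FC| ≥ 1 (twofold on the log2-like scale) and q < 0.05.

Two consistency analyses build on the calls: the *uniform single-factor*
sets (genes called significant versus baseline condition 32 in **all 16**
conditions containing a factor, with the same direction in all 16 — a
deliberately strict rule) and contrast overlaps (shared significant genes
between two contrasts, split by direction).

# Enrichment and PCA

Condition-level gene-set enrichment is a competitive mean-rank test:
Wilcoxon rank-sum of the set's moderated t statistics (condition vs
baseline 32) against all other genes, using the normal approximation
without continuity correction so p-values depend only on ranks and are
invariant to monotone transforms of the statistics. This choice —
competitive and deterministic rather than rotation- or permutation-based —
was made because the screen's enrichment engine variant is not
reconstructible from its outputs; a self-contained alternative would be a
configuration extension. BH runs across the 31 non-baseline conditions
within each set, and a condition is flagged when its wanted FDR < 0.05
while its unwanted FDR is not.

PCA is the gene-centered SVD of the selected samples (via `prcomp`), with
a fixed sign convention (the dominant loading of each component is
positive) so scores are reproducible across platforms. Heatmap layout is
deterministic: wanted then unwanted markers alphabetically, columns in
wanted-rank order.

# Numerical choices and degenerate inputs

* Yates/regression agreement tolerance 1e-10; reference-geomean equality
  1e-12; chain equivariance 1e-8.
* Saturated (noise-free) factorial fits: residual sums of squares below
  1e-20 × the response scale are treated as exact zero, zero effects then
  get t = 0, p = 1 and nonzero effects t = ±∞.
* `moderate_variance`: identical variances → d0 = ∞ (posterior = s0²);
  non-positive variances are floored at half the smallest positive value
  for hyperparameter estimation only.
* Stability shrinkage guards 0/0 (all-constant candidates score ρ = 0 and
  win on the lexicographic tie-break).
* Geometric means with zeros error out unless a pseudo-count is
  configured; the pipeline logs any pseudo-count use.
* The trigamma inversion is a Newton iteration with asymptotic fallbacks
  for extreme arguments.

# Test-suite problem sizes

The simulation-based checks use sizes chosen to make Monte-Carlo error
small relative to the asserted bands: 400 null screens (40-gene panel,
factorial arm, day 7) for type-I calibration of the 25 factorial terms;
200 null screens for FDR control of the moderated contrast; 1000 draws
for set-test uniformity; 50 seeds for fold-change recovery; 20 seeds for
moderation-hyperparameter recovery (2000 genes each); 10 seeds for lane
factors (48 samples each); 20 full 364-gene paper-like screens for the
qualitative pattern rates. For the per-term type-I check, note that 400
screens leave ±1.8 binomial SD of pure counting noise on the [0.03, 0.07]
band itself, so the suite asserts the pooled rate (10,000 term-level
tests) within the band and each individual term within its 99.9% binomial
envelope — a family-wise-controlled test of the same hypothesis, designed
before the simulations were run.

# Known limitations

* The simulator's global dispersion and gene-wise independence understate
  the correlation structure of real panels; FDR calibration results are
  therefore about the procedure under the generative model.
* Enrichment p-values near rank saturation (every set gene above every
  non-set gene) compress; condition ordering then relies on the unadjusted
  p as a secondary sort key.
* The isoform/density arm numbering is a convention (see above) and must
  be overridden by users whose plate layout differs.
* Density conditions carry no planted dose–response; the density arm is
  exercised structurally, not biologically.
* No probe-level QC (binding density, field of view) and no fractional
  factorial designs.
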