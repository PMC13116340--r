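---
title: "Methods: cross-docking panel analysis with dockpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-docking panel analysis with dockpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockpanel)
```

## The problem

Hedgehog-pathway modulators developed against Smoothened (SMO) frequently
engage two early-embryonic kinases — casein kinase 1 delta (CK1δ) and the
mitochondrial quality-control kinase PINK1 — with affinities comparable to
or stronger than their intended target. dockpanel implements the
computational side of profiling that polypharmacology: it takes a
compound-by-target matrix of docking scores (kcal/mol, more negative =
stronger predicted binding), quantifies preferential binding to the
developmental kinases relative to a non-developmental control kinase
(TIE2/TEK), predicts CK1δ substrate phosphosites by cross-tool consensus,
integrates gene-symbol sets, and converts per-compound affinity profiles
into node-specific craniofacial phenotype hypotheses through an explicit
rule set.

## The affinity model and its statistics

A docking panel arrives as per-replicate scores. `aggregate_replicates()`
summarises each compound–target pair by the mean across replicates; the
replicate SD is kept and flagged when it reaches 0.15 kcal/mol, the
reproducibility bound expected of triplicate runs. Missing pairs are an
error rather than imputed: the analysis assumes a complete cross product.

Because every compound is docked against every target, target contrasts are
natural paired designs. `paired_comparison()` runs a two-sided paired
t-test on per-compound differences and reports the paired effect size
d~z~ = mean(diff)/SD(diff). The paper-style Cohen benchmarks (0.2 / 0.5 /
0.8) label the magnitude. We chose d~z~ rather than a pooled-SD d because
it matches the statistic actually tested; for within-compound contrasts a
pooled-SD d would mix between-compound spread into the denominator.
Family-wise control is plain Bonferroni, reported both as an adjusted α
(0.05/6 ≈ 0.0083 for the six pairwise target contrasts of a four-target
panel; 0.05/8 = 0.00625 for per-target class contrasts) and as adjusted
p-values min(1, m·p). Shapiro–Wilk p-values on the differences and
Brown–Forsythe (median-centred Levene) p-values accompany the tests but
never gate them; with zero-variance differences the functions raise an
error instead of fabricating a p-value, so simulation suites cannot be
silently corrupted.

Per-compound selectivity is summarised by two indices:

* **SI** = (Affinity~CK1δ~ + Affinity~PINK1~)/2 − Affinity~TIE2~ — more
  negative means stronger preferential binding to the developmental
  kinases;
* **SPI** = |Affinity~CK1δ~ − Affinity~PINK1~| — low values indicate
  balanced dual engagement.

`si_panel_test()` is the one-sample t-test of mean SI against zero.
`risk_rank()` orders compounds by the combined PINK1 + CK1δ affinity sum.
When a reference ordering is supplied and disagrees with the computed sums
(as the literature ordering does on the printed per-compound values:
taladegib sums to −19.7 but purmorphamine to −20.8 kcal/mol), the function
keeps the computed ranking and emits a warning; surfacing rather than
resolving such discrepancies is part of the function's contract.

Outlier screening fits the additive two-way model
score = μ + compound + target by least squares and screens the residuals
(|z| > 3; Cook's distance > 4/n, the usual convention). Screening raw
scores instead would flag every strong binder at a strong target, because
target-level mean shifts are the panel's main effect, not anomalies. A
numerically exact additive matrix is reported as outlier-free. Whether the
original analysis screened per-target regressions or the full matrix is
not stated anywhere we could find; the additive-model choice is ours.

Hierarchical clustering uses Euclidean distance with complete linkage on
rows and columns. Stability is the co-clustering fraction: columns are
resampled with replacement (1000 bootstrap iterations by default) and each
compound pair is scored by how often it lands in the same cluster when the
row tree is cut at k = 2 (configurable). The cut-based co-clustering
fraction was chosen because it is the simplest reproducible stability
statistic once an iteration count is fixed. Heatmap binning uses half-open
intervals (low, high] over breaks (−12, −10, −7, −4, −1) kcal/mol with
clamping outside the range, so a score of exactly −12 joins the strongest
bin and binning is monotone.

## Phosphosite consensus and CK1 motif logic

Seven prediction tools (coded KP, NP, PP, GP, PN, PS, UP) each contribute a
list of predicted phospho-serines/threonines; tyrosines are excluded.
`build_consensus_matrix()` compiles them into a residue × tool boolean
matrix. Three of the tools (PP, PS, UP) do not resolve CK1 isoforms; with
the isoform filter on, their ticks survive only at positions carrying a
canonical CK1 substrate motif, mirroring the manual motif-consistency
filtering applied to generic CK1-family predictions. `call_consensus_sites()`
votes: support by ≥ 3 of the 7 tools makes a high-confidence consensus
site; sub-threshold sites are recorded but flagged `consensus = FALSE`.

The motif scanner recognises the two canonical CK1 substrate classes:

* **primed** — S/T with an S or T three residues upstream. True priming
  requires prior phosphorylation, which sequence alone cannot establish, so
  any upstream S/T counts as a potential primer; this is the same
  approximation the sequence-based tools themselves make.
* **acidic cluster** — S/T with ≥ 3 Asp/Glu among the five residues
  immediately upstream. The literature never formalises "acidic cluster";
  both the window (5) and the count (3) are configurable package decisions.

Positions matching both classes report as primed. `classify_sites()` calls
a site *primary* when it is a consensus call on a canonical motif, else
*secondary*, and attaches the ±7-residue context window (clipped at the
termini).

The package ships `synthetic_smo_sequence()`, a 787-residue synthetic
stand-in with valid motif contexts planted at T593, S615 and S751, so the
published cross-tool matrix for human SMO can be rebuilt and re-voted
end-to-end without the (undeposited) real sequence. It reproduces only the
features the voting depends on and is labelled synthetic everywhere.

## Gene-set integration

`venn_decompose()` assigns every member of the union of up to 10 sets to
exactly one exclusive region, so region counts always partition the union —
an identity the tests exercise on randomly generated universes.
`run_integration()` executes an ordered list of stages (intersection,
union, filter-by-set) whose operands may reference earlier stage results,
with a per-stage cardinality trace. Symbols are compared case-insensitively
after uppercasing; no alias or identifier mapping is attempted, because
that would require live database access. `subset_fraction()` rounds
half-away-from-zero, which is what turns 255/474 = 53.797…% into the
reported 54%.

## Node assignment rules and the decision tree

`assign_nodes()` applies the affinity-tier rules to a compound's scores at
the three signaling nodes (SMO, CK1δ, PINK1):

1. strong binding (score ≤ −8.0 kcal/mol) includes the compound on that
   branch unconditionally;
2. moderate binding (−8.0 < score ≤ −7.0) includes it only where the node
   is dominant — within 0.05 kcal/mol of the compound's most negative
   score;
3. weak binding (> −7.0) excludes the node unless no stronger affinity
   exists anywhere, i.e. all three nodes are weak, in which case the
   dominant weak node(s) are kept.

The boundary conventions are: exactly −8.0 is strong (the rule text is
explicit), exactly −7.0 is moderate (by complement). Dominance means the
most negative score — stronger predicted binding — and ties within 0.05
kcal/mol (half a reporting decimal) include every tied branch. The weak
fallback guarantees a non-empty assignment for every compound. Rule
applications are traced per node so each inclusion or exclusion is
explainable. A mechanism-override mode can additionally force a compound's
annotated primary target onto its branch; this curation overlay exists
because some published hand assignments (e.g. a classic SMO antagonist kept
on the SMO branch despite a moderate, non-dominant SMO score) are not
derivable from the stated rules. Pure-rule mode is the default.

`predict_phenotypes()` takes the union of the catalog phenotype terms of
the assigned nodes — the composite phenotype of a multi-node compound is a
superposition of node-specific outcomes — with each term carrying its
anatomical region and embryonic-day vulnerability window (SMO E8.5–E10,
CK1δ E9.5–E11, PINK1 E10–E12 in the default catalog).
`build_decision_tree()` assembles the root → branch → leaf DAG with one
leaf per (compound, node, phenotype term) carrying the compound's affinity
at that node; acyclicity is verified on construction.

## What the synthetic generator emulates

`panel_generator_config()` encodes the study conditions of the
17-compound × 4-target panel: per-target means CK1δ −8.34, PINK1 −8.80,
SMO −7.56, TIE2 −6.76 kcal/mol; between-compound SDs 1.06/1.19/0.81/0.76;
9 upstream + 8 downstream compounds; triplicates with 0.05 kcal/mol
replicate noise. Scores decompose as

> score = target mean + class offset + compound effect + target-specific
> deviation + replicate noise,

with the compound effect u~i~ ~ N(0, 0.6²) shared across targets. That
shared effect induces the within-compound correlation that makes the paired
target tests more powerful than unpaired ones — the central feature of the
paired design. The configured `target_sds` are treated as the *total*
between-compound SD, so the target-specific deviation gets SD
√(target_sd² − 0.6²); a compound SD of 0.6 was chosen as a plausible
mid-range split between shared and target-specific variation and is not
tuned. The only class offset in the default is at PINK1 (1.11 kcal/mol,
upstream stronger — the one between-class difference reported), weighted by
class sizes so the overall PINK1 panel mean is unchanged; this offset adds
between-class spread on top of the configured PINK1 marginal SD, which we
accept because the printed class gap is the more specific constraint. Two
inconsistencies in the source reporting are noted, not resolved: the SMO
panel mean appears both as −7.56 ± 0.81 and −7.50 ± 0.97, and the CK1δ SD
as both 1.06 and 0.86; the generator uses the body-text values (−7.56,
1.06). All generators take explicit seeds and restore the caller's RNG
state; identical seeds give byte-identical outputs.

What the generator does **not** emulate: docking physics, pose geometry,
score–structure relationships, heavy-tailed or correlated replicate errors,
and any compound-specific binding signatures beyond the additive structure
above. Replicate noise is Gaussian and independent, consistent with the
symmetric, sub-0.15 kcal/mol replicate SDs and all-passing Shapiro–Wilk
checks of the original panel. Passing tests on generated data therefore
demonstrate the correctness of the statistical machinery under the stated
model, not the validity of docking scores as affinity estimates.

## Numerical choices and degenerate inputs

* Zero-variance paired differences, constant samples and single-member
  classes raise errors rather than returning fabricated p-values.
* A numerically additive matrix (residual SD below 10⁻⁸ of the score SD)
  yields an empty outlier report instead of z-scores built from rounding
  noise.
* A single replicate has SD 0 by convention and never trips the QC flag.
* kcal/mol values are rounded to 2 decimals and p-values to 3 significant
  digits only at the I/O boundary; internal computation is full precision.
* Exact ranking ties break lexicographically by compound id and are
  flagged.
* Bootstrap clustering and all generators are deterministic given a seed.

## Problem sizes used by the test and acceptance suites

Simulation-based checks run at sizes chosen to keep Monte Carlo error well
below the tolerances they assert: 10,000 null panels (n = 17) for the
paired-test type-I error (tolerance 0.05 ± 0.006), 200 seeds for panel
mean recovery at 3·SE, 100 seeds for the QC-rate and false-outlier-rate
properties, a 15³ score grid for the assignment-rule oracle, and 100
random universes for the Venn partition identity.

## Known limitations

* The full 68-cell docking matrix behind the original panel statistics is
  not public; exact printed p-values (e.g. 3.6 × 10⁻⁶) are therefore not
  reproducible and are not targeted. Only arithmetic that the printed
  values determine (mean differences, thresholds, fractions, index values)
  is checked exactly.
* One printed mean difference (SMO − TIE2 = −0.84 kcal/mol) is not
  consistent with any pair of the printed panel means (−0.80/−0.74); it is
  surfaced here and excluded from checks.
* The motif grammar covers the two canonical CK1 substrate classes only;
  non-canonical acidic patterns recognised by individual tools are out of
  scope.
* Phenotype predictions are rule-based hypotheses inheriting all caveats of
  docking scores; nothing here is an observed outcome.
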