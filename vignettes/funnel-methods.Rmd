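---
title: "Methods: the GWAS-to-repurposing candidate funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the GWAS-to-repurposing candidate funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasfunnel)
```

## The model

The package prioritizes drug-repurposing candidates from case–control GWAS
summary statistics. The underlying reasoning is epidemiological, not
mechanistic: a gene is a candidate when (i) a variant associated with
disease risk is also an expression quantitative trait locus (eQTL) for the
gene in a disease-relevant tissue, and (ii) a drug already exists whose
action *antagonizes* the expression effect of the risk allele.

Writing OR for the per-allele odds ratio of the effect allele and
$d \in \{+1, -1\}$ for the sign of the expression change per copy of the
same allele, the mechanism call is:

* re-orient to the risk allele: if OR < 1, replace (OR, d) by (1/OR, −d).
  This is the unique involution consistent with the fact that an
  association is a statement about an allele pair — re-labeling the
  reported allele must not change any conclusion;
* the risk allele raising expression ($d_{risk} = +1$) calls for an
  **inhibitor** of the target; lowering it calls for an **activator**;
* OR exactly 1 carries no risk direction and is rejected (in the full
  funnel such supporting pairs are dropped with a warning).

Assumptions worth making explicit: eQTL direction and OR must refer to the
same allele, so eQTL records carry their own effect allele and
`harmonize_direction()` negates the direction when that allele equals the
GWAS other allele. Records without an effect allele cannot be harmonized:
the default (`harmonization = "strict"`) refuses them; `"assume"` treats
them as already oriented, which is only safe when both tables were built
against the same reference. The approach also assumes a single dominant
direction of effect per gene; when different supporting SNPs imply
conflicting mechanisms the gene is flagged discordant and excluded by
default (`discordant_policy = "majority"` keeps the majority call instead,
with exact ties still excluded). Conflicting calls can arise in real data
through distinct causal variants or tissue heterogeneity; excluding such
genes is the conservative choice for a pipeline whose output is a drug
recommendation.

## The funnel and its parameters

`run_funnel()` executes, in order: significance filter, annotation,
CNS-eQTL intersection, mechanism inference, drug match, ortholog filter,
optional blood–brain-barrier filter. Parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 10⁻³ | association p-value threshold, strict `<` |
| `tissues` | 13 CNS names | tissues defining the eQTL restriction |
| `min_identity` | 40 (%) | ortholog identity threshold, inclusive `≥` |
| `approved_only` | TRUE | restrict drug matches to approved drugs |
| `harmonization` | "strict" | policy for unharmonized eQTL records |
| `discordant_policy` | "exclude" | conflicting mechanism calls |
| `bbb_filter` | FALSE | require a brain-permeable matched drug |

On `alpha`: descriptions of this kind of reanalysis quote both "p < 0.01"
and "χ² p < 10⁻³" for the same selected-SNP count; the two cannot be
reconciled from the outside, so the package makes `alpha` an explicit
parameter, defaults to the stricter 10⁻³, and treats the choice as part of
the configuration echo in every report rather than something to resolve.

Blood–brain-barrier permeability is consumed as a precomputed per-drug
annotation (`bbb` table) — the package does not predict permeability.

**Ranking.** Survivors are ordered by number of supporting SNP–eQTL pairs
(descending), best supporting association p-value (ascending), promoter
distance from the gene's own supporting SNPs (ascending), then gene id.
The promoter-distance key operationalizes "closer to the target promoter
scores higher" as a plain ascending sort; no numeric transform is applied
because none is defined for it.

**Stage counts.** The first stages count SNPs, later stages count genes,
mirroring how such funnels are reported (thousands of SNPs down to a
handful of genes). The counts are non-increasing whenever each SNP
supports at most a few genes relative to the SNP count; a pathological
input in which single SNPs regulate very many genes could make the gene
count exceed the preceding SNP count. The synthetic generator emits one
gene per eQTL record, so the monotone property is exact in all shipped
tests.

**Threshold monotonicity.** Enlarging `alpha` or the tissue set, or
lowering `min_identity`, never decreases the final candidate count *as
long as no gene's mechanism calls become discordant*: under the default
exclude policy, a newly admitted SNP with a conflicting call can knock out
a previously passing gene. This is a real property of the method, not an
implementation artifact. The property tests therefore generate tables that
are risk-consistent per gene (each gene's supporting SNPs imply one
mechanism), the regime in which monotonicity is a theorem.

## Coordinates and annotation

Gene models are BED-style, 0-based half-open; GWAS and eQTL positions are
1-based points. All conversion goes through one function pair
(`pos_1to0()`/`pos_0to1()`), tested in both directions. "Intragenic"
means inside the gene body `[start, end)` — introns and UTRs included —
which matches coarse gene-span annotation; exon-level or regulatory
annotation is out of scope. The promoter is the TSS point (`start` on +,
`end − 1` on −). A configurable upstream window (`upstream`, default
0 bp) widens the promoter to an interval, inside which the distance is 0;
it is off by default because no window width is canonical. All distance
ties break to the lexicographically smallest gene id, making every result
deterministic.

## The synthetic-data generator

`simulate_bundle()` emulates the statistical shape of the inputs:

* background association p-values uniform(0, 1]; background log-OR
  normal(0, 0.03), putting background ORs in the ≈1.03–1.04 band seen in
  underpowered complex-trait scans;
* planted SNPs: p ~ U(0, α/2), |log-OR| ~ U(0.15, 0.35) (sign random),
  placed in cis within 100 kb of the target gene's TSS;
* planted eQTL records get their direction by inverting the mechanism
  rule from the planted required action, so the planted gene passes by
  construction; background eQTL directions are fair coin flips, with the
  stated effect allele drawn from either GWAS allele;
* genes are non-overlapping by default (one slot per gene per
  chromosome); overlap stress-testing is done with hand-built tables in
  the unit tests;
* background rates (eQTL 0.05 per SNP, druggability 0.05 and ortholog
  0.05 per gene) give a joint background pass probability per gene of
  roughly 3×10⁻⁷ at the default scan size, so planted-truth recovery is
  clean by design, not by luck.

`simulate_events()` emulates a two-arm paralysis ("motility") assay:
exponential event times with a configurable hazard ratio, 90 subjects per
arm by default (matching a 30-worms-×-3-plates design), scored on a 2 h
observation grid with events recorded at the *right endpoint* of the
interval in which they occurred — the simplest convention for
interval-recorded observations; interval-censored likelihoods are out of
scope — and administratively censored at 30 h (baseline median 20 h).

What the generator does **not** emulate: linkage disequilibrium, realistic
minor-allele-frequency spectra, genotype-level data, population structure,
shared eQTL architecture across tissues, or correlated assay plates. Tests
passing on these bundles demonstrate that the pipeline's logic, joins and
orientation conventions are correct — not that the method has power or
calibration on real genotype data.

## Numerical choices

* Significance and identity thresholds: `p < alpha` is strict (a p-value
  exactly at the threshold is excluded); ortholog identity `≥` is
  inclusive (a pair at exactly 40.0% passes).
* Percent rounding is half-up (`round_half_up()`), matching how printed
  percentages like 47.71% or 0.4% are conventionally produced; base R's
  banker's rounding differs on exact ties.
* `fold_change()` defaults to magnitude orientation (max/min) so a
  swapped pair of group labels cannot silently invert a reported fold
  change; `"directed"` is available when the orientation is trusted.
* Mann–Whitney U: exact enumeration of the null distribution (ties
  included, via midranks) for n₁+n₂ ≤ 12; above that, the normal
  approximation with tie correction *and* continuity correction. The
  continuity-corrected form agrees with the exact branch to within about
  0.015 at the crossover size, against about 0.07 uncorrected, which is
  why it is the one used.
* Two-proportion χ²: continuity correction off by default (rounded
  published inputs cannot adjudicate the flavor), exposed as a flag; a
  zero margin returns p = 1 with a warning rather than NaN.
* "Student t-test" is taken at its word (pooled variance), with Welch
  available.
* Reports serialize the re-oriented odds ratio at 10 significant digits:
  OR → 1/OR is exact only to one unit in the last place in floating
  point, and bounding the printed precision keeps reports byte-stable
  under allele re-orientation.
* Degenerate inputs: `alpha = 0` yields an empty but well-formed report;
  an empty tissue set is an error (the filter would be vacuous); SNPs on
  chromosomes without gene models are classified intergenic with a
  warning.

## Test design and problem sizes

The suite checks every statistical routine against an independent oracle
(textbook formulas, brute-force enumeration, or the product-limit/log-rank
sums computed by explicit loops) on ≥ 100 random small instances each, and
checks null calibration — rejection rate at α = 0.05 over 5,000
simulations per test — at sizes where the asymptotic approximations are
conventionally adequate: 500 per group for the χ², 20 per group for the
t, 30 per group for the Mann–Whitney normal branch, 3 × 20 for
Kruskal–Wallis, and 50 per arm for the log-rank. Planted-truth recovery
runs 50 bundles of 10,000 SNPs × 500 genes with 1–3 planted candidates;
funnel monotonicity runs 1,000 randomized cases; allele-flip invariance
100 cases. An independent checker (plain loops over the raw tables,
sharing no code with `run_funnel()`) re-derives the planted truth per
seed.

## Known limitations

* The funnel operates on marginal summary statistics: no LD clumping,
  colocalization, or Mendelian randomization. A significant SNP that is
  an eQTL for a gene is treated as support for that gene even when the
  association and expression signals have different causal variants.
* The eQTL intersection counts genes given any supporting pair; when one
  SNP is an eQTL for several genes, all are carried forward.
* Mechanism inference uses only the *sign* of the expression effect;
  effect magnitudes, dose–response and tissue weighting are ignored.
* Drug matching is exact on the action vocabulary (inhibitor/activator/
  other); pharmacological subtleties (partial agonists, allosteric
  modulators) must be encoded upstream in the interaction table.
* Survival analysis treats interval-recorded paralysis times as exact at
  the interval's right endpoint; with 2–3 h grids and ~20 h medians the
  bias is small, but sub-interval resolution is not recoverable.
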