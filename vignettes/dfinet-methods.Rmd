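---
title: "Methods: mapping drug-food interactions at the molecular level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping drug-food interactions at the molecular level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfinet)
options(dfinet.quiet = TRUE)
```

`dfinet` infers which plant-based foods can interfere with drug
pharmacodynamics (therapeutic targets) and pharmacokinetics (metabolic
enzymes, transporters, carriers), starting from tabular inputs shaped like
the public food-compound, bioassay, drug-annotation, PPI and expression
resources. This vignette explains the model behind each stage, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not establish.

## The bioactivity model

A bioassay measurement is one observation of a compound against a protein
with an endpoint (Ki, Kd, IC50, EC50, inhibition, potency). All affinity
endpoints are normalised to nM on load and the potency cutoff of 50 uM is
carried internally as 50,000 nM, so a single scale serves every comparison.
A measurement is *positive* when its endpoint-specific criterion holds, all
strictly:

| endpoint            | positive when        | config default        |
|---------------------|----------------------|-----------------------|
| Ki, Kd, IC50, EC50  | pchembl > 6          | `pchembl_min = 6`     |
| inhibition          | value > 30%          | `inhibition_min_pct`  |
| potency             | value < 50 uM        | `potency_max_uM`      |

(pchembl is the negative log10 molar affinity; pchembl 6 is 1 uM.) Rows
missing the field their endpoint needs count as negative. Repeated
measurements of one (compound, protein) pair collapse to the frequency of
positive measurements, and only pairs with frequency strictly above
`frequency_min = 0.5` are confident interactions. The representative
affinity of a pair is the **geometric mean** of its positive affinity
values: affinities span orders of magnitude, so all summaries here live on
the log10 scale (a plain mean would be dominated by the weakest binder).
Ki/Kd/IC50/EC50 are pooled on the common nM scale, mirroring the single
pchembl filter that admits them.

A food compound is *active* on a protein when its representative affinity
falls **within the activity range of the drugs** on that protein. We read
"within the range" one-sidedly: active iff `aff <= max(drug affinities)`,
i.e. at least as potent as the least potent drug. The two-sided reading
(also `>= min`) would reject any phytochemical stronger than every drug,
and the canonical worked examples include exactly such compounds
(naringenin at 2.9 nM against aromatase, whose drugs sit at 11-850 nM);
`two_sided_range = TRUE` restores the strict variant. Two further choices
were genuinely open:

* **Which drug measurements define the range.** Restricting the range to
  filter-positive drug rows caps every range below 1 uM by construction
  (pchembl > 6 is value < 1000 nM), which would make a documented
  1000 nM enzyme-context interaction unreachable. We therefore build drug
  ranges from **all** valid drug affinity measurements;
  `drug_range_positive_only = TRUE` selects the narrower reading.
* **The category-mean fallback.** For proteins without drug affinity data,
  the compound is compared against the per-category mean computed as the
  **macro** geometric mean: first a geometric mean per protein, then across
  the proteins of the category. Averaging over raw measurements instead
  would let one heavily-assayed protein dominate its category.

Interactions supported only by inhibition or potency endpoints have no
affinity value for the range rule; they are called active by the frequency
rule alone and labelled `frequency_only`.

## Chemical space and target transfer

Each parseable structure yields a 1029-column descriptor vector: a
1024-bit circular fingerprint plus TPSA, SlogP, MW, and Lipinski HBA/HBD
counts. The fingerprint is an ECFP of radius 2 (the conventional reading of
a 1024-bit circular fingerprint), computed at 4096 bits by OpenBabel and
OR-folded to 1024; the radius-2 choice and the width are configurable
(`fingerprint_bits`). PCA of the descriptor matrix standardises every
column to unit variance first — otherwise the five physicochemical columns
(MW alone spans hundreds of g/mol) would swamp the binary fingerprint
columns — and drops constant columns with a warning.

Query compounds match references first by **exact structure** (canonical
InChI equality computed from the structure, so fixtures carrying only
SMILES still match exactly) and otherwise by **similarity**: Tanimoto
>= 0.85 on the fingerprint and |dMW| < 50 g/mol, both thresholds strict as
stated, all qualifying references kept, ordered by Tanimoto with the
reference id as tie-break. Confident interactions of matched references
transfer to the query with full provenance; only exact-match links seed the
first-degree PPI expansion (score > 400, human/rat/mouse), and rodent
proteins map to human orthologs through the mapping table, retaining every
human id of one-to-many rows and counting the unmapped.

## Networks and enrichment

The food-food network weights an edge by the exact number of interacting
proteins two foods share; nodes carry both the bioactive-compound and the
interacting-protein counts, and the display layer may choose either for
node size. Per-disease target networks connect two drug targets of a
disease class when they share at least `shared_pair_min = 3` (drug, food)
pairs; a pair counts once per target regardless of how many phytochemicals
mediate it. The top-k display reduction (default `top_edges_shown = 5`)
keeps each node's k heaviest incident edges and retains an edge if
**either** endpoint keeps it, with ties broken by weight then the lexical
edge key; it is idempotent, and it is strictly an export-layer option —
no statistic is computed downstream of it. Strongest-binder annotation
selects, per protein node and role context (pharmacodynamics = drug-target
records, pharmacokinetics = enzyme/transporter/carrier records), the active
phytochemical of minimal affinity, listing the foods containing it and the
drugs linked in the matching role; display truncation ("3 drugs and 3
foods") never changes the selection. A protein may legitimately appear as
two records — one per category — when its two pharmacological contexts
carry different affinities, and the annotation disambiguates by name plus
role.

Biological-system enrichment uses the expectation
`exp = (tpc / tdt) * tpa` (targets in the category, total drug targets,
targets participating in food interactions). Significance is reported two
ways: the one-sample Student t over per-category observed/expected ratios —
an unusual test for categorical data, implemented as stated for fidelity —
and an exact binomial test per category (observed successes among `tpa`
draws at probability `tpc/tdt`), which we consider the defensible check.

## The expression arm

Differential expression is a two-group moderated t-test: per-gene pooled
variances are shrunk toward a prior fitted by method of moments to the
scaled inverse chi-square model (`s_g^2 ~ s0^2 F(d, d0)`), giving
`t = lfc / sqrt(s2_post (1/n1 + 1/n0))` on `d + d0` degrees of freedom.
When the observed variances are underdispersed relative to chi-square the
moment equations have no finite solution and `d0 = Inf` (complete
shrinkage) is used. The implementation is this package's own; the
established empirical-Bayes implementation serves as an independent
cross-check in the test suite (t statistics correlate > 0.99 on simulated
data) rather than as the implementation. Genes with zero variance and zero
fold change get p = 1 and a flag. Benjamini-Hochberg q-values below
`fdr_alpha = 0.05` define significance; at `fdr_alpha >= 1` every
non-degenerate gene is called, since q-values can equal 1 exactly.

Significant genes split into up/down **tag lists** ordered by significance,
mapped into the reference profile's id space (unmapped tags dropped and
counted). No maximum list size is imposed by default — the source protocol
does not state one — but `tag_list_cap` exposes a cap.

The **connectivity score** follows the classic reference-profile KS
convention: per instance, a weighted KS statistic for each tag list against
the ranked list; instance score 0 when the up and down statistics agree in
sign, else `KS_up - KS_down`; scaling across instances maps the largest
positive score to +1 and the most negative to -1; a reference's enrichment
score is the mean of its instances' scaled scores. The hosted service's
permutation machinery is not published in reusable form, so the permutation
p here is a documented choice: random tag lists of the observed sizes
(default `n_permutations = 10000`, seeded), full rescoring per draw,
two-sided on the set-mean magnitude with the +1 correction. The non-null
percentage is the share of a reference's instances with a nonzero score
whose sign agrees with the set-level score. A food-drug pair is
correlated/anticorrelated only when all three criteria hold strictly:
|score| > 0.75, permutation p < 0.01, non-null > 80%.

One calibration caveat worth knowing: with very few instances per
reference the scaled score is strongly discrete (the maximal instance is
pinned at +/-1; an all-zero set scores exactly 0), so permutation p-values
are conservative and lumpy. With on the order of ten instances per
reference the continuous part dominates and the null p is uniform — the
calibration tests use 12.

The DE-vs-non-DE comparison restricts to compounds targeting at least one
differentially expressed and one non-DE gene, pools affinities by target
DE status, and applies the two-sample Wilcoxon rank-sum test (exact for
small untied samples, matching full enumeration in the tests).

## Synthetic data: what it emulates, and what it does not

`genChemistry()` emits every chemistry-side table with planted truth. Drug
affinities are drawn log-uniformly over 5-80 nM — deliberately below the
pchembl cutoff so that *out-of-range* food compounds (planted at 3x the
weakest drug up to 700 nM) still produce positive measurements and reach
the classifier; in-range compounds are drawn inside the per-protein drug
range with a safety margin of six standard deviations of the replicate
jitter (log-normal, `affinity_sigma = 0.03` by default) so the plant is
not blurred by noise. Replicates (3 per pair) flip negative independently
at `flip_rate` (0 by default), exercising the frequency rule with
closed-form binomial retention expectations. Twin compound pairs are chain
homologs built on a reserved scaffold, which guarantees Tanimoto >= 0.85
on the folded fingerprint structurally rather than by rejection sampling,
keeping fixture sizes deterministic. Structures come from a small
scaffold-chain-terminal grammar: valid, parseable, and cheap — but
chemically monotonous.

`genExpression()` plants DE genes (half up, half down, effect in units of
sigma) in Gaussian matrices and builds reference rank profiles in which a
correlated drug ranks the food's up-genes near the top and down-genes near
the bottom (offset 6, noise 1 on the latent score), an anticorrelated drug
the reverse, and a null drug at random.

Passing against these plants shows the pipeline's logic is faithful —
filters, aggregation, range classification, transfer, network arithmetic
and scoring recover known truth under controlled noise. It does **not**
show robustness to what real data add: correlated assay errors, batch
effects and non-Gaussian expression noise, chemically diverse structures,
incomplete and biased literature coverage, or probe-level artefacts. The
curated worked-example fixture (`inPaperFixture()`) transcribes published
case-study interactions with plausible synthetic drug affinities and
stand-in structures; it anchors the deterministic path, not the underlying
databases.

Problem sizes in the shipped tests (hundreds of compounds, thousands of
genes, tens of reference instances, permutation counts of 49-199) are the
package's chosen desk-scale study conditions; every threshold above stays
at its published default throughout.

## Known limitations

* Activity ranges pool Ki/Kd/IC50/EC50; a per-endpoint mode exists but the
  published protocol pools them under one filter.
* Compound deduplication across libraries is by identifier, with exact
  structure matching available; no InChI-key-level merging of entries is
  attempted.
* The permutation scheme and the non-null percentage are interpretations
  of a hosted service's outputs (documented above), not re-implementations
  of published code.
* No curve fitting, assay-quality weighting, probe-level microarray
  handling, or live database access.
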