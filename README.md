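# dfinet: molecular mapping of drug-food interactions

Phytochemicals — the natural small molecules of fruits, vegetables and the
beverages made from them — bind many of the same human proteins that drugs
do, both the therapeutic targets (pharmacodynamics) and the enzymes,
transporters and carriers of drug ADME (pharmacokinetics). `dfinet` is a
systems chemical biology toolkit for researchers who want to map that
interference at the molecular level from tabular inputs shaped like the
public resources (food-compound pairings, bioassay measurement dumps,
drug-protein link tables, PPI edge lists, expression matrices), without any
live database connection.

## What it computes

**Bioactivity calls.** Bioassay measurements are flagged positive per
endpoint — pchembl > 6 for Ki/Kd/IC50/EC50, inhibition > 30%, potency
< 50 uM — and repeated measurements of a compound on a protein are collapsed
by the frequency of positive measurements; a pair is a *confident
interaction* only when that frequency exceeds 0.5. A food compound is then
called **active** on a protein when its representative affinity (geometric
mean over positive measurements, in nM) lies within the activity range of
the drugs hitting the same protein:

    active(c, p)  <=>  aff(c, p) <= max_d aff(d, p)

i.e. at least as potent as the weakest drug; proteins without drug data fall
back to the mean binding activity of the drug-bound proteins of the same
category (drug target / enzyme / transporter / carrier).

**Chemical-space transfer.** Each compound gets a 1029-column descriptor
vector (1024-bit circular fingerprint of radius 2, TPSA, SlogP, MW, Lipinski
HBA and HBD). Phytochemicals are matched to reference bioactives first by
exact structure (canonical InChI), otherwise by Tanimoto >= 0.85 with a
molecular-weight difference below 50 g/mol; the references' confident
protein targets transfer to the matched phytochemicals, exact matches are
expanded with first-degree PPI partners (confidence score > 400), and
rat/mouse proteins map to human orthologs.

**Networks.** Food-food networks weighted by shared interacting proteins;
per-disease target-target networks where two drug targets connect when at
least 3 (drug, food) pairs are active against both; tripartite
drug-target-food annotation labelling every protein with its
strongest-binding phytochemical; and biological-system enrichment with
`exp = (tpc / tdt) * tpa`.

**Expression connectivity.** A moderated t-test (empirical-Bayes variance
shrinkage) with BH-FDR 0.05 splits each food's signature into up/down tag
lists, which are scored against drug reference rank profiles with a
Kolmogorov-Smirnov connectivity score in [-1, 1]; a food-drug pair is
correlated/anticorrelated only when |score| > 0.75, permutation p < 0.01
and non-null percentage > 80.

Every input can be simulated with planted ground truth (`genChemistry()`,
`genExpression()`), and `inPaperFixture()` carries a curated worked-example
dataset.

## Worked example

```r
library(dfinet)
reg   <- inPaperFixture()
inter <- aggregateInteractions(filterMeasurements(reg))
calls <- classifyActivity(inter[inter$compound_id %in% foods(reg)$compound_id, ], reg)
annotateStrongestBinder(calls, reg, "aromatase", role = "pd",
                        interactions = inter)
```

```
   protein_id protein_name best_compound best_affinity_nm endpoint
1 AROMATASE_T    aromatase    naringenin              2.9     IC50
                                   foods
1 beansprout|guava|licorice|maize|sugar-pea
                                                         drugs
1 Aminoglutethiumide|Anastrozole|Exemestane|Letrozole|Testolactone
```

Naringenin, a flavanone found in licorice, beansprout and maize, is the
strongest phytochemical binder of aromatase in the drug-target context
(IC50 2.9 nM) — the same protein targeted by five anticancer drugs. In the
enzyme (pharmacokinetics) context the same query returns naringenin at
1000 nM, comparable to the drugs' own affinities there. A full pipeline run
(`runPipeline(inputDir, outDir)`) writes interaction tables, activity
calls, network edge lists/GraphML, enrichment tables, per-food differential
expression, connectivity scores and a reproducibility manifest; a thin
command-line front end over the same functions ships in
`inst/scripts/dfi.R`.

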