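Package: dfinet
Title: Molecular Mapping of Drug-Food Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A systems chemical biology toolkit that maps phytochemicals in
    plant-based foods onto the protein space of drug pharmacodynamics
    (therapeutic targets) and pharmacokinetics (metabolic enzymes,
    transporters and carriers). Bioassay measurements are filtered with
    endpoint-specific cutoffs, aggregated into confident compound-protein
    interactions by the frequency-of-positive-measurements rule, and food
    compounds are called active when they bind within the activity range of
    the drugs hitting the same protein (with a category-mean fallback).
    Circular-fingerprint similarity transfers protein targets from reference
    bioactives to phytochemicals, with first-neighbour protein-protein
    interaction expansion and rodent-to-human ortholog mapping. The package
    builds food-food shared-target networks, per-disease target-target
    networks and disease-specific tripartite drug-target-food networks with
    strongest-binder annotation, computes biological-system enrichment, and
    compares food and drug gene-expression signatures with a moderated
    t-test and a Kolmogorov-Smirnov tag-list connectivity score. A synthetic
    data generator with planted ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
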