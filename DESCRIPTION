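Package: lxtmap
Title: Line x Tester Combining Ability, Heterosis and Marker-Trait
    Association Mapping with Dominant Band Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis pipeline for tracking heterosis in a
    Line x Tester (LxT) mating design genotyped with multi-band dominant
    markers (e.g. silver-stained SSR fragments scored presence/absence).
    Covers descriptive statistics and RCBD ANOVA of multi-environment
    phenotypes, general and specific combining ability (GCA/SCA) with
    variance components, five heterosis statistics (mid-parent,
    heterobeltiosis, heterosis index, and standard heterosis over two
    checks), admixture-model Bayesian clustering with Evanno delta-K model
    selection, pairwise linkage disequilibrium with permutation tests and
    logarithmic decay fitting, a Q+K mixed linear model association scan
    orchestrated over the full set of genotype/phenotype combinations the
    design supports, stable-QTL consensus calling across testers, and
    favorable-allele effect mining.  A synthetic-data module generates LxT
    populations with known QTL architecture so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
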