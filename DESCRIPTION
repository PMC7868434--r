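Package: ionqtl
Title: Univariate and Multivariate QTL Mapping of the Plant Ionome in
    Recombinant Inbred Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for ionomic quantitative trait locus (QTL) analysis in
    recombinant inbred line (RIL) populations genotyped by low-coverage
    whole-genome resequencing.  Implements sliding-window genotype calling
    and recombination bin-map construction from sparse SNP observations,
    genetic-map estimation with selfing-RIL corrected recombination
    fractions (Haldane or Kosambi), Haley-Knott interval mapping on a cM
    grid with permutation-based LOD thresholds, principal-component
    composite-trait scans within and across environments or tissues, and
    co-localization of elemental, PC and across-environment PC QTLs into
    QTL clusters.  A seeded simulator of RIL genomes, low-coverage SNP
    calls and multi-element phenotypes with a known truth set supports
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    e1071,
    MASS
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
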