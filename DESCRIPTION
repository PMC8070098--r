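Package: drygene
Title: Drought Indices and Genotype-Environment Association for Candidate-Gene Resequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for candidate-gene landscape genomics in
    drought-adapted germplasm. Computes habitat drought indices from monthly
    climate normals via Thornthwaite's potential evapotranspiration model,
    calls SNPs from per-gene amplicon alignments, summarises the site
    frequency spectrum (nucleotide diversity, Watterson's theta, Tajima's D),
    characterises population structure (per-SNP Hudson Fst, principal
    components, neighbor-joining dendrograms with bootstrap, median-joining
    haplotype networks, identity-by-state kinship), and scans for
    genotype-environment associations with fixed-effect, kinship mixed-model
    (EMMA-style REML) and compressed mixed-model regressions. Includes a
    coalescent-based synthetic-data generator so every stage is testable
    with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
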