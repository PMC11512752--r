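Package: cryosig
Title: Cold-Adaptation Signatures and Biogeography of Marine Giant Viruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying giant viruses (Nucleocytoviricota and
    Mirusviricota) recovered from marine metagenomes, with an emphasis on
    low-temperature ecosystems. Screens candidate metagenome-assembled
    genomes with viral marker-gene hit tables, selects genetic codes by
    coding density, and dereplicates genomes into species-level phylotypes;
    calls genome presence across samples from read-depth profiles
    (breadth-of-coverage at a depth threshold) and summarises temperature
    distributions, endemicity, and the temperature-detection relationship;
    compares amino-acid frequencies and physicochemical properties (GRAVY,
    aliphatic index, residue-class contents) of proteins from cold versus
    temperate viruses within shared orthogroups using rank-based tests;
    and classifies KEGG orthologs as cold-exclusive or cold-overrepresented
    from genome-level prevalence ratios. A synthetic-data module generates
    proteomes, orthogroups, depth profiles, marker-hit tables, and KO
    tables with known planted structure so the whole pipeline can be
    exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
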