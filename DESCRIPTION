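Package: orgatlas
Title: Building Organellar Protein-Family Atlases on Species Phylogenies
Version: 0.1.0
Authors@R: person("Atlas", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to turn orthogroup membership tables, protein sequences
    and a species phylogeny into an atlas of organellar protein families:
    classification of green, plastid and mitochondrial orthogroups,
    majority-rule functional annotation against KEGG-style orthology maps,
    minimal-ancestral-deviation (MAD) and outgroup tree rooting, binary
    equal-rates Markov (Mk/ER) ancestral presence/absence reconstruction
    with threshold-based gain calling at named ancestors, and screens for
    PPR/mTERF domain-enriched families and N-terminal charge. Includes a
    fully seeded synthetic-data generator with known ground truth so the
    whole pipeline is testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
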