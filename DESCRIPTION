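Package: proteasim
Title: In Silico Protease Digestion and Proteome Complexity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates proteolytic digestion of protein sequences under
    configurable cleavage rules (trypsin, LysC, ArgC, GluC, or any
    residue/terminus grammar), enumerating fully specific peptides with
    bounded missed cleavages and length filtering. Aggregates digests into
    proteome-wide complexity statistics relative to a reference protease
    (peptide ratios, median peptides per protein, protein-level coverage),
    including a single-residue protease scan. Provides the downstream
    statistics used to compare identification results between proteases:
    confidence filtering, count summaries, replicate CV distributions,
    rank-abundance tables, exclusive set intersections, and rank-uniformity,
    Wilcoxon and Welch tests. A seeded synthetic-data generator emulates
    proteomes, wide-dynamic-range protein abundances, replicate noise and
    stochastic data-dependent-acquisition detection, so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
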