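Package: flucspec
Title: Fluctuation-Test Mutation Rates and Mutation Spectrum Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of spontaneous mutation rates per cell division from
    Luria-Delbrueck fluctuation assays using Drake's median-based estimator,
    with verification-based exclusion of phenotypically silenced false-positive
    colonies, distribution-free confidence intervals, fold changes and synergy
    (epistasis) indices. Classifies mutation calls against a reference open
    reading frame into spectrum categories (base substitutions, 1-bp indels,
    complex and other events), annotates mononucleotide-run context with
    left-normalised indel placement, partitions total rates into per-type
    rates with relative rates and zero-count upper bounds, and computes
    mismatch-repair efficiencies. Compares spectra between genotypes with the
    asymptotic Pearson chi-square test of independence (Bonferroni-adjusted)
    and a Monte-Carlo test of spectra homogeneity conditioned on table
    margins. Includes a synthetic fluctuation-assay generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
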