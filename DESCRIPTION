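Package: igcore
Title: Core-Sequence Genotyping of Expressed Immunoglobulin Germline Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives recombination-aware "core" search strings from a
    full-length germline V/D/J allele database, counts exact core
    occurrences (raw and UMI-deduplicated) in AIRR-format immune
    repertoire tables, and filters the counts into a per-individual
    expressed genotype. Includes the allelic-ratio, minimum-count,
    expected-frequency and CDR3-diversity germline filters, longest
    common substring (LCS) D-gene cores with a one-count-per-read rule,
    an iterative truncation scan, reproducible library subsampling,
    end-variant validation, inferred haplotyping against heterozygous
    J anchors, and a ground-truthed VDJ recombination simulator for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
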