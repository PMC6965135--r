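Package: mseqevo
Title: Multi-Region Tumour Sequencing Analysis of Clonal Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intratumour heterogeneity from multi-region
    exome sequencing of hypermutated (mismatch-repair deficient) tumours:
    two-tier multi-sample variant filtering with a panel-of-normals cross
    check, ubiquitous/shared/private mutation categorisation, ploidy and
    weighted genome instability (wGII) from allele-specific copy-number
    segments, cancer-cell-fraction estimation from variant allele
    frequencies, clone-tree reconstruction under the lineage sum rule,
    copy-number gain timing, 96-context mutational-signature refitting by
    non-negative least squares, trinucleotide-context-adjusted dN/dS per
    tree compartment, and single-region versus multi-region clonality
    comparisons. Includes a ground-truthed branched-tumour simulator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    pracma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
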