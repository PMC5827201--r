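Package: mitovar
Title: Strand-Aware Mitochondrial Variant Calling and Heteroplasmy Analysis in Tumour-Normal Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for mitochondrial genome analysis of matched
    tumour-normal sequencing data: strand-aware variant calling from text
    pileups or count tables with a depth/VAF/VAC/binomial-interval/strand
    filter cascade, somatic versus constitutional classification,
    haplogroup-based derivation of private constitutional variants,
    heteroplasmy-shift tracking between tissues, functional annotation
    against the rCRS mitochondrial genome (seven-region partition,
    vertebrate mitochondrial genetic code, strand-resolved consequence
    classes), 96-trinucleotide-context and strand-asymmetric mutational
    spectra, and cohort-level summaries and distribution tests. Includes a
    seeded tumour-normal simulator with known truth (haplogroup backbones,
    D-loop-enriched private variants, Wright-Fisher heteroplasmy drift,
    strand-asymmetric somatic substitution weights) used as the test
    substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
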