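Package: AluPolyScan
Title: Discovery and Genotyping of Polymorphic Alu Insertions from
    Paired-End Sequencing Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and genotypes polymorphic Alu elements (mobile-element
    insertions and deletions relative to a reference genome) from
    coordinate-sorted paired-end alignments of one or many individuals.
    Deleted elements at annotated loci are genotyped from the insert-size
    likelihoods of spanning read pairs; population evidence is combined with
    a likelihood-ratio test under Hardy-Weinberg equilibrium.  Inserted
    elements are discovered from discordant read pairs whose mates match an
    Alu consensus library, by solving an interval set-cover problem over the
    implied insertion positions, refined by inverse-variance estimation of
    the element length and breakpoint, inserted in silico and genotyped by
    reduction to the deletion model.  A diploid population and trio
    simulator with planted, mutated consensus copies at controlled allele
    frequencies provides end-to-end benchmarks without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
biocViews: StructuralVariation, Genetics, Sequencing, Software
RoxygenNote: 7.3.3
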