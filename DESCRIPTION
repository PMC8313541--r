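Package: hybridscope
Title: Hybrid, Clone and Local-Ancestry Inference from Diploid Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for resolving hybrid origins, clonal
    lineages and local ancestry in collections of resequenced diploid genomes,
    motivated by population analyses of east Asian citrus. Implements the
    pairwise genomic distance D = 1 - (pi1 + pi2)/(4 pi12), windowed
    heterozygosity, Weir-Cockerham Fst (including on pseudo-diploids built from
    extracted haplotypes), folded allele-frequency spectra, IBS/IBD-based
    relatedness (IBSR = IBS2/(IBS2+IBS0), r = IBD1/2 + IBD2), interspecific
    phasing against parental panels with haplotype-identity calls,
    ancestry-informative-marker derivation and likelihood-based local ancestry
    in marker windows, clone-group collapsing and classical multidimensional
    scaling. A synthetic-data module simulates differentiated populations
    (Balding-Nichols drift), pedigrees with F1 hybrids, half-sib families,
    apomictic clones and multi-megabase introgressed segments, with full
    ground-truth tracks, so the whole pipeline is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
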