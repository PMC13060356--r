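Package: ancestralRecomb
Title: Inference of Ancestrally Conserved Recombination Landscapes Across Mammals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare per-species recombination-rate landscapes across
    placental mammals, project them onto a reconstructed ancestral karyotype,
    and identify syntenic regions that have remained in the lowest (ALR) or
    highest (AHR) recombination-rate quartiles across species. Includes
    sliding-block averaging of raw rate tracks, genome-wide quartile
    categorisation, linear-interpolation coordinate projection through
    syntenic fragments, cross-species consensus calling with merge and
    overlap resolution, gene-retention summaries with LOC symbol resolution
    by ortholog vote, pathway skew testing via 2x2 chi-squared with
    Benjamini-Hochberg correction, alignment column filtering and
    subsampling, paired tree comparison, conservation-score aggregation over
    regions, and a multi-species simulator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Coverage, Alignment, Annotation
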