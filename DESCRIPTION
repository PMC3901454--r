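Package: mirachip
Title: MIRA-Chip DNA Methylation Analysis with Bisulfite Verification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for two-channel MIRA (methylated-CpG island
    recovery assay) tiling microarrays: loess correction of
    intensity-dependent dye bias, quantile normalization of log2
    MIRA/input ratios across arrays, gap-tolerant consecutive-probe
    methylation peak calling, treated-versus-control differential peak
    detection at a fixed log2(3) effect threshold, and annotation of
    peaks against promoter windows and CpG islands. A companion bisulfite
    toolkit performs in-silico bisulfite conversion, COBRA (combined
    bisulfite restriction analysis) TaqalphaI site and fragment analysis,
    clone-to-amplicon methylation calling with conversion QC, percent
    methylation, and lollipop rendering. A seeded synthetic-data
    generator emulates CpG-island and promoter probe tilings, enrichment
    peaks, dye bias, replicate structure, injected differential peaks,
    and bisulfite clone reads, so the whole pipeline is testable without
    array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    limma,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
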