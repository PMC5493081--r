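Package: omapqc
Title: Genome Assembly Quality Assessment with BioNano Optical Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses genome assemblies against BioNano optical map data.
    Digests an assembly FASTA in silico with a nicking enzyme (Nt.BspQI by
    default) into a restriction map, reads consensus query maps (CMAP) and
    map-to-map alignments (XMAP), and compares inter-site distances between
    matched adjacent restriction sites. Distance differences are screened
    for outliers with Tukey fences; each reference restriction site receives
    a five-level quality score; candidate insertions and deletions are
    called from the sign of the distance difference; questionable regions
    are exported as GFF3 for genome-browser inspection. A fully synthetic
    simulator (genomes, noisy query maps, truth alignments, injected
    misassemblies) makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    BiocGenerics,
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
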