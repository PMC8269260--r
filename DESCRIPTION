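Package: polyphasic
Title: Polyphasic Taxonomic Delineation and Synthetic-Community Tracking for Gut Bacterial Isolates
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision engine for polyphasic delineation of novel bacterial taxa from
    cultured gut isolates, combining 16S rRNA gene identity, fragment-based average
    nucleotide identity (ANI), percentage of conserved proteins (POCP), digital
    DNA:DNA hybridization (dDDH, consumed as input), genomic G+C content and MinHash
    genome sketches. Also tracks members of a defined synthetic bacterial community in
    16S rRNA amplicon OTU/ASV relative-abundance tables (prevalence, abundance,
    alpha diversity, shared/unique taxa), tallies culture-collection composition, and
    provides seeded generators of synthetic genomes, proteomes, reference databases
    and community tables with recorded ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
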