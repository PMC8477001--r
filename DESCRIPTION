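Package: apa3t
Title: Alternative Polyadenylation Analysis from 3'-End Tag Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling per-gene 3'UTR shortening and lengthening
    between two conditions from 3'-end tag sequencing (3T-seq style) read
    alignments. Reads are reduced to strand-aware 3'-end positions,
    internal-priming artifacts at genomic A-rich stretches are filtered,
    positions are grouped into poly(A)-site clusters by a greedy
    seed-and-grow ("snowball") procedure, clusters are annotated against
    gene models and a known poly(A)-site database, and per-gene shifts in
    proximal versus distal site usage are tested with a Cochran-Armitage
    linear trend test, summarized by a signed 3'UTR length index (CULI),
    and called at a Benjamini-Hochberg FDR threshold. A synthetic-data
    generator with planted shifts and internal-priming traps supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
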