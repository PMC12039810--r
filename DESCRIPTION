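Package: neoscan
Title: Promoter and ORF Reconstitution in Concatemeric cDNA from Non-Coding RNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing concatemeric cDNA (ccDNA) produced by rolling
    reverse transcription of a non-coding RNA template, as in DRT2-type phage
    defence systems. Builds theoretical ccDNA by extracting the ACA-bracketed
    template region and concatemerising its reverse complement; detects the
    sigma-70 promoter (-35/-10 with 17-bp spacer), ribosome-binding site and
    the junction-spanning stop-free open reading frame reconstituted across
    repeat junctions; computes alignment-column conservation profiles,
    in-silico restriction digests, randomized-repeat null sequences and
    protein hydropathy. Segments long sequencing reads into exact k-mers
    mapped to the ncRNA, quantifies and classifies template jumps (tandem
    repeats, strand reversals, second-strand synthesis, primer read-through),
    reconstructs per-read repeat structure, and normalises strand-specific
    read counts by spike-ins. A mechanistic simulator of rolling reverse
    transcription generates loci, ortholog families, hairpin ccDNA molecules
    and error-bearing reads with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
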