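Package: pamscan
Title: Discovery and Prioritisation of Tumour-Specific CRISPR-Cas9 Target
    Sites Created by Somatic Variants and Rearrangement Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies somatic single-nucleotide variants and small indels
    that create novel 5'-NGG-3' protospacer adjacent motifs (PAMs) absent
    from the reference genome, derives the corresponding 20-nt guide RNA
    protospacers, annotates each candidate site with gene context and
    multi-omics features (expression, copy number, gene dependency) plus
    CRISPR guide scores (CFD and MIT specificity, Doench and Moreno-Mateos
    efficiency), and prioritises candidates with a weighted rank-sum score
    normalised to 0-100. Extends discovery to structural-variant and
    extrachromosomal-DNA breakpoint junctions (junction-created PAMs and
    junction-spanning guides) and summarises per-sample yields and
    cross-patient recurrence. Includes a deterministic synthetic-data
    generator producing genomes, variant sets and breakpoint lists with
    planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
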