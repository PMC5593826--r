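Package: mttrack
Title: Whole-Mitochondrial-Genome Amplicon Panels, Ultra-Deep Variant
    Calling and Tumour Clonality Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking tumour clonality across multiple lesions of
    a patient with whole mitochondrial genome (mtDNA) amplicon sequencing.
    Designs tiled overlapping amplicon panels on the circular 16.6 kb
    mitochondrial reference and partitions them into multiplex PCR pools so
    that overlapping amplicons never share a pool; simulates multi-lesion
    patients (clonal lineage trees, homoplasmic germline polymorphisms,
    heteroplasmic somatic trunk/branch/private mutations, FFPE-type
    C>T/G>A deamination noise, off-target reads) down to paired reads with
    ground truth; builds strand-aware pileups and calls variants with
    depth, allele-fraction and strand-balance thresholds; flags putative
    false variants with cohort-level heuristics; annotates known
    polymorphisms from a packaged database snapshot; and classifies somatic
    variants into trunk, branch and private categories, reconstructing a
    clonal tree per patient and issuing a monoclonal / independent /
    untrackable verdict.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    Biostrings,
    IRanges,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
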