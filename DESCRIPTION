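Package: genotag
Title: Joint Single-Cell DNA Genotyping and Antibody-Tag Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis of droplet single-cell experiments that
    capture targeted DNA amplicons and oligonucleotide-tagged antibodies from
    the same cells. Parses combinatorial cell barcodes, antibody tags and UMIs
    from paired reads with whitelist-based error correction, deduplicates UMIs
    with the adjacency network method, calls cells from the barcode rank curve
    and antibody quality filters, condenses per-cell variant calls into a coded
    genotype matrix, corrects log antibody counts for technical covariates by
    regression on singular vectors of a per-cell quality-metric matrix, embeds
    and clusters the corrected immunophenotypes (UMAP, Leiden), quantifies
    genotype-phenotype concordance (adjusted Rand index, uncertainty
    coefficient), and profiles immunophenotypic gradients within the blast
    compartment. A synthetic-data module generates complete read-level fixtures
    with planted genotype-phenotype structure for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Matrix,
    RANN,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    uwot,
    vcfR,
    yaml
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
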