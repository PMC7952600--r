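# Small in-code fixtures shared across test files.

tiny_panel <- function() {
  as_antibody_panel(data.frame(
    name = c("CD33", "CD34", "CD3", "IgG1"),
    sequence = c("AAAACCCC", "GGGGTTTT", "ACGTACGT", "TTTTAAAA"),
    is_isotype_control = c(FALSE, FALSE, FALSE, TRUE)))
}

tiny_schema <- function() synthetic_schema()

# two-segment whitelist with known entries, pairwise Hamming >= 3
tiny_whitelist <- function() {
  whitelist(list(
    c("AAAAAAAAA", "CCCCCCCCC", "GGGGGGGGG", "TTTTTTTTT"),
    c("ACGTACGTA", "TGCATGCAT", "AAACCCGGG", "TTTGGGAAA")))
}

build_read1 <- function(s1, s2, schema = tiny_schema()) {
  paste0(schema$adapter_5p, s1, schema$linker_sequences[1], s2)
}

# small matrix-level pipeline run used by several module tests
small_run <- function(n_cells = 400, gradient = FALSE, seed = 1) {
  scn <- scenario_bundled(gradient = gradient, n_cells = n_cells)
  truth <- simulate_truth(scn$populations, scn$tech, scn$panel, seed = seed)
  dna <- emit_dna_fixtures(truth, tempfile(fileext = ".vcf"), seed = seed + 3)
  tm <- truth_matrices(truth, seed = seed + 4)
  qc <- call_cells(dna$amplicon_reads, dna$interval_depths, tm$counts,
                   scn$panel)
  cells <- qc$cell_barcode[qc$is_cell]
  q <- build_quality_matrix(tm$counts[cells, ], tm$raw_reads[cells],
                            dna$amplicon_reads[cells], scn$panel)
  design <- build_design(q, scn$params$n_vectors)
  u <- correct_counts(transform_counts(tm$counts[cells, ]), design)
  list(scn = scn, truth = truth, dna = dna, tm = tm, qc = qc, cells = cells,
       q = q, design = design, u = u,
       pop = truth$cells$population[match(cells, truth$cells$barcode)],
       pos = truth$cells$position[match(cells, truth$cells$barcode)])
}
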