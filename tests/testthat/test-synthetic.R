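test_that("simulation is deterministic under a fixed seed", {
  scn <- scenario_bundled(n_cells = 120)
  t1 <- simulate_truth(scn$populations, scn$tech, scn$panel, seed = 9)
  t2 <- simulate_truth(scn$populations, scn$tech, scn$panel, seed = 9)
  expect_identical(t1$cells, t2$cells)
  expect_identical(t1$molecules, t2$molecules)
  expect_identical(t1$ambient, t2$ambient)
  t3 <- simulate_truth(scn$populations, scn$tech, scn$panel, seed = 10)
  expect_false(identical(t1$molecules, t3$molecules))
  expect_true(verify_truth(t1))
})

test_that("dropout zero leaves planted genotypes untouched", {
  scn <- scenario_bundled(n_cells = 100)
  tech0 <- tech_model(dropout_prob = 0, n_empty = 10)
  truth <- simulate_truth(scn$populations, tech0, scn$panel, seed = 2)
  for (l in truth$loci) {
    expect_identical(truth$cells[[paste0("obs_", l)]],
                     truth$cells[[paste0("geno_", l)]])
  }
})

test_that("dropout converts heterozygous sites at the configured rate", {
  scn <- scenario_bundled(n_cells = 2000)
  tech <- tech_model(dropout_prob = 0.2, n_empty = 10)
  truth <- simulate_truth(scn$populations, tech, scn$panel, seed = 3)
  g <- truth$cells$geno_KRASG13D
  o <- truth$cells$obs_KRASG13D
  het <- g == 1L
  rate <- mean(o[het] != 1L)
  se <- sqrt(0.2 * 0.8 / sum(het))
  expect_lt(abs(rate - 0.2), 4 * se)
  # non-het sites never change
  expect_identical(o[!het], g[!het])
})

test_that("counts are Poisson around the planted profile without noise", {
  panel <- synthetic_panel()
  prof <- setNames(rep(3, nrow(panel)), panel$name)
  pops <- list(population_spec("p", 1000, c(L1 = 0L), prof, ab_sd = 0))
  tech <- tech_model(depth_sdlog = 0, ambient_rate = 0, n_empty = 0)
  truth <- simulate_truth(pops, tech, panel, seed = 12)
  lam <- exp(3)
  for (j in c("CD3", "CD33")) {
    m <- mean(truth$molecules[, j])
    v <- stats::var(truth$molecules[, j])
    expect_lt(abs(m - lam) / sqrt(lam / 1000), 3.5)     # mean within 3.5 SE
    expect_lt(abs(v - lam) / (lam * sqrt(2 / 1000)), 4) # variance ~ mean
  }
})

test_that("duplicate population names are rejected", {
  panel <- synthetic_panel()
  prof <- setNames(rep(2, nrow(panel)), panel$name)
  p <- population_spec("x", 10, c(L = 0L), prof)
  expect_error(simulate_truth(list(p, p), tech_model(), panel, seed = 1),
               "duplicate")
})

test_that("empty truth emits empty FASTQ files", {
  panel <- synthetic_panel()
  prof <- setNames(rep(-10, nrow(panel)), panel$name)  # ~0 molecules
  pops <- list(population_spec("p", 3, c(L = 0L), prof, ab_sd = 0))
  tech <- tech_model(ambient_rate = 0, n_empty = 0)
  truth <- simulate_truth(pops, tech, panel, seed = 1)
  f1 <- tempfile(); f2 <- tempfile()
  emit_antibody_reads(truth, f1, f2, seed = 2)
  expect_equal(length(readLines(f1)), 0)
})

test_that("ambient-only barcodes stay far below the antibody QC floor", {
  run <- small_run(n_cells = 300)
  amb <- run$tm$counts[run$truth$empty_barcodes, , drop = FALSE]
  tot <- rowSums(amb)
  expect_true(all(tot < 100))
  med <- stats::median(run$qc$isotype_count[run$qc$pass_knee])
  expect_false(any(antibody_qc(tot, amb[, "IgG1"], med)))
})

test_that("DNA fixtures give empty droplets failing coverage", {
  run <- small_run(n_cells = 200)
  d <- run$dna$interval_depths
  empt <- run$truth$empty_barcodes
  expect_false(any(amplicon_coverage_ok(d[empt, , drop = FALSE])))
  # cells mostly pass
  expect_gt(mean(amplicon_coverage_ok(d[run$truth$cells$barcode, ])), 0.9)
})

test_that("planted clone proportions are recovered within binomial error", {
  run <- small_run(n_cells = 600)
  gm <- read_genotype_vcf(run$dna$vcf)
  gm <- gm[run$truth$cells$barcode, ]
  lab <- genotype_cluster_labels(gm, run$truth$loci)
  cf <- clone_fractions(lab[!is.na(lab)])
  planted <- table(run$truth$cells$population) / nrow(run$truth$cells)
  # cloneA carries mut at locus 1: planted 40%
  pA <- cf$fraction[cf$clone == "mut:wt"]
  se <- sqrt(0.4 * 0.6 / sum(cf$n))
  expect_lt(abs(pA - unname(planted["cloneA"])), 4 * se + 0.02)
})
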