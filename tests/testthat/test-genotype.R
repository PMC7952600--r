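test_that("condense_call codes zygosity and applies GQ/DP filters", {
  expect_equal(condense_call("0/1", 45, 20), 1L)
  expect_equal(condense_call("1/1", 29, 50), 3L)  # quality below 30
  expect_equal(condense_call("0/0", 99, 9), 3L)   # depth below 10
  expect_equal(condense_call("0/0", 99, 10), 0L)  # boundaries inclusive
  expect_equal(condense_call("1/1", 30, 10), 2L)
  expect_equal(condense_call("./.", 99, 99), 3L)
  expect_equal(condense_call("0|1", 45, 20), 1L)
  expect_error(condense_call("1/2", 45, 20), "multiallelic")
})

test_that("raising thresholds never converts no-call back to a call", {
  set.seed(3)
  gt <- sample(c("0/0", "0/1", "1/1", "./."), 300, replace = TRUE)
  gq <- sample(0:99, 300, replace = TRUE)
  dp <- sample(0:50, 300, replace = TRUE)
  base <- condense_call(gt, gq, dp)
  for (mg in c(40, 60)) {
    for (md in c(15, 30)) {
      stricter <- condense_call(gt, gq, dp, min_gq = mg, min_dp = md)
      expect_true(all(stricter[base == 3L] == 3L))
    }
  }
})

test_that("clone label spaces enumerate to 16 (unmerged) and 9 (merged)", {
  combos <- as.matrix(expand.grid(0:3, 0:3))
  colnames(combos) <- c("locA", "locB")
  expect_equal(length(unique(assign_clone(combos, c("locA", "locB")))), 16)
  expect_equal(length(unique(assign_clone(combos, c("locA", "locB"),
                                          merge_alternates = TRUE))), 9)
  expect_equal(assign_clone(c(locA = 0L, locB = 0L), c("locA", "locB")),
               "wt:wt")
  expect_error(assign_clone(combos, character(0)), "empty")
})

test_that("toy pileup genotyper thresholds on alternate fraction", {
  r <- toy_pileup_genotype(c(10, 5, 1, 0), c(0, 5, 9, 0))
  expect_equal(r$gt, c("0/0", "0/1", "1/1", "./."))
  expect_equal(r$dp, c(10, 10, 10, 0))
  expect_true(all(r$gq[1:3] > 0))
})

test_that("clone fractions reproduce printed-count arithmetic", {
  lab <- c(rep("wt:mut", 43), rep("mut:wt", 1539), rep("wt:wt", 4563 - 43 - 1539))
  cf <- clone_fractions(lab)
  expect_equal(cf$percent[cf$clone == "wt:mut"], 100 * 43 / 4563)
  expect_equal(round(cf$percent[cf$clone == "wt:mut"], 2), 0.94)
  expect_equal(round(cf$percent[cf$clone == "mut:wt"], 1), 33.7)
  cf2 <- clone_fractions(c(rep("m", 6800), rep("w", 7516 - 6800)))
  expect_equal(round(cf2$percent[cf2$clone == "m"], 1), 90.5)
  cf3 <- clone_fractions(rep("w", 50))
  expect_equal(cf3$percent, 100)
  expect_true(all(!cf3$has_no_call))
  cf4 <- clone_fractions(c("wt:nc", "wt:wt"))
  expect_equal(cf4$has_no_call[cf4$clone == "wt:nc"], TRUE)
})

test_that("VCF ingestion round-trips planted genotype codes", {
  run <- small_run(n_cells = 200)
  gm <- read_genotype_vcf(run$dna$vcf)
  expect_true(all(gm %in% 0:3))
  expect_setequal(colnames(gm), run$truth$loci)
  # deep confident calls must match the planted post-dropout genotype
  cells <- run$truth$cells
  gm <- gm[cells$barcode, run$truth$loci]
  planted <- as.matrix(cells[, paste0("obs_", run$truth$loci)])
  called <- gm != 3L
  expect_true(mean(gm[called] == planted[called]) > 0.99)
})

test_that("multiallelic VCF records are rejected", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "c1", sep = "\t"),
    paste("chr1", "10", ".", "A", "G,T", ".", "PASS", ".", "GT", "0/1",
          sep = "\t")), p)
  expect_error(read_genotype_vcf(p), "multiallelic")
})

test_that("site QUAL can substitute for per-sample GQ", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "c1", "c2", sep = "\t"),
    paste("chr1", "10", "v1", "A", "G", "50", "PASS", ".", "GT:DP",
          "0/1:20", "1/1:20", sep = "\t"),
    paste("chr1", "20", "v2", "A", "G", "10", "PASS", ".", "GT:DP",
          "0/1:20", "0/0:20", sep = "\t")), p)
  gm <- read_genotype_vcf(p, quality_from = "QUAL")
  expect_equal(unname(gm[, "v1"]), c(1L, 2L))
  expect_equal(unname(gm[, "v2"]), c(3L, 3L))  # QUAL 10 < 30
})
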