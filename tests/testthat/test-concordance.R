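test_that("ARI matches exhaustive pair counting and known cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c("a", "a", "b", "b"),
                                   c("x", "x", "y", "y")), 1)
  # any partition against a single cluster is chance level
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 3, 3), rep(1, 6)), 0)
  # frozen value from the exhaustive pair-counting oracle on [[2,1],[1,2]]
  lt <- labels_from_table(matrix(c(2, 1, 1, 2), 2, byrow = TRUE))
  expect_equal(adjusted_rand_index(lt$x, lt$y), -1 / 9)
  expect_equal(adjusted_rand_index(lt$x, lt$y), naive_ari(lt$x, lt$y))
  expect_error(adjusted_rand_index(1, 1), "two")
})

test_that("ARI agrees with independent oracles on random partitions", {
  set.seed(42)
  for (i in 1:20) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), naive_ari(a, b),
                 tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    # symmetry and label-renaming invariance
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
    expect_equal(adjusted_rand_index(a, b),
                 adjusted_rand_index(letters[a], 10 - b))
  }
})

test_that("uncertainty coefficient matches plug-in computation", {
  x <- rep(1:3, times = c(10, 5, 5))
  expect_equal(uncertainty_coefficient(x, x), 1)
  # exact product table: independence -> 0
  lt <- labels_from_table(matrix(c(25, 25, 25, 25), 2))
  expect_equal(uncertainty_coefficient(lt$x, lt$y), 0)
  # diagonal table -> 1
  lt2 <- labels_from_table(matrix(c(5, 0, 0, 5), 2))
  expect_equal(uncertainty_coefficient(lt2$x, lt2$y), 1)
  # frozen plug-in value for [[4,1],[1,4]]
  lt3 <- labels_from_table(matrix(c(4, 1, 1, 4), 2))
  expect_equal(uncertainty_coefficient(lt3$x, lt3$y), 0.2780719,
               tolerance = 1e-6)
  expect_equal(uncertainty_coefficient(lt3$x, lt3$y),
               naive_uncertainty(lt3$x, lt3$y))
  expect_error(uncertainty_coefficient(rep(1, 10), rep(1:2, 5)),
               "undefined")
})

test_that("uncertainty coefficient is asymmetric, ARI symmetric", {
  # X (3 categories) fully determined by Y (6 categories), not vice versa
  y <- rep(1:6, each = 5)
  x <- c(1, 1, 2, 2, 3, 3)[y]
  expect_equal(uncertainty_coefficient(x, y), 1)
  expect_lt(uncertainty_coefficient(y, x), 1)
  expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
  set.seed(8)
  a <- sample(1:3, 40, replace = TRUE)
  b <- sample(1:4, 40, replace = TRUE)
  expect_equal(uncertainty_coefficient(a, b),
               naive_uncertainty(a, b), tolerance = 1e-12)
})

test_that("genotype labels drop no-call cells by default", {
  gm <- rbind(c(0L, 1L), c(1L, 3L), c(2L, 0L))
  colnames(gm) <- c("l1", "l2")
  rownames(gm) <- c("a", "b", "c")
  lab <- genotype_cluster_labels(gm, c("l1", "l2"))
  expect_equal(unname(lab), c("wt:mut", NA, "mut:wt"))
  lab2 <- genotype_cluster_labels(gm, c("l1", "l2"), drop_no_call = FALSE)
  expect_equal(unname(lab2[2]), "mut:nc")
  lab3 <- genotype_cluster_labels(gm, c("l1", "l2"),
                                  merge_alternates = FALSE)
  expect_equal(unname(lab3[3]), "hom:wt")
})

test_that("degenerate label vectors are reported as not applicable", {
  rep_ <- concordance_report(rep("wt", 20), sample(1:3, 20, replace = TRUE))
  expect_false(rep_$applicable)
  expect_true(is.na(rep_$ari))
  rep2 <- concordance_report(c(rep("a", 10), rep("b", 10)),
                             rep(1:2, each = 10))
  expect_true(rep2$applicable)
  expect_equal(rep2$ari, 1)
  expect_equal(rep2$u_genotype_given_cluster, 1)
})

test_that("clean simulated structure yields near-perfect concordance", {
  run <- small_run(n_cells = 400)
  gm <- read_genotype_vcf(run$dna$vcf)
  gm <- gm[intersect(run$cells, rownames(gm)), ]
  lab <- genotype_cluster_labels(gm, run$scn$loci)
  cl <- cluster_cells(run$u, resolution = run$scn$params$resolution,
                      seed = 0)
  rep_ <- concordance_report(lab[rownames(run$u)], as.integer(cl))
  expect_gte(rep_$ari, 0.95)
  expect_gte(rep_$u_genotype_given_cluster, 0.95)
})
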