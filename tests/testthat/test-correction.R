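test_that("transform_counts adds one pseudocount and takes natural log", {
  m <- matrix(c(0, exp(1) - 1, 4, 0), 2)
  expect_equal(transform_counts(m)[1, 1], 0)
  expect_equal(transform_counts(m)[2, 1], 1)
  z <- matrix(0, 3, 2)
  expect_equal(transform_counts(z), z)
})

test_that("build_design z-scores, decomposes and falls back when degenerate", {
  set.seed(2)
  q <- matrix(rexp(200 * 4, 1 / 100), 200, 4,
              dimnames = list(paste0("c", 1:200),
                              c("ab_reads", "ab_umis", "isotype",
                                "amplicon_reads")))
  for (k in 1:3) {
    d <- build_design(q, k)
    expect_equal(ncol(d), k + 1)
    expect_equal(unname(d[, 1]), rep(1, 200))
    # singular vectors are orthonormal
    sv <- d[, -1, drop = FALSE]
    expect_equal(crossprod(sv), diag(k), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # identical rows -> constant after centering -> intercept only
  qi <- matrix(5, 50, 4, dimnames = list(NULL, colnames(q)))
  expect_warning(di <- build_design(qi, 2), "constant")
  expect_equal(ncol(di), 1)
})

test_that("regressing out a rank-1 quality matrix removes it completely", {
  set.seed(4)
  x <- rnorm(300, 4, 0.8)
  # after log(q+1) each column is x + a_k exactly: transformed q has rank 1
  q <- exp(outer(x, c(0, 0.5, -0.3, 1), `+`)) - 1
  colnames(q) <- c("a", "b", "c", "d")
  d <- build_design(q, 1)
  u <- correct_counts(log(q + 1), d)
  expect_lt(max(abs(u)), 1e-10)
})

test_that("residuals are orthogonal to the design and mean-free", {
  run <- small_run(n_cells = 300)
  u <- run$u
  expect_equal(max(abs(colMeans(u))), 0, tolerance = 1e-12)
  rel <- abs(crossprod(u, run$design)) /
    (sqrt(colSums(u^2)) %o% sqrt(colSums(run$design^2)))
  expect_lt(max(rel), 1e-10)
  expect_identical(dim(u), dim(run$tm$counts[run$cells, ]))
  expect_identical(rownames(u), run$cells)
  expect_error(correct_counts(matrix(0, 2, 3), matrix(1, 2, 3)), "fewer")
})

test_that("intercept-only design reduces to column centering", {
  m <- matrix(rpois(60, 20), 20, 3)
  lc <- transform_counts(m)
  d <- matrix(1, 20, 1, dimnames = list(NULL, "intercept"))
  u <- correct_counts(lc, d)
  expect_equal(u, scale(lc, center = TRUE, scale = FALSE),
               ignore_attr = TRUE)
})

test_that("planted depth confounder is removed from residuals", {
  run <- small_run(n_cells = 400)
  ld <- log(run$truth$cells$depth_factor[
    match(run$cells, run$truth$cells$barcode)])
  qt <- scale(log(run$q + 1))
  # the design span captures the depth covariate
  fit <- lm(ld ~ run$design - 1)
  expect_gt(summary(lm(ld ~ run$design[, -1]))$r.squared, 0.95)
  # residual correlation with the in-span depth component is negligible
  inspan <- fitted(lm(ld ~ run$design[, -1]))
  expect_lt(max(abs(cor(run$u, inspan))), 1e-6)
})

test_that("population separation survives correction", {
  # two populations differing in one antibody, orthogonal to a planted
  # depth covariate
  set.seed(9)
  n <- 400
  pop <- rep(c(1, 2), each = n / 2)
  depth <- rlnorm(n, 0, 0.5)
  # populations swap A and B so per-cell totals (hence the quality matrix)
  # carry no population signal
  mu <- cbind(A = ifelse(pop == 1, 4.5, 2.5),
              B = ifelse(pop == 1, 2.5, 4.5), C = 3, D = 1)
  counts <- matrix(rpois(n * 4, exp(mu) * depth), n)
  colnames(counts) <- colnames(mu)
  rownames(counts) <- paste0("c", 1:n)
  panel <- as_antibody_panel(data.frame(
    name = c("A", "B", "C", "D"),
    sequence = c("AAAACCCC", "GGGGTTTT", "ACGTACGT", "TTTTAAAA"),
    is_isotype_control = c(FALSE, FALSE, FALSE, TRUE)))
  q <- build_quality_matrix(counts, rowSums(counts) * 1.3,
                            setNames(1000 * depth, rownames(counts)), panel)
  lc <- transform_counts(counts)
  u <- correct_counts(lc, build_design(q, 2))
  clc <- scale(lc, center = TRUE, scale = FALSE)
  sep_raw <- abs(mean(clc[pop == 1, "A"]) - mean(clc[pop == 2, "A"]))
  sep_cor <- abs(mean(u[pop == 1, "A"]) - mean(u[pop == 2, "A"]))
  expect_lt(abs(sep_cor - sep_raw) / sep_raw, 0.05)
})
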