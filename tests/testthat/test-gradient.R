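# deterministic planted gradient matrix: position-driven slopes + noise
planted_gradient <- function(n = 500, seed = 17, noise = 0.1) {
  set.seed(seed)
  pos <- sort(runif(n))
  slopes <- c(A = 2, B = -2, C = 1.5, D = -1.5, E = 0, F = 0)
  u <- outer(pos - mean(pos), slopes) +
    matrix(rnorm(n * 6, 0, noise), n)
  colnames(u) <- names(slopes)
  rownames(u) <- paste0("c", 1:n)
  # a dominant constant offset mode orthogonal to the gradient markers, so
  # the first singular vector is the offset and the second the gradient
  u <- cbind(u, G = 3 + rnorm(n, 0, noise))
  list(u = u, pos = pos)
}

test_that("blast_subset selects configured clusters", {
  u <- matrix(1:12, 4, dimnames = list(paste0("c", 1:4), NULL))
  cl <- c(0L, 1L, 0L, 2L)
  expect_equal(rownames(blast_subset(u, cl, c(0, 1, 2))), rownames(u))
  expect_equal(rownames(blast_subset(u, cl, 0L)), c("c1", "c3"))
  expect_error(blast_subset(u, cl, integer(0)), "no blast")
  expect_error(blast_subset(u, cl, 9L), "empty")
})

test_that("ordering recovers a planted monotone gradient", {
  pg <- planted_gradient()
  ord <- order_by_gradient(pg$u)
  tau <- cor(order(ord), rank(pg$pos), method = "kendall")
  expect_gte(abs(tau), 0.9)
  # sign flip of the input reverses the ordering (equivalent result)
  ord2 <- order_by_gradient(-pg$u)
  tau2 <- cor(order(ord2), rank(pg$pos), method = "kendall")
  expect_equal(abs(tau2), abs(tau), tolerance = 0.05)
  expect_error(order_by_gradient(pg$u[1:2, ]), "3 cells")
  expect_error(order_by_gradient(matrix(rep(1:5, 3), 5)), "rank")
})

test_that("duplicated rows tie-break stably", {
  u <- matrix(rnorm(40), 10, 4)
  u2 <- rbind(u, u[3, , drop = FALSE])
  ord <- order_by_gradient(u2)
  s <- attr(ord, "scores")
  expect_equal(s[3], s[11], tolerance = 1e-12)
  # numerically tied rows end up adjacent in the ordering
  expect_equal(abs(which(ord == 3) - which(ord == 11)), 1)
})

test_that("moving profiles average antibodies, clones and coordinates", {
  n <- 50
  u <- cbind(const = rep(2, n), lin = seq_len(n))
  rownames(u) <- paste0("c", 1:n)
  lab <- rep(c("a", "b"), each = n / 2)
  emb <- cbind(x = seq_len(n), y = rep(1, n))
  prof <- moving_profiles(seq_len(n), u, lab, emb, window = 10)
  expect_equal(unname(prof$antibody[, "const"]), rep(2, n - 9))
  expect_equal(unname(prof$antibody[, "lin"]), seq(5.5, by = 1,
                                                   length.out = n - 9))
  expect_true(all(prof$clones >= 0 & prof$clones <= 1))
  expect_true(all(abs(rowSums(prof$clones) - 1) < 1e-12))
  expect_equal(unname(prof$coords[, "y"]), rep(1, n - 9))
  # window equal to n: single global mean
  p1 <- moving_profiles(seq_len(n), u, window = n)
  expect_equal(nrow(p1$antibody), 1)
  expect_equal(unname(p1$antibody[1, "lin"]), mean(seq_len(n)))
  expect_error(moving_profiles(seq_len(n), u, window = 1), ">= 2")
  expect_error(moving_profiles(seq_len(n), u, window = n + 1), "exceeds")
})

test_that("gradient correlations report signed trends and p-values", {
  pg <- planted_gradient()
  ord <- order_by_gradient(pg$u)
  # orient so the ordering follows the planted position
  if (cor(order(ord), rank(pg$pos), method = "kendall") < 0)
    ord <- rev(ord)
  clone <- ifelse(pg$pos < 0.5, "early", "late")
  prof <- moving_profiles(ord, pg$u, clone, window = 100)
  cors <- gradient_correlations(prof)
  r <- setNames(cors$antibody$pearson_r, cors$antibody$antibody)
  expect_gt(r["A"], 0.9)
  expect_lt(r["B"], -0.9)
  tau <- setNames(cors$clones$kendall_tau, cors$clones$clone)
  expect_lt(tau["early"], 0)
  expect_gt(tau["late"], 0)
  expect_true(all(cors$clones$p_value < 1e-10))
  # perfectly linear profile
  lin <- moving_profiles(seq_len(100),
                         cbind(z = seq_len(100)) + 0, window = 10)
  expect_equal(gradient_correlations(lin)$antibody$pearson_r, 1)
})

test_that("sign invariance: negation mirrors profiles, magnitudes fixed", {
  pg <- planted_gradient(n = 300)
  clone <- ifelse(pg$pos < 0.5, "early", "late")
  ord_a <- order_by_gradient(pg$u)
  ord_b <- order_by_gradient(-pg$u)
  pa <- moving_profiles(ord_a, pg$u, clone, window = 50)
  pb <- moving_profiles(ord_b, pg$u, clone, window = 50)
  ca <- gradient_correlations(pa)
  cb <- gradient_correlations(pb)
  flipped <- !identical(ord_a, ord_b)
  if (flipped) {
    expect_equal(ca$antibody$pearson_r, -cb$antibody$pearson_r,
                 tolerance = 1e-6)
  }
  expect_equal(abs(ca$clones$kendall_tau), abs(cb$clones$kendall_tau),
               tolerance = 1e-6)
})

test_that("spline interpolates knots and degenerates to a line", {
  # collinear points
  coords <- cbind(x = seq(0, 1, length.out = 20),
                  y = 2 * seq(0, 1, length.out = 20) + 1)
  f <- fit_spline(coords)
  tt <- seq(0, 1, length.out = 101)
  pts <- f(tt)
  expect_lt(max(abs(pts[, "y"] - (2 * pts[, "x"] + 1))), 1e-8)
  # interpolation at the knots of a curved arc
  set.seed(6)
  arc <- cbind(x = cumsum(runif(12)), y = cumsum(rnorm(12)))
  g <- fit_spline(arc)
  expect_equal(unname(g(attr(g, "knots"))), unname(arc),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(fit_spline(arc[1:3, ]), "4")
})
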