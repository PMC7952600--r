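#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance under the permutation model:
#' with contingency counts `n_xy`, row sums `a_x`, column sums `b_y` and
#' `E = sum_x C(a_x,2) * sum_y C(b_y,2) / C(n,2)`,
#' `ARI = (sum_xy C(n_xy,2) - E) / (0.5*(sum_x C(a_x,2) + sum_y C(b_y,2)) - E)`.
#' Identical partitions score 1; independent partitions score ~0; the index
#' can be negative.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return Numeric in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  if (n < 2) stop("need at least two observations")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  e <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - e
  if (denom == 0) return(1)  # both partitions trivial and identical
  (sum_ij - e) / denom
}

#' Uncertainty coefficient U(X|Y)
#'
#' The fraction of information in `X` predictable from `Y`:
#' `U(X|Y) = I(X;Y) / H(X)`, with mutual information and entropy computed
#' from the empirical joint frequencies (plug-in estimator, natural log; the
#' ratio is base-free). Asymmetric in its arguments.
#'
#' @param x_labels,y_labels Equal-length label vectors.
#' @return Numeric in [0, 1].
#' @export
uncertainty_coefficient <- function(x_labels, y_labels) {
  stopifnot(length(x_labels) == length(y_labels))
  tab <- table(x_labels, y_labels)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  if (hx == 0) stop("undefined: H(X) = 0 (single category in X)")
  pos <- p > 0
  mi <- sum(p[pos] * log(p[pos] / outer(px, py)[pos]))
  mi / hx
}

#' Genotype-cluster label vector for concordance statistics
#'
#' Genotypic clusters are the combined variant calls over the relevant loci
#' (see [assign_clone()]). For patient samples, heterozygous and homozygous
#' alternate calls are merged to suppress allele-dropout noise. Cells whose
#' label contains a no-call state are set to `NA` by default so that both
#' concordance statistics are computed over confidently assigned clones
#' only.
#'
#' @param gm Coded genotype matrix (cells x variants).
#' @param loci Relevant variant columns.
#' @param merge_alternates Merge het/hom-alt states (default TRUE, patient
#'   mode).
#' @param drop_no_call Replace labels containing a no-call with `NA`
#'   (default TRUE); with FALSE, "no call" acts as its own category.
#' @return Character vector of labels (with `NA` for dropped cells), named
#'   by cell barcode when `gm` has rownames.
#' @export
genotype_cluster_labels <- function(gm, loci, merge_alternates = TRUE,
                                    drop_no_call = TRUE) {
  lab <- assign_clone(gm, loci, merge_alternates)
  if (drop_no_call) lab[grepl("(^|:)nc(:|$)", lab)] <- NA_character_
  names(lab) <- rownames(gm)
  lab
}

#' Genotype-phenotype concordance report
#'
#' Computes the adjusted Rand index and both directions of the uncertainty
#' coefficient between genotype clone labels and phenotype cluster labels,
#' after removing cells with missing (dropped no-call) labels. With fewer
#' than two categories on either side the statistics are not applicable and
#' reported as `NA`.
#'
#' @param genotype_labels From [genotype_cluster_labels()] (may contain NA).
#' @param cluster_labels Phenotype cluster labels (may contain NA).
#' @return data.frame with `n_cells`, `ari`, `u_genotype_given_cluster`,
#'   `u_cluster_given_genotype`, and `applicable`.
#' @export
concordance_report <- function(genotype_labels, cluster_labels) {
  stopifnot(length(genotype_labels) == length(cluster_labels))
  keep <- !is.na(genotype_labels) & !is.na(cluster_labels)
  g <- genotype_labels[keep]
  c_ <- cluster_labels[keep]
  ok <- length(g) >= 2 && length(unique(g)) > 1 && length(unique(c_)) > 1
  data.frame(
    n_cells = length(g),
    ari = if (ok) adjusted_rand_index(g, c_) else NA_real_,
    u_genotype_given_cluster = if (ok) uncertainty_coefficient(g, c_)
                               else NA_real_,
    u_cluster_given_genotype = if (ok) uncertainty_coefficient(c_, g)
                               else NA_real_,
    applicable = ok)
}
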