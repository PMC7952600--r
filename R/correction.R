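#' Log-transform a count matrix with one pseudocount
#' @param c_mat Non-negative count matrix (cells x antibodies).
#' @return Natural-log matrix `log(c + 1)` of the same shape.
#' @export
transform_counts <- function(c_mat) {
  stopifnot(all(c_mat >= 0))
  log(c_mat + 1)
}

#' Assemble the per-cell technical quality matrix
#'
#' Four per-cell metrics that track sequencing depth and background: total
#' antibody reads (pre-deduplication), total antibody counts after UMI
#' correction, isotype-control (IgG1) count, and total amplicon reads. Rows
#' align with the count matrix rows.
#'
#' @param ab_counts Deduplicated count matrix (cells x antibodies).
#' @param raw_reads Named vector of raw tag reads per cell.
#' @param amplicon_reads Named vector of total DNA amplicon reads per cell.
#' @param panel `antibody_panel` identifying isotype-control columns.
#' @return Numeric matrix cells x 4 with columns `ab_reads`, `ab_umis`,
#'   `isotype`, `amplicon_reads`.
#' @export
build_quality_matrix <- function(ab_counts, raw_reads, amplicon_reads, panel) {
  cells <- rownames(ab_counts)
  iso_cols <- panel$name[panel$is_isotype_control]
  q <- cbind(
    ab_reads = as.numeric(raw_reads[cells]),
    ab_umis = rowSums(ab_counts),
    isotype = rowSums(ab_counts[, iso_cols, drop = FALSE]),
    amplicon_reads = as.numeric(amplicon_reads[cells]))
  rownames(q) <- cells
  if (any(is.na(q))) stop("quality metrics missing for some cells")
  if (any(q < 0)) stop("quality metrics must be non-negative")
  q
}

#' Build the technical regression design from the quality matrix
#'
#' The quality matrix is log-transformed (pseudocount 1), column-wise scaled
#' to unit standard deviation and mean-centered (a z-score), and decomposed
#' by SVD. The first `n_vectors` left-singular vectors, plus an intercept
#' column, form the design used to regress technical variation out of the
#' log antibody counts. Columns that are constant after transformation carry
#' no information and are dropped with a warning before the SVD.
#'
#' @param q Quality matrix from [build_quality_matrix()].
#' @param n_vectors Number of left-singular vectors to retain: 3 for patient
#'   samples, 2 for PBMC, 1 for cell-line experiments.
#' @param intercept Include an intercept column (default TRUE; without it
#'   residuals are not mean-free).
#' @return Design matrix (cells x (n_vectors + 1)); attributes
#'   `variance_explained` (per retained vector) and `svd_u` (all left
#'   singular vectors of the transformed q, for diagnostics).
#' @export
build_design <- function(q, n_vectors, intercept = TRUE) {
  stopifnot(n_vectors %in% 1:3, nrow(q) > n_vectors + 1)
  z <- log(q + 1)
  sdv <- apply(z, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning("dropping constant quality column(s): ",
            paste(colnames(z)[!keep], collapse = ", "))
    z <- z[, keep, drop = FALSE]
  }
  if (ncol(z) == 0) {
    des <- matrix(1, nrow(q), 1, dimnames = list(rownames(q), "intercept"))
    attr(des, "variance_explained") <- numeric()
    return(des)
  }
  z <- scale(z, center = FALSE, scale = sdv[keep])
  z <- scale(z, center = TRUE, scale = FALSE)
  sv <- svd(z)
  tol <- max(dim(z)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  n_use <- min(n_vectors, rank)
  cols <- if (n_use > 0) sv$u[, seq_len(n_use), drop = FALSE]
          else matrix(0, nrow(q), 0)
  des <- if (intercept) cbind(intercept = 1, cols) else cols
  if (n_use > 0)
    colnames(des)[(ncol(des) - n_use + 1):ncol(des)] <-
      paste0("sv", seq_len(n_use))
  rownames(des) <- rownames(q)
  attr(des, "variance_explained") <-
    if (rank > 0) (sv$d^2 / sum(sv$d^2))[seq_len(n_use)] else numeric()
  attr(des, "svd_u") <- sv$u[, seq_len(rank), drop = FALSE]
  des
}

#' Regress technical covariates out of the log antibody counts
#'
#' Each antibody column of the log-transformed count matrix is regressed by
#' ordinary least squares on the design; the residual vectors form the
#' corrected antibody signal.
#'
#' @param log_c Log-transformed count matrix (from [transform_counts()]).
#' @param design Design matrix from [build_design()]; rows must align.
#' @return Corrected matrix of residuals (same shape and dimnames as
#'   `log_c`); attribute `regressors` records the design column names.
#' @export
correct_counts <- function(log_c, design) {
  stopifnot(nrow(log_c) == nrow(design))
  if (nrow(log_c) <= ncol(design))
    stop("fewer cells than design columns")
  fit <- stats::lm.fit(design, log_c)
  u <- as.matrix(fit$residuals)
  dimnames(u) <- dimnames(log_c)
  attr(u, "regressors") <- colnames(design)
  u
}

#' Correction diagnostics report
#'
#' @param u Corrected matrix from [correct_counts()].
#' @param design Design matrix used.
#' @return List with `variance_explained` (from the design) and
#'   `residual_regressor_cor` (antibodies x regressors Pearson correlations;
#'   all should be ~0).
#' @export
correction_diagnostics <- function(u, design) {
  nonconst <- apply(design, 2, function(x) stats::sd(x) > 0)
  rc <- if (any(nonconst))
    stats::cor(u, design[, nonconst, drop = FALSE]) else NULL
  list(variance_explained = attr(design, "variance_explained"),
       residual_regressor_cor = rc)
}
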