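#' Restrict the corrected matrix to blast-phenotype clusters
#'
#' @param u Corrected matrix (cells x antibodies).
#' @param clusters Cluster labels, one per row of `u`.
#' @param blast_cluster_ids Cluster labels annotated as blast (non-empty).
#' @return Submatrix of `u` for cells in blast clusters.
#' @export
blast_subset <- function(u, clusters, blast_cluster_ids) {
  stopifnot(nrow(u) == length(clusters))
  if (length(blast_cluster_ids) == 0) stop("no blast clusters configured")
  keep <- clusters %in% blast_cluster_ids
  if (!any(keep)) stop("empty blast subset")
  u[keep, , drop = FALSE]
}

#' Order blast cells along the dominant immunophenotypic gradient
#'
#' The singular value decomposition of the blast submatrix of the corrected
#' signal is computed and cells are ordered by their entry in the second
#' left-singular vector, which captures the dominant within-compartment
#' gradient (the first vector mostly reflects the compartment offset). The
#' sign of a singular vector is arbitrary, so the reversed ordering is an
#' equivalent result. Ties are broken stably by row position.
#'
#' @param u_blast Blast submatrix from [blast_subset()] (>= 3 cells).
#' @return Integer permutation of `1:nrow(u_blast)`; attribute `scores`
#'   holds the per-cell singular-vector values (in original row order).
#' @export
order_by_gradient <- function(u_blast) {
  if (nrow(u_blast) < 3) stop("need at least 3 cells")
  sv <- svd(u_blast)
  tol <- max(dim(u_blast)) * max(sv$d) * .Machine$double.eps
  if (sum(sv$d > tol) < 2) stop("rank below 2: no gradient axis")
  scores <- sv$u[, 2]
  ord <- order(scores, seq_along(scores))
  structure(ord, scores = scores)
}

roll_mean <- function(x, w) {
  n <- length(x)
  cs <- cumsum(as.numeric(x))
  (cs[w:n] - c(0, cs[seq_len(n - w)])) / w
}

#' Smoothed antibody, clone and position profiles along the gradient
#'
#' Slides a dense (stride 1) window of `window` cells along the gradient
#' ordering and records, per window, the mean of every antibody, the
#' fraction of every clone, and (when an embedding is given) the mean 2-D
#' coordinates. Only fully populated windows are emitted, so profiles have
#' `n - window + 1` rows.
#'
#' @param ordering Permutation from [order_by_gradient()].
#' @param u_blast Blast submatrix (rows in original order).
#' @param clone_labels Clone label per blast cell (NA allowed; NA cells
#'   count in the window denominator but belong to no clone).
#' @param embedding Optional cells x 2 coordinate matrix for the same rows.
#' @param window Window length in cells (default 200).
#' @return List of class `gradient_profile`: `window`, `ordering`,
#'   `positions` (window start index), `antibody` (windows x antibodies),
#'   `clones` (windows x clone labels), `coords` (windows x 2 or NULL),
#'   `clone_labels` (per-cell, in gradient order).
#' @export
moving_profiles <- function(ordering, u_blast, clone_labels = NULL,
                            embedding = NULL, window = 200) {
  n <- nrow(u_blast)
  if (window < 2) stop("window must be >= 2")
  if (window > n) stop("window exceeds number of blast cells")
  stopifnot(length(ordering) == n)
  uo <- u_blast[ordering, , drop = FALSE]
  nw <- n - window + 1L
  ab <- matrix(vapply(seq_len(ncol(uo)),
                      function(j) roll_mean(uo[, j], window), numeric(nw)),
               nrow = nw)
  colnames(ab) <- colnames(u_blast)
  cl <- NULL
  lab_o <- NULL
  if (!is.null(clone_labels)) {
    stopifnot(length(clone_labels) == n)
    lab_o <- clone_labels[ordering]
    cls <- sort(unique(stats::na.omit(lab_o)))
    cl <- matrix(vapply(cls, function(k)
      roll_mean(!is.na(lab_o) & lab_o == k, window), numeric(nw)),
      nrow = nw)
    colnames(cl) <- cls
  }
  xy <- NULL
  if (!is.null(embedding)) {
    stopifnot(nrow(embedding) == n)
    eo <- embedding[ordering, , drop = FALSE]
    xy <- cbind(x = roll_mean(eo[, 1], window),
                y = roll_mean(eo[, 2], window))
  }
  structure(list(window = window, ordering = ordering,
                 positions = seq_len(n - window + 1),
                 antibody = ab, clones = cl, coords = xy,
                 clone_labels = lab_o),
            class = "gradient_profile")
}

#' Correlations of markers and clones with gradient position
#'
#' Pearson correlation (two-sided test) of each smoothed antibody profile
#' against window position, and Kendall rank correlation of each clone's
#' per-cell indicator against the cell's rank along the ordering (computed
#' on the unsmoothed indicators, where ties are handled by the tau-b
#' statistic).
#'
#' @param profiles A `gradient_profile` from [moving_profiles()].
#' @return List with `antibody` (data.frame: antibody, pearson_r, p_value)
#'   and `clones` (data.frame: clone, kendall_tau, p_value; NULL when no
#'   clone labels were profiled). Zero-variance series yield `NA`.
#' @export
gradient_correlations <- function(profiles) {
  stopifnot(inherits(profiles, "gradient_profile"))
  pos <- profiles$positions
  ab <- data.frame(antibody = colnames(profiles$antibody),
                   pearson_r = NA_real_, p_value = NA_real_)
  for (j in seq_len(ncol(profiles$antibody))) {
    yv <- profiles$antibody[, j]
    if (length(yv) >= 3 && stats::sd(yv) > 0) {
      ct <- stats::cor.test(pos, yv, method = "pearson")
      ab$pearson_r[j] <- unname(ct$estimate)
      ab$p_value[j] <- ct$p.value
    }
  }
  cl <- NULL
  if (!is.null(profiles$clones)) {
    lab <- profiles$clone_labels
    rank_pos <- seq_along(lab)
    cls <- colnames(profiles$clones)
    cl <- data.frame(clone = cls, kendall_tau = NA_real_,
                     p_value = NA_real_)
    for (k in seq_along(cls)) {
      ind <- as.numeric(!is.na(lab) & lab == cls[k])
      if (length(ind) >= 3 && stats::sd(ind) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(rank_pos, ind, method = "kendall"))
        cl$kendall_tau[k] <- unname(ct$estimate)
        cl$p_value[k] <- ct$p.value
      }
    }
  }
  list(antibody = ab, clones = cl)
}

#' Cubic spline through the smoothed gradient positions
#'
#' Interpolating third-order spline through the window-averaged embedding
#' coordinates, parameterized by normalized window position in [0, 1];
#' used to draw the orientation of the gradient on the embedding.
#'
#' @param coords Windows x 2 matrix of smoothed coordinates (>= 4 rows).
#' @return Function of class `gradient_spline`: `f(t)` for `t` in [0, 1]
#'   returns an `length(t) x 2` matrix of curve points; attribute `knots`
#'   holds the normalized knot positions.
#' @export
fit_spline <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4) stop("need at least 4 smoothed points")
  tt <- seq(0, 1, length.out = nrow(coords))
  fx <- stats::splinefun(tt, coords[, 1], method = "natural")
  fy <- stats::splinefun(tt, coords[, 2], method = "natural")
  f <- function(t) cbind(x = fx(t), y = fy(t))
  class(f) <- c("gradient_spline", "function")
  attr(f, "knots") <- tt
  f
}
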