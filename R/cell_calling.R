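#' Barcode rank knee: read-count threshold at the curve's inflection
#'
#' Barcodes sorted by descending total amplicon reads form a characteristic
#' curve with a plateau of cell-containing barcodes and a steep drop into
#' ambient barcodes. The knee is located as the point of maximum
#' perpendicular distance between the log-rank/log-count curve and the chord
#' joining its endpoints; the read count at that point is the calling
#' threshold.
#'
#' @param reads Named numeric vector of total amplicon reads per barcode
#'   (any order; zeros dropped).
#' @return Numeric threshold with attributes `candidates` (barcode names with
#'   reads strictly above the threshold) and `rank` (knee position).
#' @export
rank_inflection <- function(reads) {
  reads <- reads[reads > 0]
  if (length(reads) < 2) stop("need at least two barcodes with non-zero reads")
  ord <- order(reads, decreasing = TRUE)
  r <- as.numeric(reads[ord])
  if (max(r) / min(r) < 10) stop("no knee: dynamic range below 10x")
  x <- log10(seq_along(r))
  y <- log10(r)
  # perpendicular distance from each point to the chord (x1,y1)-(xn,yn)
  dx <- x[length(x)] - x[1]; dy <- y[length(y)] - y[1]
  len <- sqrt(dx^2 + dy^2)
  dist <- abs(dy * (x - x[1]) - dx * (y - y[1])) / len
  if (max(dist) < 1e-9) {
    # collinear in log-log space (e.g. a two-point curve): split at the
    # geometric mean of the endpoints
    thr <- sqrt(max(r) * min(r))
    k <- sum(r > thr)
  } else {
    k <- which.max(dist)
    thr <- r[k]
  }
  cand <- names(reads)[ord][which(r > thr)]
  structure(thr, candidates = cand, rank = sum(r > thr))
}

#' Amplicon coverage filter for one cell
#'
#' A valid cell must show reads across most of the targeted panel; barcodes
#' with patchy coverage are ambient or degraded. The default demands that
#' 60% of panel intervals carry at least eight reads.
#'
#' @param depths Numeric vector of per-interval read counts for one cell (or
#'   a matrix cells x intervals, returning one flag per row).
#' @param min_fraction Fraction of intervals that must be covered.
#' @param min_reads Minimum reads for an interval to count as covered.
#' @return Logical.
#' @export
amplicon_coverage_ok <- function(depths, min_fraction = 0.6, min_reads = 8) {
  if (is.matrix(depths)) {
    if (ncol(depths) == 0) stop("empty interval list")
    return(rowMeans(depths >= min_reads) >= min_fraction)
  }
  if (length(depths) == 0) stop("empty interval list")
  mean(depths >= min_reads) >= min_fraction
}

#' Antibody-count quality filter
#'
#' Requires a minimum number of deduplicated antibody UMIs and bounds the
#' isotype-control (IgG1) count, which measures nonspecific binding, at a
#' multiple of the experiment-wide median. The isotype bound is inclusive
#' ("no greater than").
#'
#' @param total_umis Deduplicated antibody UMI total(s) per cell.
#' @param isotype_count Isotype-control count(s) per cell.
#' @param median_isotype Median isotype count over candidate cells of the
#'   same experiment.
#' @param min_umis Minimum UMI total (default 100).
#' @param isotype_factor Allowed multiple of the median (default 5).
#' @return Logical.
#' @export
antibody_qc <- function(total_umis, isotype_count, median_isotype,
                        min_umis = 100, isotype_factor = 5) {
  if (any(c(total_umis, isotype_count, median_isotype) < 0))
    stop("negative inputs")
  total_umis >= min_umis & isotype_count <= isotype_factor * median_isotype
}

#' Call cells from DNA read totals, amplicon coverage and antibody QC
#'
#' Applies, in AND, (i) the barcode-rank knee on total amplicon reads,
#' (ii) the per-cell amplicon coverage rule, and (iii) the antibody-count
#' rules. The isotype median is computed over post-knee candidates so that
#' ambient barcodes cannot distort it.
#'
#' @param amplicon_reads Named vector, total DNA reads per barcode.
#' @param interval_depths Matrix barcodes x intervals of DNA reads.
#' @param ab_counts Deduplicated count matrix (barcodes x antibodies).
#' @param panel `antibody_panel` identifying isotype-control columns.
#' @param min_fraction,min_reads,min_umis,isotype_factor Filter parameters.
#' @return data.frame (one row per barcode appearing in `amplicon_reads`)
#'   with the stored metrics, per-rule flags and overall `is_cell`.
#' @export
call_cells <- function(amplicon_reads, interval_depths, ab_counts, panel,
                       min_fraction = 0.6, min_reads = 8,
                       min_umis = 100, isotype_factor = 5) {
  bcs <- names(amplicon_reads)
  stopifnot(!is.null(bcs), all(bcs %in% rownames(interval_depths)))
  thr <- rank_inflection(amplicon_reads)
  pass_knee <- bcs %in% attr(thr, "candidates")
  cov <- amplicon_coverage_ok(interval_depths[bcs, , drop = FALSE],
                              min_fraction, min_reads)
  iso_cols <- panel$name[panel$is_isotype_control]
  tot <- iso <- numeric(length(bcs))
  present <- bcs %in% rownames(ab_counts)
  tot[present] <- rowSums(ab_counts[bcs[present], , drop = FALSE])
  iso[present] <- rowSums(ab_counts[bcs[present], iso_cols, drop = FALSE])
  med_iso <- stats::median(iso[pass_knee])
  pass_ab <- antibody_qc(tot, iso, med_iso, min_umis, isotype_factor)
  frac_cov <- rowMeans(interval_depths[bcs, , drop = FALSE] >= min_reads)
  data.frame(cell_barcode = bcs,
             amplicon_reads = as.numeric(amplicon_reads),
             fraction_covered = as.numeric(frac_cov),
             total_ab_umis = tot, isotype_count = iso,
             pass_knee = pass_knee, pass_coverage = as.logical(cov),
             pass_antibody = pass_ab,
             is_cell = pass_knee & cov & pass_ab,
             row.names = NULL)
}

#' Read an amplicon panel BED file (0-based half-open intervals)
#' @param path BED file path.
#' @return A `GRanges` of panel intervals, named by the BED name column when
#'   present.
#' @export
read_amplicon_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}
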