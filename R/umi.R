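#' Count molecules in one UMI set with the adjacency network method
#'
#' PCR and sequencing errors scatter reads from one molecule across several
#' near-identical UMIs. The adjacency rule merges UMI `b` into UMI `a` when
#' the two differ by a single substitution and `count(a) >= 2*count(b) - 1`,
#' i.e. the error UMI is rare relative to its putative parent. Nodes are
#' visited in order of decreasing read count (ties broken by lexicographic
#' UMI order); each unaccounted node is selected as a true molecule and
#' absorbs its not-yet-covered children one adjacency step away. The molecule
#' count is the number of selected nodes.
#'
#' @param umis Named integer vector: UMI sequence -> read count. May be empty.
#' @return Integer molecule count (0 for an empty set).
#' @examples
#' adjacency_dedup(c(AAAAAAAAAA = 10, AAAAAAAAAT = 1))  # 1 molecule
#' adjacency_dedup(c(AAAAAAAAAA = 2, AAAAAAAAAT = 2))   # merge blocked: 2
#' @export
adjacency_dedup <- function(umis) {
  if (length(umis) == 0) return(0L)
  counts <- as.integer(umis)
  seqs <- names(umis)
  if (is.null(seqs) || any(!nzchar(seqs))) stop("UMIs must be named")
  if (length(unique(nchar(seqs))) != 1L) stop("UMIs of unequal length")
  if (any(counts < 1L)) stop("UMI read counts must be >= 1")
  if (anyDuplicated(seqs)) stop("duplicate UMI sequences")
  n <- length(seqs)
  if (n == 1L) return(1L)
  ord <- order(-counts, seqs)
  seqs <- seqs[ord]; counts <- counts[ord]
  cm <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  covered <- rep(FALSE, n)
  selected <- 0L
  for (i in seq_len(n)) {
    if (covered[i]) next
    selected <- selected + 1L
    covered[i] <- TRUE
    # children: Hamming distance 1 and parent count >= 2*child - 1
    d1 <- rowSums(cm != matrix(cm[i, ], n, ncol(cm), byrow = TRUE)) == 1L
    child <- d1 & (counts[i] >= 2L * counts - 1L)
    covered[child] <- TRUE
  }
  selected
}

#' Build the raw antibody count matrix from parsed tag reads
#'
#' Groups valid reads by (cell barcode, antibody), deduplicates each group's
#' UMI set with [adjacency_dedup()], and assembles the cells x antibodies
#' molecule count matrix. Per-cell raw (pre-deduplication) tag read totals are
#' returned alongside, as they feed the technical quality matrix.
#'
#' @param parsed data.frame from [parse_tag_reads()] (invalid rows ignored).
#' @param panel An `antibody_panel`; defines the column set.
#' @param cells Optional character vector fixing the row set (e.g. all
#'   whitelisted barcodes); defaults to barcodes observed in `parsed`.
#' @return List with `counts` (integer matrix, cells x antibodies),
#'   `raw_reads` (named integer vector of valid tag reads per cell).
#' @export
build_count_matrix <- function(parsed, panel, cells = NULL) {
  stopifnot(inherits(panel, "antibody_panel"))
  keep <- parsed$valid & !is.na(parsed$cell_barcode) & !is.na(parsed$antibody)
  p <- parsed[keep, c("cell_barcode", "antibody", "umi")]
  if (is.null(cells)) cells <- sort(unique(p$cell_barcode))
  counts <- matrix(0L, length(cells), nrow(panel),
                   dimnames = list(cells, panel$name))
  raw <- integer(length(cells)); names(raw) <- cells
  if (nrow(p) > 0) {
    p <- p[p$cell_barcode %in% cells, ]
    rr <- table(p$cell_barcode)
    raw[names(rr)] <- as.integer(rr)
    key <- paste(p$cell_barcode, p$antibody, sep = "\r")
    groups <- split(p$umi, key)
    dedup <- vapply(groups, function(u) adjacency_dedup(table_to_vec(u)),
                    integer(1))
    parts <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
    counts[cbind(match(parts[, 1], cells), match(parts[, 2], panel$name))] <-
      dedup
  }
  list(counts = counts, raw_reads = raw)
}

table_to_vec <- function(u) {
  tb <- table(u)
  v <- as.integer(tb)
  names(v) <- names(tb)
  v
}

#' Write a count matrix as TSV and MatrixMarket triples
#'
#' @param counts cells x antibodies matrix.
#' @param prefix Output path prefix; writes `<prefix>.tsv`, `<prefix>.mtx`,
#'   `<prefix>.barcodes.txt`, `<prefix>.antibodies.txt`.
#' @return Invisibly, the paths written.
#' @export
write_count_matrix <- function(counts, prefix) {
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(data.frame(cell_barcode = rownames(counts), counts,
                                check.names = FALSE),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), mtx)
  bc <- paste0(prefix, ".barcodes.txt")
  ab <- paste0(prefix, ".antibodies.txt")
  writeLines(rownames(counts), bc)
  writeLines(colnames(counts), ab)
  invisible(c(tsv, mtx, bc, ab))
}
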