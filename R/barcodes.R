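#' Define the combinatorial cell-barcode layout of Read 1
#'
#' Droplet platforms concatenate a cell barcode from several fixed-length
#' segments separated by constant linker sequences, preceded by a constant
#' 5' adapter. The schema describes those fixed positions so that segments
#' can be sliced out of Read 1 without alignment.
#'
#' @param segment_lengths Integer vector, bases per barcode segment (all > 0).
#' @param linker_sequences Character vector of constant sequences between
#'   consecutive segments; length must be `length(segment_lengths) - 1`.
#' @param adapter_5p Constant prefix before the first segment (may be `""`).
#' @return An object of class `barcode_schema`.
#' @examples
#' barcode_schema(c(9L, 9L), "GTACTCGC", "CGATGACG")
#' @export
barcode_schema <- function(segment_lengths, linker_sequences = character(),
                           adapter_5p = "") {
  segment_lengths <- as.integer(segment_lengths)
  stopifnot(length(segment_lengths) >= 1, all(segment_lengths > 0),
            length(linker_sequences) == length(segment_lengths) - 1L,
            is.character(adapter_5p), length(adapter_5p) == 1L)
  ok <- grepl("^[ACGT]*$", c(adapter_5p, linker_sequences))
  if (!all(ok)) stop("adapter and linkers must be ACGT strings")
  structure(
    list(segment_lengths = segment_lengths,
         linker_sequences = as.character(linker_sequences),
         adapter_5p = adapter_5p),
    class = "barcode_schema")
}

#' @export
print.barcode_schema <- function(x, ...) {
  cat("barcode_schema:", length(x$segment_lengths), "segment(s) of",
      paste(x$segment_lengths, collapse = "+"), "bp; read span",
      schema_read_length(x), "bp\n")
  invisible(x)
}

#' Total Read 1 span covered by a schema (adapter + segments + linkers)
#' @param schema A [barcode_schema()].
#' @return Integer number of bases.
#' @export
schema_read_length <- function(schema) {
  nchar(schema$adapter_5p) + sum(schema$segment_lengths) +
    sum(nchar(schema$linker_sequences))
}

min_pairwise_hamming <- function(entries) {
  n <- length(entries)
  if (n < 2) return(NA_integer_)
  m <- do.call(rbind, strsplit(entries, "", fixed = TRUE))
  best <- nchar(entries[1])
  for (i in seq_len(n - 1)) {
    d <- rowSums(m[(i + 1):n, , drop = FALSE] !=
                   matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
  }
  as.integer(best)
}

#' Build a whitelist of valid barcode segments
#'
#' One character vector of equal-length ACGT entries per segment. The minimum
#' pairwise Hamming distance of each segment list is computed at load time;
#' correction at Hamming distance 1 is unambiguous only when that distance
#' is at least 3.
#'
#' @param segments A character vector (single segment) or list of character
#'   vectors, one per barcode segment.
#' @return An object of class `tag_whitelist` with per-segment
#'   `min_distance` attribute.
#' @export
whitelist <- function(segments) {
  if (is.character(segments)) segments <- list(segments)
  stopifnot(length(segments) >= 1)
  for (s in segments) {
    stopifnot(is.character(s), length(s) >= 1)
    if (length(unique(nchar(s))) != 1L)
      stop("whitelist entries must all have the same length within a segment")
    if (!all(grepl("^[ACGT]+$", s))) stop("whitelist alphabet is {A,C,G,T}")
    if (anyDuplicated(s)) stop("duplicate whitelist entries")
  }
  structure(list(segments = lapply(segments, as.character)),
            min_distance = vapply(segments, min_pairwise_hamming, integer(1)),
            class = "tag_whitelist")
}

#' Read a whitelist from one-sequence-per-line text files
#' @param paths One file per barcode segment.
#' @return A [whitelist()].
#' @export
read_whitelist <- function(paths) {
  whitelist(lapply(paths, function(p) toupper(readLines(p, warn = FALSE))))
}

# Hash index mapping every sequence within Hamming distance 1 of a whitelist
# entry to that entry. A key reachable from >1 distinct entry is marked
# ambiguous (NA); exact whitelist entries always map to themselves (distance
# 0 beats any distance-1 neighbor).
hamming1_index <- function(entries) {
  L <- nchar(entries[1])
  keys <- entries
  vals <- entries
  for (pos in seq_len(L)) {
    for (b in c("A", "C", "G", "T")) {
      mut <- entries
      substr(mut, pos, pos) <- b
      keep <- mut != entries
      keys <- c(keys, mut[keep])
      vals <- c(vals, entries[keep])
    }
  }
  dup_keys <- unique(keys[duplicated(keys)])
  amb_key <- if (length(dup_keys)) {
    amb <- vapply(split(vals[keys %in% dup_keys], keys[keys %in% dup_keys]),
                  function(v) length(unique(v)) > 1L, logical(1))
    setdiff(names(amb)[amb], entries)
  } else character()
  first <- !duplicated(keys)
  idx <- vals[first]
  names(idx) <- keys[first]
  idx[entries] <- entries
  idx[amb_key] <- NA_character_
  idx
}

#' Correct an observed sequence against a whitelist segment
#'
#' Matches an observed fixed-length sequence to the unique whitelist entry
#' within `max_dist` substitutions. Exact matches are returned at distance 0.
#' Two or more equidistant nearest entries, or a nearest distance above
#' `max_dist`, both yield no-match, with distinct reasons.
#'
#' @param observed Character vector of observed sequences.
#' @param entries Character vector of whitelist entries (one segment), or a
#'   [whitelist()] (its first segment is used).
#' @param max_dist Maximum substitutions tolerated (default 1).
#' @return A data.frame with columns `match` (corrected entry or `NA`) and
#'   `reason` (`"exact"`, `"corrected"`, `"ambiguous"`, `"no_match"`,
#'   `"length"`).
#' @examples
#' correct_sequence(c("ACGTACGT", "ACGTACGA"), c("ACGTACGA"))
#' @export
correct_sequence <- function(observed, entries, max_dist = 1L) {
  if (inherits(entries, "tag_whitelist")) entries <- entries$segments[[1]]
  L <- nchar(entries[1])
  n <- length(observed)
  match_out <- rep(NA_character_, n)
  reason <- rep("no_match", n)
  bad_len <- nchar(observed) != L
  reason[bad_len] <- "length"
  use <- which(!bad_len)
  if (length(use) == 0)
    return(data.frame(match = match_out, reason = reason))
  if (max_dist == 1L) {
    idx <- hamming1_index(entries)
    hit <- idx[observed[use]]
    present <- observed[use] %in% names(idx)
    amb <- present & is.na(hit)
    got <- present & !is.na(hit)
    match_out[use[got]] <- hit[got]
    reason[use[got]] <- ifelse(observed[use[got]] == hit[got],
                               "exact", "corrected")
    reason[use[amb]] <- "ambiguous"
  } else {
    em <- do.call(rbind, strsplit(entries, "", fixed = TRUE))
    for (k in use) {
      obs <- strsplit(observed[k], "", fixed = TRUE)[[1]]
      d <- rowSums(em != matrix(obs, nrow(em), L, byrow = TRUE))
      dm <- min(d)
      if (dm > max_dist) next
      if (sum(d == dm) > 1L) { reason[k] <- "ambiguous"; next }
      match_out[k] <- entries[which.min(d)]
      reason[k] <- if (dm == 0) "exact" else "corrected"
    }
  }
  data.frame(match = match_out, reason = reason)
}

# allow up to 1 mismatch in fixed adapter/linker sequences (cutadapt-like
# tolerance without indel handling)
fixed_seq_ok <- function(observed, expected) {
  if (nchar(expected) == 0) return(rep(TRUE, length(observed)))
  out <- rep(FALSE, length(observed))
  full <- nchar(observed) == nchar(expected)
  if (any(full)) {
    obs <- do.call(rbind, strsplit(observed[full], "", fixed = TRUE))
    exp <- strsplit(expected, "", fixed = TRUE)[[1]]
    out[full] <-
      rowSums(obs != matrix(exp, nrow(obs), length(exp), byrow = TRUE)) <= 1L
  }
  out
}

#' Parse cell barcodes from Read 1 sequences
#'
#' Slices barcode segments out of fixed schema positions, verifies adapter and
#' linker placement (at most one substitution each), and corrects every
#' segment independently against its whitelist. A read succeeds only if every
#' segment resolves to a unique whitelist entry at Hamming distance <= 1.
#'
#' @param read1_seq Character vector of Read 1 sequences.
#' @param read1_qual Optional Read 1 quality strings (unused by the fixed
#'   position parser; retained for interface symmetry).
#' @param schema A [barcode_schema()].
#' @param wl A [whitelist()] with one segment list per schema segment.
#' @return data.frame with `cell_barcode` (concatenated corrected segments or
#'   `NA`), `valid`, and `reason` (`"ok"`, `"structure"`, `"too_short"`,
#'   `"segment"`).
#' @export
parse_cell_barcode <- function(read1_seq, read1_qual = NULL, schema, wl) {
  stopifnot(inherits(schema, "barcode_schema"), inherits(wl, "tag_whitelist"),
            length(wl$segments) == length(schema$segment_lengths))
  n <- length(read1_seq)
  need <- schema_read_length(schema)
  valid <- rep(TRUE, n)
  reason <- rep("ok", n)
  short <- nchar(read1_seq) < need
  valid[short] <- FALSE; reason[short] <- "too_short"
  pos <- 1L
  ok_struct <- !short
  seg_starts <- integer(length(schema$segment_lengths))
  # adapter
  if (nchar(schema$adapter_5p) > 0 && any(ok_struct)) {
    ad <- substr(read1_seq, 1L, nchar(schema$adapter_5p))
    bad <- ok_struct & !fixed_seq_ok(ad, schema$adapter_5p)
    valid[bad] <- FALSE; reason[bad] <- "structure"
    ok_struct <- ok_struct & !bad
  }
  pos <- pos + nchar(schema$adapter_5p)
  for (i in seq_along(schema$segment_lengths)) {
    seg_starts[i] <- pos
    pos <- pos + schema$segment_lengths[i]
    if (i < length(schema$segment_lengths)) {
      lk <- schema$linker_sequences[i]
      if (nchar(lk) > 0 && any(ok_struct)) {
        obs <- substr(read1_seq, pos, pos + nchar(lk) - 1L)
        bad <- ok_struct & !fixed_seq_ok(obs, lk)
        valid[bad] <- FALSE; reason[bad] <- "structure"
        ok_struct <- ok_struct & !bad
      }
      pos <- pos + nchar(lk)
    }
  }
  segs <- matrix(NA_character_, n, length(schema$segment_lengths))
  for (i in seq_along(schema$segment_lengths)) {
    raw <- substr(read1_seq, seg_starts[i],
                  seg_starts[i] + schema$segment_lengths[i] - 1L)
    cor <- correct_sequence(raw, wl$segments[[i]], max_dist = 1L)
    segs[, i] <- cor$match
    bad <- ok_struct & is.na(cor$match)
    valid[bad] <- FALSE; reason[bad] <- "segment"
  }
  bc <- rep(NA_character_, n)
  ok <- valid
  if (any(ok))
    bc[ok] <- do.call(paste0, as.data.frame(segs[ok, , drop = FALSE]))
  data.frame(cell_barcode = bc, valid = valid, reason = reason)
}

#' Load an antibody panel table
#'
#' CSV with columns `name`, `sequence` (8 bp tag) and `is_isotype_control`.
#' Tags are validated to be mutually separated by at least 3 substitutions so
#' that Hamming-1 correction can never be ambiguous.
#'
#' @param path CSV file path.
#' @return data.frame of class `antibody_panel`.
#' @export
read_antibody_panel <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_antibody_panel(p)
}

#' Validate an antibody panel data.frame
#' @param p data.frame with `name`, `sequence`, `is_isotype_control`.
#' @return Validated panel with class `antibody_panel`.
#' @export
as_antibody_panel <- function(p) {
  stopifnot(all(c("name", "sequence", "is_isotype_control") %in% names(p)))
  p$sequence <- toupper(p$sequence)
  p$is_isotype_control <- as.logical(p$is_isotype_control)
  if (any(nchar(p$sequence) != 8L)) stop("antibody tags must be 8 bp")
  if (anyDuplicated(p$name)) stop("duplicate antibody names")
  md <- min_pairwise_hamming(p$sequence)
  if (!is.na(md) && md < 3L)
    stop("antibody tags must have pairwise Hamming distance >= 3, got ", md)
  class(p) <- c("antibody_panel", "data.frame")
  p
}

#' Parse antibody tag and UMI from Read 2 sequences
#'
#' Read 2 carries an 8 bp antibody tag followed by a 10 bp UMI. The tag is
#' corrected against the panel at Hamming distance <= 1; the UMI is accepted
#' only if all 10 bases have Phred quality >= 20 (Phred+33 encoding).
#'
#' @param read2_seq Character vector of Read 2 sequences.
#' @param read2_qual Character vector of Read 2 quality strings.
#' @param panel An `antibody_panel`.
#' @param tag_length,umi_length Layout of Read 2 (defaults 8 and 10).
#' @param min_umi_qual Minimum per-base UMI Phred score (default 20).
#' @return data.frame with `antibody` (panel name or `NA`), `umi`, `valid`,
#'   `reason` (`"ok"`, `"too_short"`, `"tag"`, `"umi_quality"`).
#' @export
parse_antibody_tag <- function(read2_seq, read2_qual, panel,
                               tag_length = 8L, umi_length = 10L,
                               min_umi_qual = 20L) {
  stopifnot(inherits(panel, "antibody_panel"),
            length(read2_seq) == length(read2_qual))
  n <- length(read2_seq)
  need <- tag_length + umi_length
  valid <- rep(TRUE, n); reason <- rep("ok", n)
  ab <- rep(NA_character_, n); umi <- rep(NA_character_, n)
  short <- nchar(read2_seq) < need | nchar(read2_qual) < need
  valid[short] <- FALSE; reason[short] <- "too_short"
  use <- !short
  if (any(use)) {
    tag <- substr(read2_seq, 1L, tag_length)
    cor <- correct_sequence(tag, panel$sequence, max_dist = 1L)
    hit <- match(cor$match, panel$sequence)
    bad <- use & is.na(cor$match)
    valid[bad] <- FALSE; reason[bad] <- "tag"
    uq <- substr(read2_qual, tag_length + 1L, need)
    minq <- vapply(uq, function(q) {
      if (nchar(q) < umi_length) return(-1L)
      min(utf8ToInt(q)) - 33L
    }, integer(1), USE.NAMES = FALSE)
    lowq <- use & valid & minq < min_umi_qual
    valid[lowq] <- FALSE; reason[lowq] <- "umi_quality"
    ok <- use & valid
    ab[ok] <- panel$name[hit[ok]]
    umi[ok] <- substr(read2_seq[ok], tag_length + 1L, need)
  }
  data.frame(antibody = ab, umi = umi, valid = valid, reason = reason)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Parse paired antibody-library reads into tagged molecules
#'
#' Reads paired FASTQ files (gzip transparent), parses the cell barcode from
#' Read 1 and the antibody tag + UMI from Read 2, and returns one row per read
#' with validity flags plus a failure-reason tally.
#'
#' @param fastq1,fastq2 Paths to Read 1 / Read 2 FASTQ files.
#' @param schema,wl,panel See [parse_cell_barcode()] and
#'   [parse_antibody_tag()].
#' @param log_tsv Optional path; if given, the failure-reason count table is
#'   written there as TSV.
#' @return data.frame with `cell_barcode`, `antibody`, `umi`, `valid`,
#'   `reason`; attribute `report` holds the reason tally.
#' @export
parse_tag_reads <- function(fastq1, fastq2, schema, wl, panel, log_tsv = NULL) {
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  if (length(r1$seq) != length(r2$seq))
    stop("paired FASTQ files have different read counts")
  pc <- parse_cell_barcode(r1$seq, r1$qual, schema, wl)
  pa <- parse_antibody_tag(r2$seq, r2$qual, panel)
  valid <- pc$valid & pa$valid
  reason <- ifelse(pc$valid, ifelse(pa$valid, "ok", pa$reason),
                   paste0("barcode_", pc$reason))
  out <- data.frame(cell_barcode = pc$cell_barcode, antibody = pa$antibody,
                    umi = pa$umi, valid = valid, reason = reason)
  rep_tab <- as.data.frame(table(reason = reason), stringsAsFactors = FALSE)
  names(rep_tab)[2] <- "reads"
  attr(out, "report") <- rep_tab
  if (!is.null(log_tsv))
    utils::write.table(rep_tab, log_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
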