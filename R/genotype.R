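#' Condense a diploid genotype call into a coded value
#'
#' Codes: 0 wild type, 1 heterozygous alternate, 2 homozygous alternate,
#' 3 no call. A call is demoted to no-call when missing, when its quality is
#' below `min_gq`, or when its total depth is below `min_dp`.
#'
#' @param gt Character vector of diploid GT strings (`"0/0"`, `"0/1"`,
#'   `"1/1"`, `"./."`; `|` separators accepted).
#' @param gq Numeric call quality (GQ, or site QUAL if so configured).
#' @param dp Numeric total read depth.
#' @param min_gq Minimum quality (default 30).
#' @param min_dp Minimum depth (default 10).
#' @return Integer vector of codes in \{0,1,2,3\}.
#' @export
condense_call <- function(gt, gq, dp, min_gq = 30, min_dp = 10) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  if (any(grepl("[2-9]", gt)))
    stop("multiallelic genotype encountered; records must be pre-split")
  code <- rep(3L, length(gt))
  known <- !is.na(gt) & gt %in% c("0/0", "0/1", "1/0", "1/1")
  zyg <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  code[known] <- zyg[gt[known]]
  low <- is.na(gq) | is.na(dp) | gq < min_gq | dp < min_dp
  code[low] <- 3L
  code
}

#' Read a multi-sample VCF of per-cell calls into a coded genotype matrix
#'
#' Expects one sample column per cell barcode and biallelic, left-aligned
#' records (pre-normalized input; multiallelic records are rejected). GT, GQ
#' and DP are extracted per cell and condensed with [condense_call()].
#'
#' @param path VCF file path.
#' @param min_gq,min_dp Filter thresholds passed to [condense_call()].
#' @param quality_from `"GQ"` (per-sample genotype quality, default) or
#'   `"QUAL"` (site quality applied to every sample).
#' @return Integer matrix cells x variants with codes in \{0,1,2,3\};
#'   attribute `variants` holds a data.frame of locus metadata (id, chrom,
#'   pos, ref, alt).
#' @export
read_genotype_vcf <- function(path, min_gq = 30, min_dp = 10,
                              quality_from = c("GQ", "QUAL")) {
  quality_from <- match.arg(quality_from)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)  # single-record VCF drops to a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multiallelic VCF records; split and left-align before import")
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (quality_from == "GQ") {
    gq <- suppressWarnings(
      vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  } else {
    gq <- matrix(as.numeric(fix$QUAL), nrow(gt), ncol(gt))
    dimnames(gq) <- dimnames(gt)
  }
  codes <- condense_call(as.vector(gt), as.vector(gq), as.vector(dp),
                         min_gq, min_dp)
  m <- matrix(codes, nrow = ncol(gt), ncol = nrow(gt), byrow = TRUE,
              dimnames = list(colnames(gt), NULL))
  vid <- paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = "_")
  has_id <- !is.na(fix$ID) & fix$ID != "."
  vid[has_id] <- fix$ID[has_id]
  colnames(m) <- vid
  attr(m, "variants") <- data.frame(id = vid, chrom = fix$CHROM,
                                    pos = as.integer(fix$POS),
                                    ref = fix$REF, alt = fix$ALT)
  m
}

#' Assign clone labels from coded genotypes at the relevant loci
#'
#' The clone (combined variant call) of a cell is the tuple of its per-locus
#' states over the configured relevant loci. With two loci and four call
#' states per locus, 16 labels are possible. With `merge_alternates = TRUE`
#' heterozygous and homozygous alternate states collapse into a single
#' "mutant" state (three states per locus), which suppresses label noise
#' caused by allele dropout.
#'
#' @param gm Coded genotype matrix (cells x variants) or a single row.
#' @param loci Character or integer vector of relevant variant columns.
#' @param merge_alternates Collapse codes \{1,2\} into `"mut"`.
#' @return Character vector of clone labels, one per cell; locus states
#'   joined with `":"`. States are `"wt"`, `"het"`, `"hom"` (or `"mut"`),
#'   `"nc"`.
#' @export
assign_clone <- function(gm, loci, merge_alternates = FALSE) {
  if (is.null(dim(gm))) gm <- matrix(gm, 1, dimnames = list(NULL, names(gm)))
  if (length(loci) == 0) stop("empty loci list")
  sub <- gm[, loci, drop = FALSE]
  lab <- if (merge_alternates) c("wt", "mut", "mut", "nc")
         else c("wt", "het", "hom", "nc")
  states <- matrix(lab[sub + 1L], nrow(sub), ncol(sub))
  apply(states, 1, paste, collapse = ":")
}

#' Toy pileup genotyper from per-site allele counts
#'
#' A deliberately simple stand-in genotyper used by the synthetic end-to-end
#' fixtures: genotype from the alternate-allele fraction f (f < 0.2 ref/ref,
#' 0.2 <= f <= 0.8 het, f > 0.8 alt/alt), with a quality score defined as
#' -10*log10 of the binomial probability of the observed counts under the
#' runner-up genotype model (allele-fraction models 0.05/0.5/0.95). It is a
#' toy: no base qualities, no priors, no indel realignment.
#'
#' @param ref_reads,alt_reads Non-negative integer read counts.
#' @return data.frame with `gt` (`"0/0"`, `"0/1"`, `"1/1"`, or `"./."` at
#'   zero depth), `gq` (toy quality score), `dp`.
#' @export
toy_pileup_genotype <- function(ref_reads, alt_reads) {
  stopifnot(all(ref_reads >= 0), all(alt_reads >= 0),
            length(ref_reads) == length(alt_reads))
  dp <- ref_reads + alt_reads
  gt <- rep("./.", length(dp))
  gq <- rep(0, length(dp))
  pos <- dp > 0
  f <- ifelse(pos, alt_reads / dp, NA_real_)
  gt[pos & f < 0.2] <- "0/0"
  gt[pos & f >= 0.2 & f <= 0.8] <- "0/1"
  gt[pos & f > 0.8] <- "1/1"
  models <- c("0/0" = 0.05, "0/1" = 0.5, "1/1" = 0.95)
  for (k in which(pos)) {
    lik <- stats::dbinom(alt_reads[k], dp[k], models)
    runner <- max(lik[names(models) != gt[k]])
    gq[k] <- -10 * log10(max(runner, 1e-300))
  }
  data.frame(gt = gt, gq = gq, dp = dp)
}

#' Clone fractions per group
#'
#' Tabulates the fraction of cells carrying each clone label, optionally
#' within groups (e.g. timepoints). Labels containing a no-call state are
#' tallied but flagged so they can be reported separately.
#'
#' @param labels Character vector of clone labels (from [assign_clone()]).
#' @param group Optional grouping factor (e.g. timepoint); a single group is
#'   assumed when omitted.
#' @return data.frame with `group`, `clone`, `n`, `n_group`, `fraction`,
#'   `percent`, `has_no_call`.
#' @export
clone_fractions <- function(labels, group = NULL) {
  if (is.null(group)) group <- rep("all", length(labels))
  stopifnot(length(group) == length(labels))
  tb <- as.data.frame(table(group = group, clone = labels),
                      stringsAsFactors = FALSE)
  tb <- tb[tb$Freq > 0, ]
  ng <- table(group)
  tb$n <- tb$Freq
  tb$Freq <- NULL
  tb$n_group <- as.integer(ng[tb$group])
  tb$fraction <- tb$n / tb$n_group
  tb$percent <- 100 * tb$fraction
  tb$has_no_call <- grepl("(^|:)nc(:|$)", tb$clone)
  tb[order(tb$group, -tb$n), ]
}

#' Write a coded genotype matrix as TSV
#' @param gm Coded matrix from [read_genotype_vcf()].
#' @param path Output TSV path.
#' @export
write_genotype_matrix <- function(gm, path) {
  utils::write.table(data.frame(cell_barcode = rownames(gm), gm,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
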