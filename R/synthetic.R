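#' Specify a planted cell population
#'
#' @param name Population name (unique within a scenario).
#' @param n_cells Number of cells (> 0).
#' @param genotype Named integer vector of per-locus codes (0 wild type,
#'   1 heterozygous, 2 homozygous alternate).
#' @param ab_mean Named numeric vector: mean log molecule count per panel
#'   antibody.
#' @param ab_sd Cell-to-cell dispersion of the log profile (lognormal
#'   biological noise).
#' @param gradient_slopes Named numeric vector of log-scale antibody slopes
#'   over the latent within-population position in [0, 1]; empty for flat
#'   populations.
#' @param position_range Range of the latent position occupied by this
#'   population (allows planting populations at opposite ends of a shared
#'   gradient).
#' @param blast Logical: carries a blast immunophenotype (used to pick blast
#'   clusters in the gradient analysis).
#' @return List of class `population_spec`.
#' @export
population_spec <- function(name, n_cells, genotype, ab_mean, ab_sd = 0.2,
                            gradient_slopes = numeric(),
                            position_range = c(0, 1), blast = FALSE) {
  stopifnot(n_cells > 0, !is.null(names(ab_mean)),
            all(genotype %in% 0:2))
  structure(list(name = name, n_cells = as.integer(n_cells),
                 genotype = genotype, ab_mean = ab_mean, ab_sd = ab_sd,
                 gradient_slopes = gradient_slopes,
                 position_range = position_range, blast = blast),
            class = "population_spec")
}

#' Specify the technical noise model of a simulated experiment
#'
#' @param depth_meanlog,depth_sdlog Log-normal per-cell depth factor; the
#'   factor multiplies every molecule rate of the cell and is the technical
#'   covariate the correction regression is expected to remove.
#' @param ambient_rate Ambient tag molecules as a fraction of planted
#'   molecules; assigned to random barcodes including empty droplets.
#' @param barcode_sub_rate Per-read probability of one substitution within
#'   the Read 1 barcode region.
#' @param umi_sub_rate Per-read probability of one substitution within the
#'   UMI.
#' @param umi_lowq_rate Per-read probability that one UMI base is emitted
#'   with Phred quality 10 (below the Q20 acceptance floor).
#' @param dropout_prob Allele dropout probability: a heterozygous site loses
#'   one allele and presents as homozygous (either direction, equal odds).
#' @param n_empty Number of empty (ambient-only) droplet barcodes.
#' @param empty_depth_factor DNA depth of empty barcodes relative to the
#'   median cell.
#' @param copies_lambda Extra sequenced copies per molecule ~ Poisson.
#' @return List of class `tech_model`.
#' @export
tech_model <- function(depth_meanlog = 0, depth_sdlog = 0.5,
                       ambient_rate = 0.02, barcode_sub_rate = 0.002,
                       umi_sub_rate = 0.001, umi_lowq_rate = 0.002,
                       dropout_prob = 0.05, n_empty = 1000,
                       empty_depth_factor = 0.005, copies_lambda = 0.5) {
  rates <- c(ambient_rate, barcode_sub_rate, umi_sub_rate, umi_lowq_rate,
             dropout_prob)
  stopifnot(all(rates >= 0), all(rates <= 1), depth_sdlog >= 0)
  structure(list(depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 ambient_rate = ambient_rate,
                 barcode_sub_rate = barcode_sub_rate,
                 umi_sub_rate = umi_sub_rate, umi_lowq_rate = umi_lowq_rate,
                 dropout_prob = dropout_prob, n_empty = as.integer(n_empty),
                 empty_depth_factor = empty_depth_factor,
                 copies_lambda = copies_lambda),
            class = "tech_model")
}

rand_dna <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n, len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# greedily draw `n` length-`len` sequences with pairwise Hamming >= min_dist
rand_dna_separated <- function(n, len, min_dist = 3) {
  out <- character(0)
  tries <- 0
  while (length(out) < n) {
    cand <- rand_dna(max(2L * (n - length(out)), 8L), len)
    for (s in cand) {
      if (length(out) == 0) { out <- s; next }
      d <- vapply(out, function(o)
        sum(strsplit(o, "")[[1]] != strsplit(s, "")[[1]]), integer(1))
      if (min(d) >= min_dist) out <- c(out, s)
      if (length(out) == n) break
    }
    tries <- tries + 1
    if (tries > 200) stop("could not construct separated sequence set")
  }
  out
}

#' Bundled synthetic barcode schema (two 9 bp segments)
#' @return A [barcode_schema()] with an 8 bp adapter and one 8 bp linker.
#' @export
synthetic_schema <- function() {
  barcode_schema(c(9L, 9L), linker_sequences = "GTACTCGC",
                 adapter_5p = "CGATGACG")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Deterministic synthetic whitelist
#' @param n_per_segment Entries per barcode segment.
#' @param seed Seed for the deterministic construction.
#' @return A [whitelist()] with two 9 bp segments, pairwise Hamming >= 3.
#' @export
synthetic_whitelist <- function(n_per_segment = 96, seed = 42) {
  with_seed(seed, whitelist(list(rand_dna_separated(n_per_segment, 9L),
                                 rand_dna_separated(n_per_segment, 9L))))
}

#' Bundled synthetic antibody panel
#'
#' Ten hematopoietic markers plus an IgG1 isotype control, with 8 bp tags at
#' pairwise Hamming distance >= 3 (deterministic construction).
#' @param seed Seed for the tag construction.
#' @return An `antibody_panel` data.frame.
#' @export
synthetic_panel <- function(seed = 43) {
  nm <- c("CD3", "CD11b", "CD15", "CD33", "CD34", "CD38", "CD45", "CD56",
          "CD71", "IgG1")
  tags <- with_seed(seed, rand_dna_separated(length(nm), 8L))
  as_antibody_panel(data.frame(name = nm, sequence = tags,
                               is_isotype_control = nm == "IgG1"))
}

#' Simulate ground truth for a droplet experiment
#'
#' Draws, per cell: a unique combinatorial barcode, a latent gradient
#' position, a log-normal depth factor, planted genotypes (pre- and
#' post-allele-dropout), and planted antibody molecule counts
#' `Poisson(exp(profile + slope * position + biological noise) * depth)`.
#' Ambient molecules and empty-droplet barcodes are generated alongside.
#'
#' @param populations List of [population_spec()]s (unique names).
#' @param tech A [tech_model()].
#' @param panel An `antibody_panel`.
#' @param wl Optional [whitelist()] (defaults to [synthetic_whitelist()]).
#' @param seed Integer seed; fixed seed reproduces the truth exactly.
#' @return List of class `gt_truth` with `cells` (data.frame: barcode,
#'   population, position, depth_factor, `geno_<locus>` pre-dropout,
#'   `obs_<locus>` post-dropout), `molecules` (cells x antibodies planted
#'   counts), `log_mean` (biological log profile actually drawn, without
#'   depth), `ambient` (data.frame barcode/antibody/n), `empty_barcodes`,
#'   and the specs used.
#' @export
simulate_truth <- function(populations, tech, panel = synthetic_panel(),
                           wl = synthetic_whitelist(), seed = 1) {
  nms <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate population names")
  loci <- unique(unlist(lapply(populations, function(p) names(p$genotype))))
  set.seed(seed)
  n_cells <- sum(vapply(populations, `[[`, integer(1), "n_cells"))
  combos <- expand.grid(s1 = wl$segments[[1]], s2 = wl$segments[[2]],
                        stringsAsFactors = FALSE)
  need <- n_cells + tech$n_empty
  if (need > nrow(combos))
    stop("whitelist too small for requested cells + empty droplets")
  pick <- sample.int(nrow(combos), need)
  bcs <- paste0(combos$s1[pick], combos$s2[pick])
  cell_bc <- bcs[seq_len(n_cells)]
  empty_bc <- bcs[-seq_len(n_cells)]
  pop <- rep(nms, vapply(populations, `[[`, integer(1), "n_cells"))
  pos <- numeric(n_cells)
  geno <- matrix(0L, n_cells, length(loci), dimnames = list(NULL, loci))
  logmu <- matrix(NA_real_, n_cells, nrow(panel),
                  dimnames = list(cell_bc, panel$name))
  for (p in populations) {
    idx <- which(pop == p$name)
    pos[idx] <- stats::runif(length(idx), p$position_range[1],
                             p$position_range[2])
    for (l in names(p$genotype)) geno[idx, l] <- p$genotype[[l]]
    mu <- matrix(p$ab_mean[panel$name], length(idx), nrow(panel),
                 byrow = TRUE)
    if (length(p$gradient_slopes) > 0) {
      sl <- rep(0, nrow(panel)); names(sl) <- panel$name
      sl[names(p$gradient_slopes)] <- p$gradient_slopes
      mu <- mu + outer(pos[idx], sl)
    }
    mu <- mu + matrix(stats::rnorm(length(mu), 0, p$ab_sd), nrow(mu))
    logmu[idx, ] <- mu
  }
  depth <- stats::rlnorm(n_cells, tech$depth_meanlog, tech$depth_sdlog)
  lambda <- exp(logmu) * depth
  mol <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda),
                dimnames = dimnames(lambda))
  # allele dropout: heterozygous sites lose one allele
  obs <- geno
  het <- which(geno == 1L)
  if (length(het) > 0 && tech$dropout_prob > 0) {
    drop <- het[stats::runif(length(het)) < tech$dropout_prob]
    obs[drop] <- ifelse(stats::runif(length(drop)) < 0.5, 0L, 2L)
  }
  # ambient molecules spread over all barcodes (cells + empties)
  ambient <- NULL
  n_amb <- round(tech$ambient_rate * sum(mol))
  if (n_amb > 0) {
    amb_bc <- sample(bcs, n_amb, replace = TRUE)
    amb_ab <- sample(panel$name, n_amb, replace = TRUE,
                     prob = pmax(colSums(mol), 1))
    ambient <- as.data.frame(table(barcode = amb_bc, antibody = amb_ab),
                             stringsAsFactors = FALSE)
    names(ambient)[3] <- "n"
    ambient <- ambient[ambient$n > 0, ]
  }
  cells <- data.frame(barcode = cell_bc, population = pop, position = pos,
                      depth_factor = depth)
  for (l in loci) cells[[paste0("geno_", l)]] <- geno[, l]
  for (l in loci) cells[[paste0("obs_", l)]] <- obs[, l]
  structure(list(cells = cells, molecules = mol, log_mean = logmu,
                 ambient = ambient, empty_barcodes = empty_bc,
                 panel = panel, populations = populations, tech = tech,
                 loci = loci, whitelist = wl, seed = seed),
            class = "gt_truth")
}

#' @export
print.gt_truth <- function(x, ...) {
  cat("gt_truth:", nrow(x$cells), "cells in",
      length(x$populations), "population(s);",
      length(x$empty_barcodes), "empty droplets;",
      sum(x$molecules), "planted tag molecules\n")
  invisible(x)
}

# draw `m` UMIs pairwise Hamming >= 2 so that adjacency deduplication of an
# error-free library is exactly invertible
draw_umis <- function(m, len = 10L) {
  u <- rand_dna(m, len)
  if (m == 1) return(u)
  repeat {
    cm <- do.call(rbind, strsplit(u, "", fixed = TRUE))
    bad <- integer(0)
    for (i in seq_len(m - 1)) {
      d <- rowSums(cm[(i + 1):m, , drop = FALSE] !=
                     matrix(cm[i, ], m - i, len, byrow = TRUE))
      bad <- c(bad, i + which(d < 2))
    }
    bad <- unique(bad)
    if (length(bad) == 0) return(u)
    u[bad] <- rand_dna(length(bad), len)
  }
}

substitute_one_base <- function(seqs, hit, region_start, region_end) {
  if (!any(hit)) return(seqs)
  idx <- which(hit)
  pos <- sample(region_start:region_end, length(idx), replace = TRUE)
  for (k in seq_along(idx)) {
    old <- substr(seqs[idx[k]], pos[k], pos[k])
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    substr(seqs[idx[k]], pos[k], pos[k]) <- new
  }
  seqs
}

#' Emit paired antibody-library FASTQ files from a simulated truth
#'
#' One read pair per sequenced copy of every planted and ambient molecule.
#' Every molecule receives a distinct UMI (planted UMI sets are pairwise
#' Hamming >= 2, so adjacency deduplication of an error-free library is
#' exactly invertible); substitution and low-quality-base errors are
#' injected at the configured rates; read order is shuffled.
#'
#' @param truth A `gt_truth`.
#' @param fastq1,fastq2 Output paths (gzip when ending in `.gz`).
#' @param schema Barcode schema (default [synthetic_schema()]).
#' @param seed Seed for UMIs, copy numbers and injected errors.
#' @return Invisibly, `c(fastq1, fastq2)`; attribute `n_reads`.
#' @export
emit_antibody_reads <- function(truth, fastq1, fastq2,
                                schema = synthetic_schema(), seed = 2) {
  set.seed(seed)
  tech <- truth$tech
  mol_idx <- which(truth$molecules > 0, arr.ind = TRUE)
  mol <- data.frame(
    barcode = rownames(truth$molecules)[mol_idx[, 1]],
    antibody = colnames(truth$molecules)[mol_idx[, 2]],
    n = truth$molecules[mol_idx])
  if (!is.null(truth$ambient)) mol <- rbind(mol, truth$ambient)
  if (nrow(mol) == 0) {
    writeLines(character(0), con1 <- file(fastq1)); close(con1)
    writeLines(character(0), con2 <- file(fastq2)); close(con2)
    return(invisible(structure(c(fastq1, fastq2), n_reads = 0L)))
  }
  # aggregate planted + ambient per (barcode, antibody)
  key <- paste(mol$barcode, mol$antibody, sep = "\r")
  n_per <- tapply(mol$n, key, sum)
  groups <- names(n_per)
  umis <- lapply(as.integer(n_per), draw_umis)
  parts <- do.call(rbind, strsplit(groups, "\r", fixed = TRUE))
  per_mol <- data.frame(
    barcode = rep(parts[, 1], as.integer(n_per)),
    antibody = rep(parts[, 2], as.integer(n_per)),
    umi = unlist(umis))
  copies <- 1L + stats::rpois(nrow(per_mol), tech$copies_lambda)
  reads <- per_mol[rep(seq_len(nrow(per_mol)), copies), ]
  reads <- reads[sample.int(nrow(reads)), ]
  tagseq <- truth$panel$sequence[match(reads$antibody, truth$panel$name)]
  seg_len <- schema$segment_lengths
  r1 <- paste0(schema$adapter_5p,
               substr(reads$barcode, 1, seg_len[1]),
               schema$linker_sequences[1],
               substr(reads$barcode, seg_len[1] + 1, seg_len[1] + seg_len[2]))
  # inject one substitution in the barcode region of affected reads
  bc_start <- nchar(schema$adapter_5p) + 1L
  hit1 <- stats::runif(nrow(reads)) < tech$barcode_sub_rate
  r1 <- substitute_one_base(r1, hit1, bc_start, nchar(r1[1]))
  umi_seq <- reads$umi
  hit2 <- stats::runif(nrow(reads)) < tech$umi_sub_rate
  umi_seq <- substitute_one_base(umi_seq, hit2, 1L, 10L)
  r2 <- paste0(tagseq, umi_seq)
  q1 <- strrep("I", nchar(r1[1]))
  q2 <- rep(strrep("I", 18L), nrow(reads))
  lowq <- which(stats::runif(nrow(reads)) < tech$umi_lowq_rate)
  if (length(lowq) > 0) {
    p <- sample(9:18, length(lowq), replace = TRUE)
    for (k in seq_along(lowq)) substr(q2[lowq[k]], p[k], p[k]) <- "+"
  }
  ids <- paste0("@read", seq_len(nrow(reads)))
  write_fq <- function(path, ids, seqs, quals) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste(ids, seqs, "+", quals, sep = "\n"), con)
  }
  write_fq(fastq1, ids, r1, q1)
  write_fq(fastq2, ids, r2, q2)
  invisible(structure(c(fastq1, fastq2), n_reads = nrow(reads)))
}

#' Emit DNA-side fixtures: interval depth table and a per-cell VCF
#'
#' Per-interval read depths are Poisson around `cell depth factor x
#' interval efficiency x dna_depth`; empty-droplet barcodes receive the
#' configured small fraction of a typical cell's depth. Genotype loci map to
#' the first panel intervals; per-cell ref/alt read counts are drawn from
#' the post-dropout planted genotype and passed through
#' [toy_pileup_genotype()], and the resulting GT/GQ/DP calls are written as
#' a multi-sample VCF (one sample column per cell barcode).
#'
#' @param truth A `gt_truth`.
#' @param vcf_path Output VCF path (plain text).
#' @param n_intervals Panel size (default 49 intervals).
#' @param dna_depth Mean reads per interval for a depth-factor-1 cell.
#' @param seed Seed for depth and allele draws.
#' @return List: `interval_depths` (barcodes x intervals, cells then
#'   empties), `amplicon_reads` (named totals), `vcf` (path), `bed`
#'   (data.frame of 0-based half-open intervals).
#' @export
emit_dna_fixtures <- function(truth, vcf_path, n_intervals = 49,
                              dna_depth = 20, seed = 3) {
  set.seed(seed)
  tech <- truth$tech
  cells <- truth$cells
  loci <- truth$loci
  if (length(loci) > n_intervals) stop("more loci than intervals")
  eff <- stats::rlnorm(n_intervals, 0, 0.3)
  bcs <- c(cells$barcode, truth$empty_barcodes)
  depth_factor <- c(cells$depth_factor,
                    rep(tech$empty_depth_factor, length(truth$empty_barcodes)))
  lam <- outer(depth_factor * dna_depth, eff)
  depths <- matrix(stats::rpois(length(lam), lam), nrow(lam),
                   dimnames = list(bcs, paste0("interval", seq_len(n_intervals))))
  # toy genotyping at the locus intervals, cells only
  n <- nrow(cells)
  calls <- vector("list", length(loci))
  for (k in seq_along(loci)) {
    dp <- depths[seq_len(n), k]
    g <- cells[[paste0("obs_", loci[k])]]
    alt_p <- c(0, 0.5, 1)[g + 1L]
    alt <- stats::rbinom(n, dp, alt_p)
    calls[[k]] <- toy_pileup_genotype(dp - alt, alt)
  }
  bed <- data.frame(chrom = "chrS", start = (seq_len(n_intervals) - 1L) * 1000L,
                    end = (seq_len(n_intervals) - 1L) * 1000L + 250L,
                    name = colnames(depths))
  write_toy_vcf(vcf_path, cells$barcode, loci, calls,
                pos = bed$start[seq_along(loci)] + 100L)
  list(interval_depths = depths,
       amplicon_reads = rowSums(depths),
       vcf = vcf_path, bed = bed)
}

# minimal VCF 4.2 writer: one biallelic SNV record per locus, GT:GQ:DP per
# cell sample
write_toy_vcf <- function(path, samples, loci, calls, pos) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrS>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- character(length(loci))
  for (k in seq_along(loci)) {
    cc <- calls[[k]]
    fmt <- paste(cc$gt, round(cc$gq), cc$dp, sep = ":")
    rows[k] <- paste(c("chrS", pos[k], loci[k], "A", "G", ".", "PASS", ".",
                       "GT:GQ:DP", fmt), collapse = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a BED file of panel intervals (0-based half-open)
#' @param bed data.frame with chrom, start, end, name.
#' @param path Output path.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Verify internal consistency of a simulated truth
#'
#' Checks that barcodes are unique and whitelist-derived, genotype codes are
#' valid, molecule counts are non-negative and aligned with the cell table,
#' and that dropout only altered heterozygous sites.
#'
#' @param truth A `gt_truth`.
#' @return TRUE invisibly; stops on inconsistency.
#' @export
verify_truth <- function(truth) {
  cells <- truth$cells
  stopifnot(!anyDuplicated(c(cells$barcode, truth$empty_barcodes)),
            identical(rownames(truth$molecules), cells$barcode),
            all(truth$molecules >= 0))
  wl <- truth$whitelist
  s1 <- substr(cells$barcode, 1, 9); s2 <- substr(cells$barcode, 10, 18)
  stopifnot(all(s1 %in% wl$segments[[1]]), all(s2 %in% wl$segments[[2]]))
  for (l in truth$loci) {
    g <- cells[[paste0("geno_", l)]]; o <- cells[[paste0("obs_", l)]]
    stopifnot(all(g %in% 0:2), all(o %in% 0:2), all(o[g != 1L] == g[g != 1L]))
  }
  invisible(TRUE)
}
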