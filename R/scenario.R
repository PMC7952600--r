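#' Bundled three-population scenario
#'
#' Emulates a leukemia sample harboring two mutually exclusive mutant blast
#' clones (heterozygous at one locus each) plus a wild-type blast-like
#' population, at desk scale (~3,000 cells by default). Two variants:
#'
#' * `gradient = FALSE` (default): the three populations carry distinct
#'   antibody profiles and separate cleanly in phenotype space; used to
#'   validate clustering and concordance recovery. Being a simple
#'   well-separated mixture, its recommended Leiden resolution is 0.1.
#' * `gradient = TRUE`: the two mutant clones share one blast profile and
#'   lie on a common immunophenotypic continuum — a latent position in
#'   [0, 1] with monotone log-scale antibody slopes (CD15 rising; CD11b,
#'   CD33, CD56 falling) and the clones occupying overlapping position
#'   ranges (one dominating the low end, the other the high end). A
#'   CD3-high non-blast population is included to exercise blast-subset
#'   selection.
#'
#' The technical model uses clean-condition defaults: 1% allele dropout,
#' 2% ambient tags, 0.2%/0.1% barcode/UMI substitution, log-normal depth
#' with sdlog 0.5, 1,000 empty droplets.
#'
#' @param gradient Plant the shared continuum variant.
#' @param n_cells Approximate total planted cells.
#' @return List with `populations`, `tech`, `panel`, `loci`, and `params`
#'   (recommended n_vectors, min_dist, resolution, annotation rules and
#'   blast-selection rule).
#' @export
scenario_bundled <- function(gradient = FALSE, n_cells = 3000) {
  panel <- synthetic_panel()
  base <- c(CD3 = 0.8, CD11b = 2.5, CD15 = 2.5, CD33 = 4.3, CD34 = 3.0,
            CD38 = 4.0, CD45 = 3.0, CD56 = 2.2, CD71 = 2.5, IgG1 = 1.2)
  n1 <- round(n_cells * 0.4); n2 <- round(n_cells * 0.3)
  n3 <- n_cells - n1 - n2
  if (!gradient) {
    profA <- base
    profA[c("CD11b", "CD56", "CD15", "CD34", "CD71")] <-
      c(4.2, 3.8, 1.2, 1.5, 2.0)
    profB <- base
    profB[c("CD15", "CD34", "CD11b", "CD56", "CD71")] <-
      c(4.2, 4.0, 1.2, 1.2, 2.0)
    profC <- base
    profC[c("CD71", "CD34", "CD15", "CD11b", "CD56")] <-
      c(4.5, 2.5, 2.5, 2.5, 1.6)
    pops <- list(
      population_spec("cloneA", n1, c(KRASG13D = 1L, FLT3D835Y = 0L),
                      profA, blast = TRUE),
      population_spec("cloneB", n2, c(KRASG13D = 0L, FLT3D835Y = 1L),
                      profB, blast = TRUE),
      population_spec("wt_blast", n3, c(KRASG13D = 0L, FLT3D835Y = 0L),
                      profC, blast = TRUE))
    params <- list(n_vectors = 3, min_dist = 0.2, resolution = 0.1,
                   annotation_rules = c(CD11b = "blast_CD11b",
                                        CD15 = "blast_CD15",
                                        CD71 = "blast_CD71"))
  } else {
    # The continuum is carried by six markers with rising/falling slope
    # pairs whose bases are mirrored, so the expected per-cell total stays
    # near-flat along the gradient: the planted biological continuum must
    # be orthogonal to the technical depth covariate the regression
    # removes. The blast profile runs at ~1,500-2,000 tag molecules per
    # cell (a panel sequenced to saturation) so per-marker shot noise
    # stays well below the planted slopes.
    slopes <- c(CD15 = 2.5, CD34 = 2.5, CD71 = 1.8,
                CD11b = -2.5, CD56 = -2.5, CD33 = -1.8)
    profG <- c(CD3 = 1.2, CD11b = 6.45, CD15 = 3.95, CD33 = 6.1,
               CD34 = 3.95, CD38 = 4.7, CD45 = 3.7, CD56 = 6.45,
               CD71 = 3.9, IgG1 = 1.9)
    # The non-blast population is separated on markers that carry no slope
    # (CD3, CD38, CD45) and sits at the continuum midpoint on the gradient
    # markers, so the blast-offset mode and the continuum mode of the
    # corrected matrix are orthogonal and the second singular vector is
    # unambiguously the gradient axis.
    profN <- profG + slopes[names(profG)] * 0.5
    profN[is.na(profN)] <- profG[is.na(profN)]
    names(profN) <- names(profG)
    profN[c("CD3", "CD38", "CD45")] <- c(6.2, 1.0, 0.8)
    pops <- list(
      population_spec("cloneA", n1, c(KRASG13D = 1L, FLT3D835Y = 0L),
                      profG, ab_sd = 0.1, gradient_slopes = slopes,
                      position_range = c(0, 0.65), blast = TRUE),
      population_spec("cloneB", n2, c(KRASG13D = 0L, FLT3D835Y = 1L),
                      profG, ab_sd = 0.1, gradient_slopes = slopes,
                      position_range = c(0.35, 1), blast = TRUE),
      population_spec("normal", n3, c(KRASG13D = 0L, FLT3D835Y = 0L),
                      profN, blast = FALSE))
    params <- list(n_vectors = 3, min_dist = 0.1, resolution = 1,
                   annotation_rules = c(CD38 = "blast", CD3 = "lymphoid"))
  }
  params$blast_name <- "blast"
  list(populations = pops,
       tech = tech_model(dropout_prob = 0.01),
       panel = panel,
       loci = c("KRASG13D", "FLT3D835Y"),
       params = params)
}

#' Matrix-level observation of a simulated truth
#'
#' Produces the observed antibody count matrix (planted molecules plus
#' ambient molecules, over cell and empty-droplet barcodes) and per-barcode
#' raw read totals, mirroring what read emission, parsing and deduplication
#' would yield on an error-free library — useful for desk-scale runs that
#' skip read-level processing.
#'
#' @param truth A `gt_truth`.
#' @param seed Seed for the per-molecule copy-number draw.
#' @return List with `counts` (all barcodes x antibodies) and `raw_reads`
#'   (named per-barcode read totals).
#' @export
truth_matrices <- function(truth, seed = 4) {
  set.seed(seed)
  bcs <- c(truth$cells$barcode, truth$empty_barcodes)
  counts <- matrix(0L, length(bcs), nrow(truth$panel),
                   dimnames = list(bcs, truth$panel$name))
  counts[rownames(truth$molecules), ] <- truth$molecules
  if (!is.null(truth$ambient)) {
    idx <- cbind(match(truth$ambient$barcode, bcs),
                 match(truth$ambient$antibody, truth$panel$name))
    counts[idx] <- counts[idx] + truth$ambient$n
  }
  tot <- rowSums(counts)
  raw <- tot + stats::rpois(length(tot), truth$tech$copies_lambda * tot)
  names(raw) <- bcs
  list(counts = counts, raw_reads = raw)
}
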