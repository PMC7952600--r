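#' Default run configuration
#'
#' Nested list understood by [run_all()]. `input$mode` is `"simulate"`
#' (bundled scenario; optionally read-level, emitting and re-parsing FASTQ)
#' or `"files"` (user-supplied FASTQ pair, whitelist, panel CSV, interval
#' depth table and VCF). `params$sample_type` selects the per-experiment
#' preset: `"patient"` (3 singular vectors, min_dist 0.2, resolution 1),
#' `"pbmc"` (2, 0.2, 1), `"cell_lines"` (1, 0.2, 0.1); any explicitly set
#' parameter overrides its preset. In simulate mode, unset parameters
#' default to the scenario's recommended values.
#'
#' @return The default configuration list.
#' @export
default_config <- function() {
  list(
    input = list(
      mode = "simulate",
      read_level = FALSE,
      scenario = list(gradient = FALSE, n_cells = 3000),
      fastq1 = NULL, fastq2 = NULL, whitelist = NULL, panel = NULL,
      interval_depths = NULL, vcf = NULL),
    params = list(
      sample_type = "patient",
      n_vectors = NULL, min_dist = NULL, resolution = NULL,
      n_neighbors = 15, n_pcs = 16,
      min_gq = 30, min_dp = 10, min_umis = 100, isotype_factor = 5,
      min_fraction = 0.6, min_reads = 8,
      loci = NULL, merge_alternates = TRUE, drop_no_call = TRUE,
      annotation_rules = NULL, blast_name = "blast",
      gradient_window = 200),
    seed = 1,
    outdir = "genotag_run")
}

sample_type_presets <- list(
  patient = list(n_vectors = 3, min_dist = 0.2, resolution = 1),
  pbmc = list(n_vectors = 2, min_dist = 0.2, resolution = 1),
  cell_lines = list(n_vectors = 1, min_dist = 0.2, resolution = 0.1))

merge_config <- function(defaults, given, path = "") {
  for (k in names(given)) {
    if (!k %in% names(defaults))
      stop("unknown configuration key: ", path, k)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(given[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], given[[k]],
                                    paste0(path, k, "$"))
    } else {
      defaults[[k]] <- given[[k]]
    }
  }
  defaults
}

#' Validate and complete a run configuration
#'
#' Merges user settings over [default_config()], rejecting unknown keys,
#' applies the sample-type preset for unset parameters, and checks input
#' paths in `files` mode.
#'
#' @param config Partial configuration list, or a YAML file path.
#' @return Completed configuration.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  explicit <- if (!is.null(config$explicit_params)) config$explicit_params
              else names(config$params)
  config$explicit_params <- NULL
  cfg <- merge_config(default_config(), config)
  cfg$explicit_params <- explicit
  if (!cfg$input$mode %in% c("simulate", "files"))
    stop("input$mode must be 'simulate' or 'files'")
  if (!cfg$params$sample_type %in% names(sample_type_presets))
    stop("unknown sample_type: ", cfg$params$sample_type)
  preset <- sample_type_presets[[cfg$params$sample_type]]
  for (k in names(preset))
    if (is.null(cfg$params[[k]])) cfg$params[[k]] <- preset[[k]]
  if (cfg$input$mode == "files") {
    need <- c("fastq1", "fastq2", "whitelist", "panel", "interval_depths",
              "vcf")
    for (k in need) {
      if (is.null(cfg$input[[k]]))
        stop("files mode requires input$", k)
      if (!file.exists(cfg$input[[k]]))
        stop("input file not found: ", cfg$input[[k]])
    }
    if (is.null(cfg$params$loci))
      stop("files mode requires params$loci")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

pipeline_stages <- c("simulate", "parse", "count", "cellcall", "genotype",
                     "correct", "cluster", "concord", "gradient")

#' Run the full pipeline (or selected stages) under one configuration
#'
#' Executes simulate (or file ingestion) -> parse -> count -> cellcall ->
#' genotype -> correct -> cluster -> concord -> gradient, writing tabular
#' artifacts and a deterministic JSON manifest under `config$outdir`. State
#' is checkpointed (`state.rds`) so stages can be run one at a time; any
#' stage failure aborts with the stage name and leaves a `FAILED` marker.
#'
#' @param config Configuration (list or YAML path); see [default_config()].
#' @param stages Subset of stages to run (default: all, in order). Stages
#'   other than the first require the checkpoint left by their predecessor.
#' @return The pipeline state (invisibly): truth, counts, qc, genotypes,
#'   corrected matrix, clusters, embedding, concordance, gradient results.
#' @export
run_all <- function(config = list(), stages = NULL) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(cfg$outdir, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)
  if (is.null(stages)) stages <- pipeline_stages
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  state_path <- file.path(cfg$outdir, "state.rds")
  state <- if (stages[1] != pipeline_stages[1] && file.exists(state_path))
    readRDS(state_path) else list(cfg = cfg, manifest = list())
  state$cfg <- cfg
  for (st in pipeline_stages[pipeline_stages %in% stages]) {
    state <- tryCatch(
      do.call(paste0("stage_", st), list(state)),
      error = function(e) {
        writeLines(paste0(st, ": ", conditionMessage(e)), failed_marker)
        stop("stage ", st, " failed: ", conditionMessage(e), call. = FALSE)
      })
    saveRDS(state, state_path)
  }
  write_manifest(state)
  invisible(state)
}

out_tsv <- function(state, name, df) {
  utils::write.table(df, file.path(state$cfg$outdir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

stage_simulate <- function(state) {
  cfg <- state$cfg
  p <- cfg$params
  if (cfg$input$mode == "simulate") {
    scn <- scenario_bundled(gradient = isTRUE(cfg$input$scenario$gradient),
                            n_cells = cfg$input$scenario$n_cells)
    for (k in c("n_vectors", "min_dist", "resolution", "annotation_rules"))
      if (!k %in% cfg$explicit_params) p[[k]] <- scn$params[[k]]
    if (is.null(p$loci)) p$loci <- scn$loci
    truth <- simulate_truth(scn$populations, scn$tech, scn$panel,
                            seed = cfg$seed)
    verify_truth(truth)
    dna <- emit_dna_fixtures(truth, file.path(cfg$outdir, "cells.vcf"),
                             seed = cfg$seed + 3L)
    state$truth <- truth
    state$panel <- truth$panel
    state$dna <- dna
    out_tsv(state, "truth_cells.tsv", truth$cells)
    if (cfg$input$read_level) {
      state$fastq1 <- file.path(cfg$outdir, "tags_R1.fastq.gz")
      state$fastq2 <- file.path(cfg$outdir, "tags_R2.fastq.gz")
      emit_antibody_reads(truth, state$fastq1, state$fastq2,
                          seed = cfg$seed + 2L)
      state$whitelist <- truth$whitelist
      state$schema <- synthetic_schema()
    } else {
      tm <- truth_matrices(truth, seed = cfg$seed + 4L)
      state$counts <- tm$counts
      state$raw_reads <- tm$raw_reads
    }
    state$manifest$simulate <- list(
      n_cells = nrow(truth$cells), n_empty = length(truth$empty_barcodes),
      n_molecules = sum(truth$molecules), gradient =
        isTRUE(cfg$input$scenario$gradient))
  } else {
    state$panel <- read_antibody_panel(cfg$input$panel)
    state$whitelist <- read_whitelist(cfg$input$whitelist)
    state$schema <- synthetic_schema()
    state$fastq1 <- cfg$input$fastq1
    state$fastq2 <- cfg$input$fastq2
    depths <- utils::read.table(cfg$input$interval_depths, header = TRUE,
                                sep = "\t", row.names = 1)
    state$dna <- list(interval_depths = as.matrix(depths),
                      amplicon_reads = rowSums(as.matrix(depths)),
                      vcf = cfg$input$vcf)
    state$manifest$simulate <- list(mode = "files")
  }
  state$params <- p
  state
}

stage_parse <- function(state) {
  if (is.null(state$fastq1)) return(state)  # matrix-level run
  parsed <- parse_tag_reads(state$fastq1, state$fastq2, state$schema,
                            state$whitelist, state$panel,
                            log_tsv = file.path(state$cfg$outdir,
                                                "parse_log.tsv"))
  state$parsed <- parsed
  state$manifest$parse <- list(
    n_reads = nrow(parsed), n_valid = sum(parsed$valid))
  state
}

stage_count <- function(state) {
  if (is.null(state$parsed)) return(state)
  cm <- build_count_matrix(state$parsed, state$panel)
  state$counts <- cm$counts
  state$raw_reads <- cm$raw_reads
  state$manifest$count <- list(n_barcodes = nrow(cm$counts),
                               n_antibodies = ncol(cm$counts),
                               total_umis = sum(cm$counts))
  state
}

stage_cellcall <- function(state) {
  p <- state$params
  if (is.null(state$counts)) stop("missing artifact: count matrix")
  if (is.null(state$dna)) stop("missing artifact: interval depths")
  reads <- state$dna$amplicon_reads
  # align antibody matrix universe with DNA barcode universe
  missing_bc <- setdiff(names(reads), rownames(state$counts))
  if (length(missing_bc) > 0) {
    pad <- matrix(0L, length(missing_bc), ncol(state$counts),
                  dimnames = list(missing_bc, colnames(state$counts)))
    state$counts <- rbind(state$counts, pad)
    state$raw_reads <- c(state$raw_reads,
                         stats::setNames(rep(0L, length(missing_bc)),
                                         missing_bc))
  }
  qc <- call_cells(reads, state$dna$interval_depths, state$counts,
                   state$panel, min_fraction = p$min_fraction,
                   min_reads = p$min_reads, min_umis = p$min_umis,
                   isotype_factor = p$isotype_factor)
  state$qc <- qc
  state$cells <- qc$cell_barcode[qc$is_cell]
  out_tsv(state, "cell_qc.tsv", qc)
  writeLines(state$cells, file.path(state$cfg$outdir, "cells.txt"))
  state$manifest$cellcall <- list(n_barcodes = nrow(qc),
                                  n_cells = length(state$cells))
  state
}

stage_genotype <- function(state) {
  p <- state$params
  gm <- read_genotype_vcf(state$dna$vcf, min_gq = p$min_gq,
                          min_dp = p$min_dp)
  gm <- gm[intersect(state$cells, rownames(gm)), , drop = FALSE]
  state$genotypes <- gm
  loci <- p$loci
  if (is.null(loci)) loci <- colnames(gm)
  state$loci <- vapply(loci, function(l)
    grep(l, colnames(gm), value = TRUE, fixed = TRUE)[1], character(1))
  if (any(is.na(state$loci))) stop("relevant loci not found in VCF")
  state$clone_labels <- genotype_cluster_labels(
    gm, state$loci, merge_alternates = p$merge_alternates,
    drop_no_call = p$drop_no_call)
  write_genotype_matrix(gm, file.path(state$cfg$outdir, "genotypes.tsv"))
  state$manifest$genotype <- list(
    n_cells = nrow(gm), n_variants = ncol(gm),
    n_no_call = sum(gm == 3L), n_clones =
      length(unique(stats::na.omit(state$clone_labels))))
  state
}

stage_correct <- function(state) {
  p <- state$params
  cells <- state$cells
  counts <- state$counts[cells, , drop = FALSE]
  q <- build_quality_matrix(counts, state$raw_reads[cells],
                            state$dna$amplicon_reads[cells], state$panel)
  design <- build_design(q, n_vectors = p$n_vectors)
  u <- correct_counts(transform_counts(counts), design)
  state$quality <- q
  state$design <- design
  state$corrected <- u
  out_tsv(state, "corrected.tsv",
          data.frame(cell_barcode = rownames(u), u, check.names = FALSE))
  state$manifest$correct <- list(
    n_cells = nrow(u), n_vectors = p$n_vectors,
    variance_explained = round(attr(design, "variance_explained"), 4))
  state
}

stage_cluster <- function(state) {
  p <- state$params
  u <- state$corrected
  state$clusters <- cluster_cells(u, resolution = p$resolution,
                                  n_neighbors = p$n_neighbors,
                                  n_pcs = p$n_pcs, seed = state$cfg$seed)
  emb <- embed_cells(u, n_neighbors = p$n_neighbors, n_pcs = p$n_pcs,
                     min_dist = p$min_dist, seed = state$cfg$seed)
  state$embedding <- emb
  means <- cluster_means(u, state$clusters)
  state$cluster_names <- annotate_clusters(means, p$annotation_rules)
  out_tsv(state, "clusters.tsv", data.frame(
    cell_barcode = rownames(u), cluster = as.integer(state$clusters),
    name = state$cluster_names[state$clusters + 1L],
    umap1 = emb$coords[, 1], umap2 = emb$coords[, 2]))
  out_tsv(state, "cluster_means.tsv", data.frame(
    cluster = rownames(means), name = state$cluster_names, means,
    check.names = FALSE))
  state$manifest$cluster <- list(
    n_clusters = length(unique(state$clusters)),
    resolution = p$resolution, min_dist = p$min_dist)
  state
}

stage_concord <- function(state) {
  rep_ <- concordance_report(state$clone_labels[rownames(state$corrected)],
                             as.integer(state$clusters))
  state$concordance <- rep_
  out_tsv(state, "concordance.tsv", rep_)
  state$manifest$concord <- as.list(rep_)
  state
}

stage_gradient <- function(state) {
  p <- state$params
  blast_ids <- which(startsWith(state$cluster_names, p$blast_name)) - 1L
  if (length(blast_ids) == 0) {
    state$manifest$gradient <- list(skipped = "no blast clusters")
    return(state)
  }
  u <- state$corrected
  keep <- as.integer(state$clusters) %in% blast_ids
  ub <- blast_subset(u, as.integer(state$clusters), blast_ids)
  ord <- order_by_gradient(ub)
  # with fewer blast cells than the configured window, fall back to half
  # the subset so the profile retains resolution
  w <- min(p$gradient_window, nrow(ub))
  if (w >= nrow(ub)) w <- max(2L, nrow(ub) %/% 2L)
  prof <- moving_profiles(ord, ub,
                          clone_labels =
                            state$clone_labels[rownames(ub)],
                          embedding = state$embedding$coords[keep, ,
                                                            drop = FALSE],
                          window = w)
  cors <- gradient_correlations(prof)
  state$gradient <- list(ordering = ord, profiles = prof,
                         correlations = cors)
  out_tsv(state, "gradient_antibody.tsv",
          data.frame(position = prof$positions, prof$antibody,
                     check.names = FALSE))
  if (!is.null(prof$clones))
    out_tsv(state, "gradient_clones.tsv",
            data.frame(position = prof$positions, prof$clones,
                       check.names = FALSE))
  out_tsv(state, "gradient_correlations.tsv", cors$antibody)
  if (!is.null(cors$clones))
    out_tsv(state, "gradient_clone_correlations.tsv", cors$clones)
  if (!is.null(prof$coords) && nrow(prof$coords) >= 4) {
    sp <- fit_spline(prof$coords)
    tt <- seq(0, 1, length.out = 200)
    out_tsv(state, "gradient_spline.tsv",
            data.frame(t = tt, sp(tt)))
  }
  state$manifest$gradient <- list(n_blast = nrow(ub), window = w)
  state
}

write_manifest <- function(state) {
  m <- list(package = "genotag",
            version = as.character(utils::packageVersion("genotag")),
            seed = state$cfg$seed,
            params = state$params,
            input = state$cfg$input[c("mode", "read_level")],
            stages = state$manifest)
  jsonlite::write_json(m, file.path(state$cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
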