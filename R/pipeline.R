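#' Pipeline configuration
#'
#' Collects per-stage parameters for the end-to-end synthetic run. All
#' randomness derives from the single `seed` carried by the synthetic
#' config, so reruns are bit-identical.
#'
#' @param synthetic a [synthetic_config()] (its `seed` is the root seed).
#' @param outdir output directory.
#' @param peaks named list of overrides for [call_peaks()] parameters.
#' @param differential named list: `padj_max`, `min_fold`,
#'   `min_mean_reads`.
#' @param blocks named list: `k`, `linkage`, `candidate_min_rpm`.
#' @param orthology named list: `max_orthologs` plus the
#'   [simulate_ortholog_map()] probabilities.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            outdir = tempfile("fbfsubnet_run_"),
                            peaks = list(), differential = list(),
                            blocks = list(), orthology = list()) {
  cfg <- list(
    synthetic = synthetic, outdir = outdir,
    peaks = utils::modifyList(
      list(min_height_raw = 5, fdr = 0.01, rpm_ratio_min = 2,
           raw_ratio_min = 10, window_size = 500L, bin_width = 50L), peaks),
    differential = utils::modifyList(
      list(padj_max = 0.01, min_fold = 2, min_mean_reads = 20), differential),
    blocks = utils::modifyList(
      list(k = 5, linkage = "average", candidate_min_rpm = 25), blocks),
    orthology = utils::modifyList(
      list(max_orthologs = 10, frac_with_ortholog = 0.6,
           p_target_enriched = 0.7, p_target_background = 0.15), orthology))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  required <- c("synthetic", "outdir", "peaks", "differential", "blocks",
                "orthology")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stopf("pipeline config is missing field(s): %s",
          paste(missing, collapse = ", "))
  validate_synthetic_config(cfg$synthetic)
  known <- c(required)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stopf("unknown pipeline config field(s): %s",
          paste(unknown, collapse = ", "))
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose top-level keys mirror the
#'   [pipeline_config()] arguments (`synthetic:` holds
#'   [synthetic_config()] fields).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, y$synthetic %||% list())
  pipeline_config(synthetic = syn,
                  outdir = y$outdir %||% tempfile("fbfsubnet_run_"),
                  peaks = y$peaks %||% list(),
                  differential = y$differential %||% list(),
                  blocks = y$blocks %||% list(),
                  orthology = y$orthology %||% list())
}

#' Run the full synthetic iCLIP analysis pipeline
#'
#' Executes simulate, dedup, count, correlate, callpeaks, scanfbe, diff,
#' blocks and ortho-overlap on a seeded synthetic experiment, writing
#' every stage output under `config$outdir` and returning a manifest
#' (stage table, parameter echo, package version, output checksums)
#' sufficient to verify bit-identical reruns.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_result`: `manifest` plus the in-memory
#'   stage outputs (`truth`, `counts`, `correlation`, `peaks`,
#'   `differential`, `blocks`, `overlap`, ...).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  validate_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- character(0)
  files <- character(0)
  emit <- function(stage, fn) {
    stages <<- c(stages, stage)
    files <<- c(files, fn)
  }
  out <- function(fn) file.path(config$outdir, fn)
  scfg <- config$synthetic

  ## 1. simulate ------------------------------------------------------------
  say("stage simulate")
  exp <- simulate_experiment(scfg)
  write_genome_fasta(exp$genome, out("genome.fa"))
  write_tsv(exp$truth, out("truth.tsv"))
  if (requireNamespace("rtracklayer", quietly = TRUE))
    write_annotation_gff3(exp$annotation, out("annotation.gff3"))
  for (s in names(exp$reads))
    write_sam(exp$reads[[s]], attr(exp$annotation, "seqlengths"),
              out(paste0(s, ".sam")))
  emit("simulate", "truth.tsv")

  ## 2. dedup ---------------------------------------------------------------
  say("stage dedup")
  dedup <- lapply(exp$reads, collapse_duplicates)
  emit("dedup", NA)

  ## 3. count ---------------------------------------------------------------
  say("stage count")
  counts <- build_counts_matrix(dedup, exp$annotation)
  write_counts_tsv(counts, out("counts.tsv"))
  emit("count", "counts.tsv")

  ## 4. correlate -----------------------------------------------------------
  say("stage correlate")
  fbf_cols <- grep("^FBF_", colnames(counts$counts), value = TRUE)
  fbf_counts <- as_counts_matrix(counts$counts[, fbf_cols, drop = FALSE],
                                 counts$library_size[fbf_cols])
  gender <- ifelse(grepl("sperm", fbf_cols), "sperm", "oocyte")
  correlation <- correlation_report(fbf_counts, gender)
  write_tsv(data.frame(sample = rownames(correlation$rho), correlation$rho,
                       check.names = FALSE), out("correlation.tsv"))
  emit("correlate", "correlation.tsv")

  ## 5. callpeaks (per gender, FBF replicates pooled vs pooled controls) ----
  say("stage callpeaks")
  pk <- config$peaks
  peaks_by_gender <- lapply(c(sperm = "sperm", oocyte = "oocyte"), function(g) {
    fbf <- dedup[grep(paste0("^FBF_", g), names(dedup))]
    ctl <- dedup[grep(paste0("^control_", g), names(dedup))]
    call_peaks(fbf, ctl, exp$annotation, exp$genome,
               min_height_raw = pk$min_height_raw, fdr = pk$fdr,
               rpm_ratio_min = pk$rpm_ratio_min,
               raw_ratio_min = pk$raw_ratio_min,
               window_size = pk$window_size, bin_width = pk$bin_width)
  })
  for (g in names(peaks_by_gender))
    write_peaks_bed(peaks_by_gender[[g]], out(paste0("peaks_", g, ".bed")))
  emit("callpeaks", "peaks_sperm.bed")

  ## 6. scanfbe -------------------------------------------------------------
  say("stage scanfbe")
  fbe <- data.frame(
    gender = names(peaks_by_gender),
    n_peaks = vapply(peaks_by_gender, nrow, integer(1)),
    fbe_fraction_all = vapply(peaks_by_gender, peak_fbe_fraction, numeric(1)),
    fbe_fraction_top500 = vapply(peaks_by_gender, function(p)
      suppressMessages(peak_fbe_fraction(p, top_n = 500)), numeric(1)),
    stringsAsFactors = FALSE)
  write_tsv(fbe, out("fbe_fractions.tsv"))
  emit("scanfbe", "fbe_fractions.tsv")

  ## 7. diff ----------------------------------------------------------------
  say("stage diff")
  dcfg <- config$differential
  programs <- setNames(exp$truth$program, exp$truth$gene_id)
  testable <- filter_testable_genes(fbf_counts, programs,
                                    min_mean_reads = dcfg$min_mean_reads)
  diff_res <- NULL
  if (length(testable) >= 2) {
    sub <- as_counts_matrix(fbf_counts$counts[testable, , drop = FALSE],
                            fbf_counts$library_size)
    sf <- estimate_size_factors(fbf_counts)
    diff_res <- test_differential_binding(sub, sf, gender)
    diff_res <- call_gender_enriched(diff_res, padj_max = dcfg$padj_max,
                                     min_fold = dcfg$min_fold)
    write_tsv(diff_res, out("differential.tsv"))
  }
  emit("diff", "differential.tsv")

  ## 8. blocks --------------------------------------------------------------
  say("stage blocks")
  bcfg <- config$blocks
  targets <- sort(unique(unlist(lapply(peaks_by_gender, function(p)
    setdiff(p$gene_id, c("ambiguous", "unassigned"))))))
  rpm <- normalize_rpm(fbf_counts)
  ctl_cols <- grep("^control_", colnames(counts$counts), value = TRUE)
  ctl_rpm <- normalize_rpm(as_counts_matrix(
    counts$counts[, ctl_cols, drop = FALSE], counts$library_size[ctl_cols]))
  bm <- build_binding_matrix(rpm, rowMeans(ctl_rpm), targets)
  blocks_res <- NULL
  if (nrow(bm) >= bcfg$k) {
    assignment <- cluster_rnas(bm, k = bcfg$k,
                               sperm_cols = grep("sperm", colnames(bm)),
                               oocyte_cols = grep("oocyte", colnames(bm)),
                               linkage = bcfg$linkage)
    pca <- pca_projection(bm)
    block1 <- names(assignment$blocks)[assignment$blocks == "I"]
    candidates <- filter_block_candidates(
      block1, do.call(rbind, peaks_by_gender),
      min_rpm = bcfg$candidate_min_rpm)
    blocks_res <- list(matrix = bm, assignment = assignment, pca = pca,
                       block1_candidates = candidates)
    write_tsv(data.frame(gene_id = names(assignment$blocks),
                         block = assignment$blocks,
                         provenance = assignment$provenance),
              out("blocks.tsv"))
    write_tsv(data.frame(gene_id = rownames(pca$scores), pca$scores),
              out("pca_scores.tsv"))
    write_dendrogram_newick(assignment$dendrogram, out("dendrogram.nwk"))
  }
  emit("blocks", "blocks.tsv")

  ## 9. ortho-overlap -------------------------------------------------------
  say("stage ortho-overlap")
  ocfg <- config$orthology
  neutral <- exp$truth$gene_id[exp$truth$block %in% c("II", "III")]
  ortho <- simulate_ortholog_map(
    exp$truth$gene_id, enriched_worm = neutral,
    frac_with_ortholog = ocfg$frac_with_ortholog,
    p_target_enriched = ocfg$p_target_enriched,
    p_target_background = ocfg$p_target_background,
    seed = stage_seed(scfg$seed, "orthology"))
  fmap <- filter_degree(ortho$map, max_orthologs = ocfg$max_orthologs)
  groups <- build_groups(fmap)
  overlap <- compute_overlap(groups, targets, ortho$mammal_targets)
  write_tsv(overlap$table, out("ortholog_overlap.tsv"))
  emit("ortho-overlap", "ortholog_overlap.tsv")

  ## manifest ---------------------------------------------------------------
  outputs <- list.files(config$outdir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% "manifest.json"]
  checksums <- tools::md5sum(sort(outputs))
  names(checksums) <- basename(names(checksums))
  manifest <- list(
    stages = data.frame(stage = stages, key_output = files,
                        succeeded = TRUE, stringsAsFactors = FALSE),
    parameters = c(list(synthetic = unclass(config$synthetic)),
                   config[c("peaks", "differential", "blocks", "orthology")]),
    seed = scfg$seed,
    version = as.character(utils::packageVersion("fbfsubnet")),
    checksums = as.list(checksums))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(manifest = manifest, annotation = exp$annotation,
                 truth = exp$truth, counts = counts,
                 correlation = correlation, peaks = peaks_by_gender,
                 fbe = fbe, differential = diff_res, blocks = blocks_res,
                 orthology = list(map = fmap, groups = groups,
                                  overlap = overlap,
                                  mammal_targets = ortho$mammal_targets),
                 outdir = config$outdir),
            class = "pipeline_result")
}
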