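#' Default pipeline configuration
#'
#' All stage parameters with their defaults. A configuration is a plain named
#' list; [run_pipeline()] merges a user list (or YAML file) over these
#' defaults, validates it with [validate_config()], and writes the resolved
#' copy alongside the outputs.
#'
#' @return named list of parameters:
#' \describe{
#'   \item{seed}{master seed; per-stage seeds are derived from it.}
#'   \item{reference, condition, secondary}{condition labels: reference
#'     genotype, primary comparison, and the rescue (double-mutant)
#'     comparison.}
#'   \item{glog_c, fold_threshold, min_corr}{expression stage.}
#'   \item{metric, B, tail_level}{subtype stage.}
#'   \item{window_bp, alpha, n_perm, min_markers, undo_sd, state_thresholds,
#'     min_length_bp}{copy-number stage.}
#'   \item{exact_cutoff}{cohort stage.}
#'   \item{sim_*}{synthetic-data stage sizes and noise levels.}
#'   \item{expression, annotation, centroids, gene_map, markers, cohort}{input
#'     file paths (filled automatically after `simulate`).}
#' }
#' @export
default_config <- function() {
  list(
    seed = 1L,
    reference = "wt", condition = "p53null", secondary = "dblnull",
    glog_c = 0, fold_threshold = 1.5, min_corr = 0.996,
    metric = "spearman", B = 1000L, tail_level = 0.05,
    window_bp = 1e6, alpha = 0.01, n_perm = 100L, min_markers = 5L,
    undo_sd = 3, state_thresholds = c(-1.0, -0.3, 0.3, 0.9),
    min_length_bp = 1e6,
    exact_cutoff = 12L,
    sim_n_genes = 2000L, sim_noise_sd = 0.1, sim_n_tech_dups = 2L,
    sim_n_down = 60L, sim_n_up = 30L, sim_logfc = 1.2, sim_n_rescued = 30L,
    sim_signature_size = 100L, sim_signature_subtype = "Proneural",
    sim_map_fraction = 0.8,
    sim_chrom_lengths = c(chr1 = 100e6, chr2 = 80e6),
    sim_marker_spacing = 50000, sim_lrr_noise_sd = 0.15,
    sim_wave_coefficient = 0.3,
    sim_cohort_n = 200L, sim_cohort_effect = 1, sim_mutant_fraction = 0.3,
    expression = NULL, annotation = NULL, centroids = NULL,
    gene_map = NULL, markers = NULL, cohort = NULL, fold_changes = NULL)
}

#' Validate a pipeline configuration
#'
#' Checks every parameter against its documented range without touching any
#' data. Referenced input files that do not exist or cannot be read are
#' reported as violations, not exceptions.
#'
#' @param config named list (merged over [default_config()] first).
#' @return character vector of violations; empty means valid.
#' @export
validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  v <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L && !is.na(cfg$seed),
      "seed: must be a single integer")
  chk(is.numeric(cfg$fold_threshold) && cfg$fold_threshold > 1,
      "fold_threshold: must be > 1")
  chk(is.numeric(cfg$glog_c) && cfg$glog_c >= 0, "glog_c: must be >= 0")
  chk(is.numeric(cfg$min_corr) && cfg$min_corr >= -1 && cfg$min_corr <= 1,
      "min_corr: must be in [-1, 1]")
  chk(cfg$metric %in% c("spearman", "pearson", "euclidean"),
      "metric: must be one of spearman, pearson, euclidean")
  chk(is.numeric(cfg$B) && cfg$B >= 1, "B: must be >= 1")
  chk(is.numeric(cfg$tail_level) && cfg$tail_level > 0 && cfg$tail_level < 1,
      "tail_level: must be in (0, 1)")
  chk(is.numeric(cfg$window_bp) && cfg$window_bp > 0,
      "window_bp: must be > 0")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha: must be in (0, 1)")
  chk(is.numeric(cfg$n_perm) && cfg$n_perm >= 1, "n_perm: must be >= 1")
  chk(is.numeric(cfg$min_markers) && cfg$min_markers >= 2,
      "min_markers: must be >= 2")
  chk(is.numeric(cfg$undo_sd) && cfg$undo_sd >= 0, "undo_sd: must be >= 0")
  chk(length(cfg$state_thresholds) == 4L &&
        all(diff(cfg$state_thresholds) > 0),
      "state_thresholds: must be 4 strictly increasing cut points")
  chk(is.numeric(cfg$min_length_bp) && cfg$min_length_bp >= 0,
      "min_length_bp: must be >= 0")
  chk(is.numeric(cfg$exact_cutoff) && cfg$exact_cutoff >= 2,
      "exact_cutoff: must be >= 2")
  chk(is.numeric(cfg$sim_mutant_fraction) && cfg$sim_mutant_fraction > 0 &&
        cfg$sim_mutant_fraction < 1,
      "sim_mutant_fraction: must be in (0, 1)")
  for (p in c("expression", "annotation", "centroids", "gene_map",
              "markers", "cohort", "fold_changes")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      v <- c(v, sprintf("%s: file not readable: %s", p, cfg[[p]]))
  }
  v
}

#' Run pipeline stages
#'
#' Executes the selected stage (or the whole chain) with deterministic
#' per-stage seeds derived from the master seed, never mutating inputs:
#' all outputs, the resolved configuration, and a run manifest (parameters,
#' seeds, input/output checksums, package version) go to `out_dir`.
#' Identical configuration and seed give identical outputs.
#'
#' @param subcommand one of `"simulate"`, `"normalize"`, `"subtype"`,
#'   `"cnv"`, `"cohort"`, `"all"`.
#' @param config named list of overrides merged over [default_config()], or a
#'   YAML file path.
#' @param out_dir output directory (created; default a fresh directory under
#'   `tempdir()`).
#' @param quiet suppress log messages (default `FALSE`).
#' @return invisible named list of output file paths.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "normalize",
                                        "subtype", "cnv", "cohort"),
                         config = list(),
                         out_dir = tempfile("gliopipe_run_"),
                         quiet = FALSE) {
  subcommand <- match.arg(subcommand)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("missing config file: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  viol <- validate_config(cfg)
  if (length(viol))
    stop("invalid configuration: ", paste(viol, collapse = "; "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
  log_line <- function(stage, msg) {
    if (!quiet)
      message(sprintf("[%s] %s (params %s): %s",
                      format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                      stage, config_hash(cfg), msg))
  }
  stages <- if (subcommand == "all")
    c("simulate", "normalize", "subtype", "cnv", "cohort") else subcommand
  outputs <- character(0)
  for (st in stages) {
    sd <- stage_seed(cfg$seed, st)
    log_line(st, sprintf("start, stage seed %d", sd))
    out <- switch(st,
      simulate = stage_simulate(cfg, out_dir, sd),
      normalize = stage_normalize(cfg, out_dir),
      subtype = stage_subtype(cfg, out_dir, sd),
      cnv = stage_cnv(cfg, out_dir, sd),
      cohort = stage_cohort(cfg, out_dir))
    outputs <- c(outputs, out$files)
    # earlier stages feed their outputs to later stages of an `all` run
    if (!is.null(out$paths)) cfg <- utils::modifyList(cfg, out$paths)
    log_line(st, "done")
  }
  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("gliopipe")),
    seed = cfg$seed,
    stage_seeds = setNames(lapply(stages, function(s) stage_seed(cfg$seed, s)),
                           stages),
    files = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(as.list(setNames(outputs, basename(outputs))),
              manifest = file.path(out_dir, "manifest.json")))
}

# ---- internal stage implementations ----------------------------------------

# deterministic per-stage seed below 2^31
stage_seed <- function(master, stage) {
  off <- match(stage, c("simulate", "normalize", "subtype", "cnv", "cohort"))
  as.integer((abs(as.numeric(master)) %% 2000000) * 1000 + off)
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  codes <- utf8ToInt(s)
  h <- sum(codes * (seq_along(codes) %% 997)) %% (2^28)
  sprintf("%07x", as.integer(h))
}

need_input <- function(cfg, field) {
  p <- cfg[[field]]
  if (is.null(p) || !file.exists(p))
    stop(sprintf("missing input file for '%s': %s", field,
                 if (is.null(p)) "<unset>" else p))
  p
}

stage_simulate <- function(cfg, out_dir, seed) {
  centroids <- simulate_centroids(cfg$sim_signature_size, seed = seed)
  gene_map <- simulate_gene_map(rownames(centroids),
                                frac_mapped = cfg$sim_map_fraction,
                                seed = seed + 1L)
  n_sig <- nrow(gene_map)
  n_other <- cfg$sim_n_genes - n_sig
  gene_ids <- c(gene_map$source, sprintf("gene%04d", seq_len(n_other)))
  # deregulated genes live outside the signature so recovery is scorable
  set.seed(seed + 2L)
  dereg <- sample(sprintf("gene%04d", seq_len(n_other)),
                  cfg$sim_n_down + cfg$sim_n_up)
  down <- dereg[seq_len(cfg$sim_n_down)]
  up <- dereg[cfg$sim_n_down + seq_len(cfg$sim_n_up)]
  primary <- c(setNames(rep(-cfg$sim_logfc, length(down)), down),
               setNames(rep(cfg$sim_logfc, length(up)), up))
  # subtype signal: the planted centroid pattern, on signature source genes
  primary <- c(primary,
               setNames(centroids[gene_map$target, cfg$sim_signature_subtype],
                        gene_map$source))
  rescued <- sample(names(primary)[seq_len(cfg$sim_n_down + cfg$sim_n_up)],
                    cfg$sim_n_rescued)
  secondary <- primary
  secondary[rescued] <- 0
  sim <- simulate_expression(
    n_genes = cfg$sim_n_genes,
    conditions = setNames(c(1L, 1L, 1L),
                          c(cfg$reference, cfg$condition, cfg$secondary)),
    n_tech_dups = cfg$sim_n_tech_dups,
    planted_logfc = setNames(list(primary, secondary),
                             c(cfg$condition, cfg$secondary)),
    noise_sd = cfg$sim_noise_sd, gene_ids = gene_ids, seed = seed + 3L)
  # injected CNVs at fixed fractions of each chromosome: a hemizygous loss
  # and a gain on the first, a homozygous loss on the second (if present)
  cl <- cfg$sim_chrom_lengths
  cnv_truth <- data.frame(
    chrom = names(cl)[1L],
    start = floor(c(0.20, 0.60) * cl[[1L]]) + 1,
    end = floor(c(0.25, 0.64) * cl[[1L]]),
    state = c(1L, 3L), shift = c(-0.5, 0.6), stringsAsFactors = FALSE)
  if (length(cl) >= 2L)
    cnv_truth <- rbind(cnv_truth, data.frame(
      chrom = names(cl)[2L],
      start = floor(0.30 * cl[[2L]]) + 1, end = floor(0.36 * cl[[2L]]),
      state = 0L, shift = -1.2, stringsAsFactors = FALSE))
  trk <- simulate_marker_track(
    chrom_lengths = cfg$sim_chrom_lengths,
    marker_spacing = cfg$sim_marker_spacing,
    segments = cnv_truth,
    wave_coefficient = cfg$sim_wave_coefficient,
    noise_sd = cfg$sim_lrr_noise_sd, seed = seed + 4L)
  cohort <- simulate_cohort(cfg$sim_cohort_n, effect = cfg$sim_cohort_effect,
                            mutant_fraction = cfg$sim_mutant_fraction,
                            seed = seed + 5L)
  paths <- list(
    expression = file.path(out_dir, "expression.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    centroids = file.path(out_dir, "centroids.tsv"),
    gene_map = file.path(out_dir, "gene_map.tsv"),
    markers = file.path(out_dir, "markers.tsv"),
    cohort = file.path(out_dir, "cohort.tsv"))
  write_matrix_tsv(sim$values, paths$expression)
  write_tsv(sim$annotation, paths$annotation)
  write_matrix_tsv(centroids, paths$centroids)
  write_tsv(gene_map, paths$gene_map)
  write_tsv(trk$track, paths$markers)
  write_tsv(cohort, paths$cohort)
  truth_files <- c(file.path(out_dir, "truth_expression.tsv"),
                   file.path(out_dir, "truth_cnv.tsv"))
  write_tsv(data.frame(condition = rep(c(cfg$condition, cfg$secondary),
                                       c(length(primary), length(secondary))),
                       gene = c(names(primary), names(secondary)),
                       logfc = c(unname(primary), unname(secondary)),
                       stringsAsFactors = FALSE),
            truth_files[1L])
  write_tsv(cnv_truth, truth_files[2L])
  list(paths = paths, files = c(unlist(paths, use.names = FALSE), truth_files))
}

stage_normalize <- function(cfg, out_dir) {
  x <- read_expression_tsv(need_input(cfg, "expression"))
  ann <- read_annotation_tsv(need_input(cfg, "annotation"))
  norm <- quantile_normalize(glog_transform(x, cfg$glog_c))
  coll <- collapse_duplicates(norm, ann, min_corr = cfg$min_corr)
  fc1 <- fold_change_profile(coll$values, coll$annotation, cfg$condition,
                             cfg$reference)
  fc2 <- fold_change_profile(coll$values, coll$annotation, cfg$secondary,
                             cfg$reference)
  dereg <- select_deregulated(fc1, cfg$fold_threshold)
  resc <- classify_rescue(dereg, fc2, cfg$fold_threshold)
  fc_tab <- data.frame(gene = names(fc1), fc1 = unname(fc1),
                       fc2 = unname(fc2), stringsAsFactors = FALSE)
  names(fc_tab)[2:3] <- c(cfg$condition, cfg$secondary)
  files <- c(normalized = file.path(out_dir, "normalized.tsv"),
             fold_changes = file.path(out_dir, "fold_changes.tsv"),
             dereg = file.path(out_dir, "deregulated.tsv"),
             summary = file.path(out_dir, "rescue_summary.json"),
             correlations = file.path(out_dir, "duplicate_correlations.tsv"))
  write_matrix_tsv(coll$values, files["normalized"])
  write_tsv(fc_tab, files["fold_changes"])
  write_tsv(resc, files["dereg"])
  write_tsv(coll$correlations, files["correlations"])
  jsonlite::write_json(attr(resc, "summary"), files["summary"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = unname(files),
       paths = list(fold_changes = unname(files["fold_changes"])))
}

stage_subtype <- function(cfg, out_dir, seed) {
  fc_tab <- utils::read.delim(need_input(cfg, "fold_changes"),
                              check.names = FALSE, stringsAsFactors = FALSE)
  if (!cfg$condition %in% names(fc_tab))
    stop("fold-change table has no column for condition '", cfg$condition, "'")
  profile <- setNames(fc_tab[[cfg$condition]], fc_tab$gene)
  centroids <- read_centroids_tsv(need_input(cfg, "centroids"))
  gene_map <- read_gene_map_tsv(need_input(cfg, "gene_map"))
  res <- classify_subtype(profile, centroids, gene_map,
                          metric = cfg$metric, B = cfg$B, seed = seed,
                          tail_level = cfg$tail_level)
  files <- c(tsv = file.path(out_dir, "subtype_distances.tsv"),
             json = file.path(out_dir, "subtype_result.json"))
  write_tsv(res$table, files["tsv"])
  jsonlite::write_json(
    list(assigned = res$assigned, n_mapped = res$n_mapped, B = res$B,
         tail_level = res$tail_level, table = res$table),
    files["json"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = unname(files))
}

stage_cnv <- function(cfg, out_dir, seed) {
  trk <- read_marker_tsv(need_input(cfg, "markers"))
  fw <- fit_waviness(trk)
  segs <- segment_lrr(fw$track, alpha = cfg$alpha, n_perm = cfg$n_perm,
                      min_markers = cfg$min_markers, undo_sd = cfg$undo_sd,
                      seed = seed)
  segs <- call_states(segs, cfg$state_thresholds)
  report <- filter_cnvs(segs, cfg$min_length_bp)
  files <- c(corrected = file.path(out_dir, "corrected_track.tsv"),
             fit = file.path(out_dir, "waviness_fit.tsv"),
             segments = file.path(out_dir, "segments.tsv"),
             report = file.path(out_dir, "cnv_report.tsv"),
             bed = file.path(out_dir, "cnv_report.bed"))
  write_tsv(fw$track, files["corrected"])
  write_tsv(fw$fit, files["fit"])
  write_tsv(segs, files["segments"])
  write_tsv(report, files["report"])
  write_bed(report, files["bed"])
  list(files = unname(files))
}

stage_cohort <- function(cfg, out_dir) {
  tab <- read_cohort_tsv(need_input(cfg, "cohort"))
  res <- group_contrast(tab, "mutation_status",
                        exact_cutoff = cfg$exact_cutoff)
  out <- list(mutation_status = unclass(res))
  if ("subtype" %in% names(tab)) {
    part <- list(a = intersect(c("GCiMP", "Proneural"), unique(tab$subtype)),
                 b = intersect(c("Neural", "Classical", "Mesenchymal"),
                               unique(tab$subtype)))
    if (length(part$a) && length(part$b))
      out$subtype_partition <- unclass(
        group_contrast(tab, part, exact_cutoff = cfg$exact_cutoff))
  }
  f <- file.path(out_dir, "cohort_tests.json")
  jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = f)
}
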