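# End-to-end orchestration: simulate -> normalize -> call -> annotate ->
# compare, as one reproducible run with a resolved config, plain-file stage
# outputs and a hashed output manifest.

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults: per-probe
#' p cutoff 0.005, minimum 3 probes per region, 300 bp clustering gap,
#' smoothing window and CpG density half-window, signal-score threshold
#' 0.85, island O/E cut 0.6, QPCR fold threshold 2. Simulation defaults
#' describe the demo experiment: a 2 Mb CpG-heterogeneous genome, 50
#' planted DMRs, triplicate 250 ng high-input arrays per tissue and three
#' 1-vs-1 low-input runs at 10, 25 and 50 ng.
#'
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param outdir Output directory for [run_end_to_end()].
#' @param ... Overrides of any default field.
#' @return Named list of class `RunConfig`.
#' @export
default_run_config <- function(seed = 1L, outdir = "meklchip_run", ...) {
  cfg <- list(
    seed = as.integer(seed), outdir = outdir,
    genome_length = 2e6, island_fraction = 0.05, n_dmrs = 50L,
    spacing = 35L, probe_length = 50L,
    n_control = 500L, n_antigenomic = 500L,
    n_replicates_per_tissue = 3L, high_input_ng = 250,
    low_input_ng = c(10, 25, 50),
    tissues = c("tissueA", "tissueB"),
    dye_bias_strength = 0.3,
    span = 0.4, background_quantile = 0.9, signal_threshold = 0.85,
    intensity_floor = 1,
    max_gap = 300L, window = 300L,
    p_cutoff = 0.005, min_probes = 3L,
    half_window = 300L, island_oe = 0.6,
    n_perm = 1000L, qpcr_fold_threshold = 2)
  over <- list(...)
  assert_that(all(names(over) %in% names(cfg)),
              "unknown config fields: %s",
              paste(setdiff(names(over), names(cfg)), collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- c("RunConfig", "list")
  cfg
}

.stage_done <- function(paths) all(file.exists(paths))

.log_stage <- function(logfile, stage, t0) {
  line <- sprintf("%s\t%s\t%.2fs", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, as.numeric(Sys.time()) - t0)
  cat(line, "\n", file = logfile, append = TRUE, sep = "")
  message(line)
}

#' Run the full pipeline end to end
#'
#' Executes simulate, normalize, call, annotate and compare in order,
#' writing each stage's outputs as plain files under `config$outdir` so any
#' stage can be inspected or re-run. Completed stages (outputs already on
#' disk) are skipped when `resume = TRUE`. The fully resolved config is
#' written next to the outputs and a manifest lists every artifact with an
#' md5 hash; reruns from one config and seed are bit-identical.
#'
#' @param config A `RunConfig` from [default_run_config()].
#' @param resume Skip stages whose outputs already exist.
#' @return Invisibly, a list with the manifest data frame and key in-memory
#'   results (`regions`, `concordance`, `correlations`, `truth`).
#' @export
run_end_to_end <- function(config = default_run_config(), resume = TRUE) {
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "run.log")
  jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  simdir <- file.path(out, "sim")
  tissues <- config$tissues
  low_keys <- as.character(config$low_input_ng)

  # --- stage: simulate -----------------------------------------------------
  sim_files <- c(file.path(simdir, c("genome.fa", "probes.tsv", "truth.tsv",
                                     "manifest.tsv")),
                 file.path(simdir, paste0("manifest_low_", low_keys, ".tsv")))
  t0 <- as.numeric(Sys.time())
  if (!(resume && .stage_done(sim_files))) {
    genome <- generate_genome(config$genome_length, config$island_fraction,
                              seed = config$seed)
    probes <- tile_probes(genome, spacing = config$spacing,
                          probe_length = config$probe_length,
                          n_control = config$n_control,
                          n_antigenomic = config$n_antigenomic)
    truth <- simulate_truth(genome, n_dmrs = config$n_dmrs,
                            seed = config$seed + 1L, tissues = tissues)
    high <- simulate_experiment(genome, probes, truth,
                                n_replicates_per_tissue =
                                  config$n_replicates_per_tissue,
                                input_ng = config$high_input_ng,
                                seed = config$seed + 2L,
                                dye_bias_strength = config$dye_bias_strength)
    write_experiment(genome, probes, high, simdir, truth = truth)
    for (k in seq_along(config$low_input_ng)) {
      ng <- config$low_input_ng[k]
      lows <- simulate_experiment(genome, probes, truth,
                                  n_replicates_per_tissue = 1L,
                                  input_ng = ng,
                                  seed = config$seed + 10L + k,
                                  dye_bias_strength = config$dye_bias_strength)
      man <- do.call(rbind, lapply(lows, function(s) {
        p <- file.path("samples", paste0(s$sample_id, ".tsv"))
        write.table(
          data.frame(probe_id = s$probe_id,
                     input_intensity = s$input_intensity,
                     enriched_intensity = s$enriched_intensity),
          file.path(simdir, p), sep = "\t", quote = FALSE,
          row.names = FALSE)
        data.frame(sample_id = s$sample_id, tissue = s$tissue,
                   input_ng = s$input_ng, replicate = s$replicate, path = p)
      }))
      write.table(man, file.path(simdir,
                                 paste0("manifest_low_", ng, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .log_stage(logfile, "simulate", t0)
  } else message("stage simulate: outputs present, skipped")

  # --- stage: normalize ----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  m_path <- file.path(out, "m_matrix.tsv")
  qc_path <- file.path(out, "qc.tsv")
  bundle <- read_experiment(file.path(simdir, "probes.tsv"),
                            file.path(simdir, "manifest.tsv"),
                            genome_path = file.path(simdir, "genome.fa"),
                            intensity_floor = config$intensity_floor)
  mm <- relative_methylation(bundle, span = config$span,
                             background_quantile = config$background_quantile,
                             signal_threshold = config$signal_threshold,
                             intensity_floor = config$intensity_floor)
  if (!(resume && .stage_done(c(m_path, qc_path)))) {
    write.table(data.frame(probe_id = rownames(mm$m), mm$m,
                           check.names = FALSE),
                m_path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(mm$samples, qc_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    .log_stage(logfile, "normalize", t0)
  } else message("stage normalize: outputs present, skipped")

  # --- stage: call ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  groups <- split(mm$samples$sample_id, mm$samples$tissue)[tissues]
  clusters <- cluster_probes(mm$probes, max_gap = config$max_gap)
  smoothed <- smooth_m(mm, clusters, window = config$window)
  stats <- probe_ttest(smoothed, groups[[1]], groups[[2]],
                       clusters = clusters)
  regions <- call_regions(stats, smoothed, groups[[1]], groups[[2]],
                          p_cutoff = config$p_cutoff,
                          min_probes = config$min_probes)
  reg_path <- file.path(out, "regions.tsv")
  if (!(resume && .stage_done(reg_path))) {
    write_regions(regions, reg_path)
    .log_stage(logfile, "call", t0)
  } else message("stage call: outputs present, skipped")

  # --- stage: annotate -----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  ann_path <- file.path(out, "regions_annotated.tsv")
  land_path <- file.path(out, "landscape_summary.tsv")
  regions_ann <- annotate_regions(bundle$genome, regions,
                                  half_window = config$half_window)
  if (!(resume && .stage_done(c(ann_path, land_path)))) {
    write_regions(regions_ann, ann_path)
    land <- summarize_landscape(regions_ann)
    write.table(land$stats, land_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    .log_stage(logfile, "annotate", t0)
  } else message("stage annotate: outputs present, skipped")

  # --- stage: compare ------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  conc_path <- file.path(out, "concordance.tsv")
  corr_path <- file.path(out, "correlation_summary.tsv")
  ref_dm <- regions_delta_m(smoothed, regions_ann, groups[[1]], groups[[2]])
  low_dm <- matrix(NA_real_, nrow(regions_ann), length(low_keys),
                   dimnames = list(NULL, paste0("low", low_keys, "ng")))
  correlations <- list()
  for (k in seq_along(low_keys)) {
    lb <- read_experiment(file.path(simdir, "probes.tsv"),
                          file.path(simdir, paste0("manifest_low_",
                                                   low_keys[k], ".tsv")),
                          intensity_floor = config$intensity_floor)
    lmm <- relative_methylation(lb, span = config$span,
                                background_quantile =
                                  config$background_quantile,
                                signal_threshold = config$signal_threshold,
                                intensity_floor = config$intensity_floor)
    lsm <- smooth_m(lmm, clusters, window = config$window)
    lg <- split(lmm$samples$sample_id, lmm$samples$tissue)[tissues]
    low_dm[, k] <- regions_delta_m(lsm, regions_ann, lg[[1]], lg[[2]])
    correlations[[colnames(low_dm)[k]]] <-
      shuffled_null(ref_dm, low_dm[, k], n_perm = config$n_perm,
                    seed = config$seed + 100L + k)
  }
  conc <- classify_regions(regions_ann$region_id, ref_dm, low_dm)
  if (!(resume && .stage_done(c(conc_path, corr_path)))) {
    write.table(cbind(conc, low_dm), conc_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    corr_df <- do.call(rbind, lapply(names(correlations), function(nm) {
      x <- correlations[[nm]]
      data.frame(run = nm, observed_cc = x$observed,
                 null_mean = x$null_mean, null_sd = x$null_sd,
                 null_q025 = x$null_q025, null_q975 = x$null_q975,
                 p_empirical = x$p_empirical, n_regions = x$n_regions)
    }))
    write.table(corr_df, corr_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    .log_stage(logfile, "compare", t0)
  } else message("stage compare: outputs present, skipped")

  # --- manifest ------------------------------------------------------------
  arts <- setdiff(list.files(out, recursive = TRUE),
                  c("manifest_out.tsv", "run.log"))
  manifest <- data.frame(
    file = arts,
    md5 = unname(tools::md5sum(file.path(out, arts))))
  write.table(manifest, file.path(out, "manifest_out.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  truth_tab <- read.delim(file.path(simdir, "truth.tsv"),
                          stringsAsFactors = FALSE)
  invisible(list(manifest = manifest, regions = regions_ann,
                 concordance = conc, correlations = correlations,
                 truth = truth_tab, m_matrix = mm))
}
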