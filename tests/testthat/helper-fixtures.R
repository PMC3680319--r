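# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small simulated world shared by unit tests: 150 kb genome, 6 planted DMRs
small_world <- function() {
  memo("small_world", {
    genome <- generate_genome(150000, island_fraction = 0.08, seed = 11)
    probes <- tile_probes(genome)
    truth <- simulate_truth(genome, n_dmrs = 6, seed = 12)
    samples <- simulate_experiment(genome, probes, truth,
                                   n_replicates_per_tissue = 3,
                                   input_ng = 250, seed = 13)
    list(genome = genome, probes = probes, truth = truth,
         samples = samples)
  })
}

# the small world normalized into a smoothed matrix with groups
small_matrix <- function() {
  memo("small_matrix", {
    w <- small_world()
    dir <- tempfile("mekl_fix_")
    write_experiment(w$genome, w$probes, w$samples, dir, truth = w$truth)
    bundle <- read_experiment(file.path(dir, "probes.tsv"),
                              file.path(dir, "manifest.tsv"),
                              file.path(dir, "genome.fa"))
    mm <- relative_methylation(bundle)
    clusters <- cluster_probes(mm$probes)
    smoothed <- smooth_m(mm, clusters, window = 300)
    groups <- split(mm$samples$sample_id, mm$samples$tissue)
    list(bundle = bundle, mm = mm, clusters = clusters,
         smoothed = smoothed, groups = groups)
  })
}

# hand-built methylation matrix over one chromosome for calling tests
make_mm <- function(starts, m, tissues = rep(c("A", "B"), each = 3),
                    probe_length = 50L) {
  n <- length(starts)
  stopifnot(nrow(m) == n)
  ids <- sprintf("P%03d", seq_len(n))
  sample_ids <- sprintf("s%d_%s", seq_along(tissues), tissues)
  dimnames(m) <- list(ids, sample_ids)
  probes <- data.frame(probe_id = ids, chrom = "chr1", start = starts,
                       length = probe_length, is_control = FALSE,
                       is_antigenomic = FALSE, cpg_count = 1L)
  structure(list(m = m, probes = probes,
                 samples = data.frame(sample_id = sample_ids,
                                      tissue = tissues,
                                      input_ng = 250,
                                      replicate = seq_along(tissues),
                                      signal_score = 1, qc_flag = FALSE),
                 smoothed = TRUE),
            class = "MethylationMatrix")
}

# synthesized probe-stats table for region-calling selection tests
make_stats <- function(cluster_id, p_value, t_sign, spacing = 35L) {
  n <- length(p_value)
  data.frame(probe_id = sprintf("P%03d", seq_len(n)), chrom = "chr1",
             start = seq(0L, by = spacing, length.out = n),
             length = 50L, cluster_id = cluster_id,
             delta_m = t_sign * 0.5, t_stat = t_sign * 10,
             p_value = p_value, zero_var_flag = FALSE)
}

# full demo run (2 Mb, 50 planted DMRs, 3v3 at 250 ng + three 1v1 low-input
# runs), memoised: shared by the acceptance criteria that measure it
acceptance_demo <- function() {
  memo("acceptance_demo", {
    cfg <- default_run_config(seed = 1, outdir = tempfile("mekl_demo_"))
    suppressMessages(suppressWarnings(run_end_to_end(cfg)))
  })
}

interval_overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
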