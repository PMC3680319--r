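# helper: a bare sample + probes pair with chosen intensity vectors
bare_sample <- function(input, enriched, n_gen, n_ctl, n_ag) {
  probes <- data.frame(
    probe_id = sprintf("X%05d", seq_len(n_gen + n_ctl + n_ag)),
    chrom = c(rep("chr1", n_gen), rep(NA, n_ctl + n_ag)),
    start = c(seq_len(n_gen) * 40L, rep(NA, n_ctl + n_ag)),
    length = 50L,
    is_control = c(rep(FALSE, n_gen), rep(TRUE, n_ctl), rep(FALSE, n_ag)),
    is_antigenomic = c(rep(FALSE, n_gen + n_ctl), rep(TRUE, n_ag)),
    cpg_count = 1L)
  sample <- structure(list(sample_id = "s1", tissue = "A", input_ng = 250,
                           replicate = 1, probe_id = probes$probe_id,
                           input_intensity = input,
                           enriched_intensity = enriched),
                      class = "ArraySample")
  list(sample = sample, probes = probes)
}

test_that("signal score separates signal from background correctly", {
  # complete separation -> 1.0
  n <- 1000
  f <- bare_sample(c(rep(100, n), rep(100, 50), rep(1, 200)),
                   rep(1, n + 250), n, 50, 200)
  expect_equal(signal_score(f$sample, f$probes), 1.0)

  # identical distributions -> score approx 1 - background_quantile
  withr::with_seed(42, {
    vals <- rlnorm(10000 + 2000, meanlog = 5, sdlog = 1)
  })
  f2 <- bare_sample(vals, rep(1, 12000), 10000, 0, 2000)
  sc <- signal_score(f2$sample, f2$probes, background_quantile = 0.9)
  expect_lt(abs(sc - 0.10), 0.02)

  # adding a constant to genomic intensities never decreases the score
  for (shift in c(0.5, 2, 10, 100)) {
    f3 <- f2
    f3$sample$input_intensity[1:10000] <-
      f3$sample$input_intensity[1:10000] + shift
    expect_gte(signal_score(f3$sample, f3$probes), sc)
  }
  # no anti-genomic probes: undefined
  f4 <- bare_sample(rep(1, 100), rep(1, 100), 100, 0, 0)
  expect_error(signal_score(f4$sample, f4$probes), "anti-genomic")
})

test_that("samples below the signal threshold are flagged, not dropped", {
  w <- small_world()
  dir <- tempfile()
  write_experiment(w$genome, w$probes, w$samples, dir)
  b <- read_experiment(file.path(dir, "probes.tsv"),
                       file.path(dir, "manifest.tsv"))
  # cripple one sample's genomic input channel so its score drops
  gen <- !b$probes$is_control & !b$probes$is_antigenomic
  low_idx <- which(gen)[seq_len(round(0.4 * sum(gen)))]
  b$samples[[2]]$input_intensity[low_idx] <- 2
  mm <- suppressWarnings(relative_methylation(b))
  expect_true(mm$samples$qc_flag[2])
  expect_false(any(mm$samples$qc_flag[-2]))
  expect_identical(ncol(mm$m), length(b$samples))  # kept, not dropped
  expect_lt(mm$samples$signal_score[2], 0.85)
})

test_that("loess correction: exact identity, removes injected banana bias", {
  # enriched = input exactly -> M identically 0, correction changes nothing
  withr::with_seed(1, ints <- rlnorm(1200, 7, 1.2))
  f <- bare_sample(ints, ints, 1000, 150, 50)
  out <- loess_dye_correction(f$sample, f$probes, span = 0.4)
  expect_equal(log2(out$enriched_intensity / out$input_intensity),
               rep(0, 1200), tolerance = 1e-12)
  expect_error(loess_dye_correction(f$sample, f$probes, span = 0),
               "span")
  few <- bare_sample(ints[1:100], ints[1:100], 60, 20, 20)
  expect_error(loess_dye_correction(few$sample, few$probes), "50 control")

  # simulator banana bias at zero noise: corrected control M within +/- 0.05
  w <- small_world()
  s <- simulate_experiment(w$genome, w$probes, w$truth,
                           n_replicates_per_tissue = 1, input_ng = 250,
                           seed = 3, dye_bias_strength = 0.3,
                           noise_sd = 0)[[1]]
  ctl <- w$probes$is_control
  m_before <- log2(s$enriched_intensity / s$input_intensity)[ctl]
  expect_gt(max(abs(m_before)), 0.05)     # bias really was injected
  corr <- loess_dye_correction(s, w$probes, span = 0.4)
  m_after <- log2(corr$enriched_intensity / corr$input_intensity)[ctl]
  expect_lt(max(abs(m_after)), 0.05)
})

test_that("loess correction is idempotent once the trend is removed", {
  # linear dye bias lies in the span of a degree-1 loess: first pass removes
  # it exactly, second pass must change M by < 1e-6
  withr::with_seed(8, a <- runif(1500, 6, 14))
  input <- 2^(a - 0.5 * (0.2 * a - 2))
  enriched <- 2^(a + 0.5 * (0.2 * a - 2))   # M = 0.2*A - 2, A = a exactly
  f <- bare_sample(input, enriched, 1200, 200, 100)
  once <- loess_dye_correction(f$sample, f$probes)
  twice <- loess_dye_correction(once, f$probes)
  m1 <- log2(once$enriched_intensity / once$input_intensity)
  m2 <- log2(twice$enriched_intensity / twice$input_intensity)
  expect_lt(max(abs(m2 - m1)), 1e-6)
})

test_that("quantile normalization matches the hand example and conserves multisets", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(1.5, 3.0, 4.5))
  expect_equal(unname(out[, 2]), c(1.5, 3.0, 4.5))

  # fixed point: identical samples unchanged
  m2 <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(m2), m2)

  # property: sorted columns identical to machine precision, ranks kept
  for (seed in 1:5) {
    withr::with_seed(seed, x <- matrix(rnorm(400), 100, 4))
    q <- quantile_normalize(x)
    ref <- sort(q[, 1])
    for (j in 2:4) expect_equal(sort(q[, j]), ref, tolerance = 1e-12)
    for (j in 1:4) expect_identical(order(q[, j]), order(x[, j]))
  }
  expect_warning(quantile_normalize(matrix(1:5)), ">= 2 samples")
})

test_that("relative methylation equals the closed-form expectation at zero noise", {
  w <- small_world()
  samples <- simulate_experiment(w$genome, w$probes, w$truth,
                                 n_replicates_per_tissue = 2,
                                 input_ng = 250, seed = 17,
                                 dye_bias_strength = 0, noise_sd = 0)
  dir <- tempfile()
  write_experiment(w$genome, w$probes, samples, dir)
  b <- read_experiment(file.path(dir, "probes.tsv"),
                       file.path(dir, "manifest.tsv"))
  mm <- relative_methylation(b)

  # oracle: expected M per probe/tissue straight from the truth intervals
  # and the saturating capture formula
  gen <- !w$probes$is_control & !w$probes$is_antigenomic
  mid <- w$probes$start[gen] + w$probes$length[gen] %/% 2
  iv <- w$truth$dmr_intervals
  expected_m <- sapply(colnames(mm$m), function(sid) {
    tissue <- sub("_.*", "", sid)
    meth <- rep(w$truth$baseline_methylation, sum(gen))
    idx <- findInterval(mid, iv$start)
    hit <- idx > 0 & mid < iv$end[pmax(idx, 1)]
    meth[hit] <- iv[[paste0("meth_", tissue)]][idx[hit]]
    x <- meth * w$probes$cpg_count[gen]
    log2(0.2 + 4 * x / (x + 2))
  })
  # before quantile alignment, the bundle's raw M is the closed form exactly
  raw_m <- sapply(b$samples, function(s) {
    log2(s$enriched_intensity / s$input_intensity)[gen]
  })
  expect_equal(unname(raw_m), unname(expected_m), tolerance = 1e-9)
  # and the pipeline output is exactly that matrix after quantile alignment
  # (the closed form itself cannot be aligned independently: its exact ties
  # are averaged by the tie rule, while the 1e-15 disk round-trip jitter in
  # the pipeline's input breaks the same ties)
  expect_equal(unname(mm$m), unname(quantile_normalize(raw_m)),
               tolerance = 1e-12)

  # determinism: preprocessing has no randomness
  mm2 <- relative_methylation(b)
  expect_identical(mm$m, mm2$m)

  # control-probes-only bundle is degenerate
  ctl_only <- b
  ctl_only$probes <- b$probes[b$probes$is_control, ]
  expect_error(relative_methylation(ctl_only), "genomic")
})
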