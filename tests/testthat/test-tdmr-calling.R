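test_that("probe clustering follows the gap rule and chromosome bounds", {
  p <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr1"),
                  start = c(0L, 35L, 70L, 1000L))
  expect_identical(cluster_probes(p, max_gap = 300), c(1L, 1L, 1L, 2L))
  expect_identical(cluster_probes(p[1, , drop = FALSE]), 1L)
  p2 <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 10L))
  expect_identical(cluster_probes(p2, max_gap = 300), c(1L, 2L))
})

test_that("smoothing matches the kernel-sum oracle and respects clusters", {
  # hand case: 5 equally spaced probes, unit impulse at the center
  m <- matrix(rep(c(0, 0, 1, 0, 0), 6), ncol = 6)
  mm <- make_mm(seq(0, by = 35, length.out = 5), m)
  sm <- smooth_m(mm, rep(1L, 5), window = 300)
  expect_equal(unname(sm$m[, 1]),
               oracle_smooth(mm$probes$start, m[, 1], 300), tolerance = 1e-12)

  # constant M unchanged; singleton cluster unchanged
  mc <- make_mm(c(0, 40, 5000), matrix(c(2, 2, 9), 3, 6))
  smc <- smooth_m(mc, c(1L, 1L, 2L), window = 300)
  expect_equal(unname(smc$m[, 1]), c(2, 2, 9), tolerance = 1e-12)

  # random cases vs the exhaustive oracle, clusters never mix
  for (seed in 1:3) {
    withr::with_seed(seed, {
      pos <- sort(sample.int(3000, 40)); mr <- matrix(rnorm(40 * 6), 40, 6)
    })
    cl <- cluster_probes(data.frame(chrom = "chr1", start = pos), 300)
    mmr <- make_mm(pos, mr)
    smr <- smooth_m(mmr, cl, window = 300)
    for (k in unique(cl)) {
      idx <- which(cl == k)
      expect_equal(unname(smr$m[idx, 2]),
                   oracle_smooth(pos[idx], mr[idx, 2], 300),
                   tolerance = 1e-12)
    }
  }
})

test_that("smoothing reduces average per-probe sample variance", {
  fx <- small_matrix()
  v_raw <- mean(apply(fx$mm$m, 1, var))
  v_sm <- mean(apply(fx$smoothed$m, 1, var))
  expect_lt(v_sm, v_raw)
})

test_that("probe t statistics match the textbook pooled-variance oracle", {
  g1 <- c(1.0, 1.1, 0.9); g2 <- c(0.0, -0.1, 0.1)
  mm <- make_mm(c(0, 35), rbind(c(g1, g2), c(g1, g2)))
  st <- probe_ttest(mm, mm$samples$sample_id[1:3], mm$samples$sample_id[4:6])
  o <- oracle_pooled_t(g1, g2)
  expect_equal(st$t_stat[1], o$t, tolerance = 1e-10)
  expect_equal(st$p_value[1], o$p, tolerance = 1e-10)
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(st$p_value[1], tt$p.value, tolerance = 1e-10)

  # random probes: sign(t) == sign(delta_m); null probes give t=0, p=1
  withr::with_seed(5, mr <- matrix(rnorm(50 * 6), 50, 6))
  mr[1, ] <- 3                           # exactly equal groups
  mmr <- make_mm(seq(0, by = 400, length.out = 50), mr)
  str <- probe_ttest(mmr, mmr$samples$sample_id[1:3],
                     mmr$samples$sample_id[4:6])
  expect_identical(sign(str$t_stat[-1]), sign(str$delta_m[-1]))
  expect_identical(str$t_stat[1], 0)
  expect_identical(str$p_value[1], 1)
  # zero variance, nonzero difference: flagged, smallest positive p
  mz <- make_mm(c(0, 35), rbind(c(1, 1, 1, 0, 0, 0), rep(0, 6)))
  stz <- probe_ttest(mz, mz$samples$sample_id[1:3], mz$samples$sample_id[4:6])
  expect_true(stz$zero_var_flag[1])
  expect_identical(stz$p_value[1], .Machine$double.xmin)
  expect_error(probe_ttest(mm, mm$samples$sample_id[1],
                           mm$samples$sample_id[4:6]), ">= 2")
})

test_that("region calling: published cutoff rules on constructed patterns", {
  mat <- make_mm(seq(0, by = 35, length.out = 12),
                 matrix(rnorm(72), 12, 6))
  # 5 significant same-sign probes in one cluster -> one region of 5
  st <- make_stats(rep(1L, 5), rep(0.001, 5), rep(1, 5))
  reg <- call_regions(st, make_mm(st$start, matrix(rnorm(30), 5, 6)),
                      sprintf("s%d_A", 1:3), sprintf("s%d_B", 4:6))
  expect_identical(nrow(reg), 1L)
  expect_identical(reg$n_probes, 5L)
  expect_identical(reg$start, 0L)
  expect_identical(reg$end, 4L * 35L + 50L)

  # runs of fewer than three significant probes are excluded
  st2 <- make_stats(rep(1L, 5), c(0.001, 0.001, 0.5, 0.5, 0.5), rep(1, 5))
  reg2 <- call_regions(st2, make_mm(st2$start, matrix(rnorm(30), 5, 6)),
                       sprintf("s%d_A", 1:3), sprintf("s%d_B", 4:6))
  expect_identical(nrow(reg2), 0L)

  # a sign change splits a 6-probe significant run into two 3-probe regions
  st3 <- make_stats(rep(1L, 6), rep(0.001, 6), c(1, 1, 1, -1, -1, -1))
  reg3 <- call_regions(st3, make_mm(st3$start, matrix(rnorm(36), 6, 6)),
                       sprintf("s%d_A", 1:3), sprintf("s%d_B", 4:6))
  expect_identical(nrow(reg3), 2L)
  expect_identical(sort(reg3$n_probes), c(3L, 3L))
  expect_setequal(reg3$direction, c(1L, -1L))

  # min_probes = 1 admits short runs (default rule removed)
  reg4 <- call_regions(st2, make_mm(st2$start, matrix(rnorm(30), 5, 6)),
                       sprintf("s%d_A", 1:3), sprintf("s%d_B", 4:6),
                       min_probes = 1)
  expect_identical(nrow(reg4), 1L)
  expect_identical(reg4$n_probes, 2L)
})

test_that("region calling equals exhaustive run enumeration on random clusters", {
  withr::with_seed(99, {
    for (case in 1:60) {
      sizes <- sample(1:12, sample(1:3, 1), replace = TRUE)
      cl <- rep(seq_along(sizes), sizes)
      n <- length(cl)
      p <- ifelse(runif(n) < 0.5, runif(n, 0, 0.004), runif(n, 0.006, 1))
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      st <- make_stats(cl, p, sgn)
      mat <- make_mm(st$start, matrix(rnorm(n * 6), n, 6))
      reg <- call_regions(st, mat, sprintf("s%d_A", 1:3),
                          sprintf("s%d_B", 4:6),
                          p_cutoff = 0.005, min_probes = 3)
      # oracle: enumerate within each cluster independently
      expected <- list()
      for (k in unique(cl)) {
        idx <- which(cl == k)
        runs <- oracle_enumerate_runs(p[idx], sgn[idx], 0.005, 3)
        for (r in runs) expected[[length(expected) + 1L]] <-
            st$probe_id[idx[r]]
      }
      got <- lapply(reg$probe_ids, function(s)
        strsplit(s, ",", fixed = TRUE)[[1]])
      canon <- function(l) sort(vapply(l, paste, "", collapse = "+"))
      expect_identical(canon(got), canon(expected))
    }
  })
})

test_that("region ranking orders by p, then area, then coordinates", {
  base <- data.frame(chrom = "chr1", start = c(100L, 900L, 500L, 2000L),
                     end = c(400L, 1200L, 800L, 2300L), n_probes = 3L,
                     direction = 1L, delta_m = 1,
                     area = c(12, 40, 40, 50),
                     region_p = c(1e-5, 1e-20, 1e-20, 1e-5),
                     probe_ids = "x")
  r <- rank_regions(base)
  expect_identical(r$rank, 1:4)
  # p = 1e-20 pair first, equal areas broken by coordinates
  expect_identical(r$start[1:2], c(500L, 900L))
  # p = 1e-5 pair: larger area (50) outranks smaller (12)
  expect_identical(r$area[3:4], c(50, 12))
  expect_identical(rank_regions(base[0, ])$rank, integer(0))
})
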