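# Probe clustering, genome-weighted smoothing, per-probe t statistics and
# aggregation of significant probe runs into T-DMRs.

#' Cluster genomic probes by gap
#'
#' Consecutive probes on one chromosome whose start-to-start gap is at most
#' `max_gap` share a cluster; cluster ids are dense, 1-based and ordered by
#' genome position. Clusters never span chromosomes.
#'
#' @param probes A `ProbeSet` or any data frame with `chrom` and `start`
#'   (genomic probes only are clustered; non-genomic rows get `NA`).
#' @param max_gap Maximum start-to-start gap in bases (default 300,
#'   matching the experiment's average fragment size).
#' @return Integer vector of cluster ids aligned to `probes` rows.
#' @export
cluster_probes <- function(probes, max_gap = 300L) {
  assert_that(max_gap >= 1, "max_gap must be >= 1")
  gen <- if (all(c("is_control", "is_antigenomic") %in% names(probes))) {
    is_genomic_probe(probes)
  } else rep(TRUE, nrow(probes))
  ids <- rep(NA_integer_, nrow(probes))
  idx <- which(gen)
  if (length(idx) == 0) return(ids)
  ch <- probes$chrom[idx]
  st <- probes$start[idx]
  assert_that(!is.unsorted(order(ch, st)) ||
                all(order(ch, st) == seq_along(idx)),
              "genomic probes must be sorted by (chrom, start)")
  new_cluster <- c(TRUE, ch[-1] != ch[-length(ch)] |
                     diff(st) > max_gap)
  ids[idx] <- cumsum(new_cluster)
  ids
}

#' Genome-weighted smoothing of M values within clusters
#'
#' Replaces each probe's M value, per sample, by the triangular-kernel
#' weighted mean over probes of the same cluster within `window` bases
#' (weight 1 at the probe itself, decreasing linearly to 0 at a distance of
#' `window`). Smoothing never crosses cluster boundaries; singleton
#' clusters are unchanged. Implemented as one sparse row-stochastic
#' operator applied to the whole matrix.
#'
#' @param matrix A `MethylationMatrix`.
#' @param clusters Cluster ids aligned to `matrix$probes` rows (e.g. from
#'   [cluster_probes()] on the genomic probes).
#' @param window Kernel half-width in bases (default 300).
#' @return A `MethylationMatrix` with `smoothed = TRUE`.
#' @export
smooth_m <- function(matrix, clusters, window = 300L) {
  assert_that(window >= 1, "window must be >= 1")
  assert_that(length(clusters) == nrow(matrix$m),
              "clusters (%d) must align with matrix rows (%d)",
              length(clusters), nrow(matrix$m))
  pos <- matrix$probes$start
  n <- length(pos)
  ii <- vector("list", 0L); jj <- vector("list", 0L); ww <- vector("list", 0L)
  for (cl in split(seq_len(n), clusters)) {
    p <- pos[cl]
    lo <- findInterval(p - window - 0.5, p) + 1L
    hi <- findInterval(p + window + 0.5, p)
    cnt <- hi - lo + 1L
    i_rep <- rep.int(seq_along(cl), cnt)
    j_loc <- sequence(cnt, from = lo)
    w <- 1 - abs(p[j_loc] - p[i_rep]) / window
    keep <- w > 0
    ii[[length(ii) + 1L]] <- cl[i_rep[keep]]
    jj[[length(jj) + 1L]] <- cl[j_loc[keep]]
    ww[[length(ww) + 1L]] <- w[keep]
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(n, n))
  W <- W / Matrix::rowSums(W)
  out <- matrix
  sm <- as.matrix(W %*% matrix$m)
  dimnames(sm) <- dimnames(matrix$m)
  out$m <- sm
  out$smoothed <- TRUE
  out
}

#' Pooled-variance two-sample t statistic (vectorized over rows)
#' @noRd
.pooled_t <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / df
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  d <- m1 - m2
  t <- d / se
  p <- 2 * pt(-abs(t), df)
  zero_var <- s2 <= 0
  flag <- rep(FALSE, length(t))
  if (any(zero_var)) {
    exact0 <- zero_var & d == 0
    t[exact0] <- 0; p[exact0] <- 1
    inf <- zero_var & d != 0
    t[inf] <- sign(d[inf]) * Inf
    p[inf] <- .Machine$double.xmin
    flag[inf] <- TRUE
  }
  list(delta = d, t = t, p = p, df = df, zero_var_flag = flag)
}

#' Per-probe two-sample t statistics
#'
#' Pooled-variance two-sample t test per probe between two sample groups,
#' two-sided p from the t distribution with n1+n2-2 degrees of freedom.
#' Intended to run on smoothed M values. Zero pooled variance with zero
#' difference yields t = 0, p = 1; with a nonzero difference the p is set
#' to the smallest representable positive value and flagged.
#'
#' @param matrix A `MethylationMatrix` (typically smoothed).
#' @param group1,group2 Sample ids (columns of `matrix$m`), each of size
#'   >= 2. Reported `delta_m` is mean(group1) - mean(group2).
#' @param clusters Optional cluster ids to attach (else computed with the
#'   default gap).
#' @return `data.frame` of class `ProbeStats`: `probe_id`, `chrom`,
#'   `start`, `length`, `cluster_id`, `delta_m`, `t_stat`, `p_value`,
#'   `zero_var_flag`.
#' @export
probe_ttest <- function(matrix, group1, group2, clusters = NULL) {
  assert_that(length(group1) >= 2 && length(group2) >= 2,
              "each group needs >= 2 samples (got %d and %d)",
              length(group1), length(group2))
  assert_that(all(c(group1, group2) %in% colnames(matrix$m)),
              "unknown sample ids: %s",
              paste(setdiff(c(group1, group2), colnames(matrix$m)),
                    collapse = ", "))
  if (is.null(clusters)) clusters <- cluster_probes(matrix$probes)
  res <- .pooled_t(matrix$m[, group1, drop = FALSE],
                   matrix$m[, group2, drop = FALSE])
  out <- data.frame(probe_id = matrix$probes$probe_id,
                    chrom = matrix$probes$chrom,
                    start = matrix$probes$start,
                    length = matrix$probes$length,
                    cluster_id = clusters,
                    delta_m = res$delta,
                    t_stat = res$t,
                    p_value = res$p,
                    zero_var_flag = res$zero_var_flag)
  class(out) <- c("ProbeStats", "data.frame")
  out
}

#' Aggregate significant probe runs into T-DMRs
#'
#' Within each cluster, maximal runs of consecutive probes with p below
#' `p_cutoff` and a common t sign become candidate regions; candidates with
#' fewer than `min_probes` member probes are discarded. The region spans
#' the first member probe's start to the last member probe's end. The
#' region-level p is a pooled-variance t test on per-sample region means of
#' the smoothed M values; `area` is the sum of |t| over member probes.
#'
#' @param stats A `ProbeStats` data frame from [probe_ttest()].
#' @param matrix The (smoothed) `MethylationMatrix` the stats came from.
#' @param group1,group2 Sample ids as passed to [probe_ttest()].
#' @param p_cutoff Per-probe significance cutoff (default 0.005).
#' @param min_probes Minimum member probes per region (default 3; runs of
#'   fewer significant probes are excluded).
#' @return `data.frame` of class `TDMR`: `region_id`, `chrom`, `start`,
#'   `end`, `n_probes`, `direction`, `delta_m`, `area`, `region_p`,
#'   `probe_ids` (comma-separated), ranked by [rank_regions()].
#' @export
call_regions <- function(stats, matrix, group1, group2,
                         p_cutoff = 0.005, min_probes = 3L) {
  assert_that(p_cutoff > 0 && p_cutoff < 1, "p_cutoff must be in (0, 1)")
  assert_that(min_probes >= 1, "min_probes must be >= 1")
  sig <- stats$p_value < p_cutoff
  sgn <- sign(stats$t_stat)
  # run label: 0 outside significance, else signed, reset across clusters
  lab <- ifelse(sig, sgn, 0)
  key <- paste(stats$cluster_id, lab)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  runs <- which(r$lengths >= min_probes &
                  lab[begins] != 0 & !is.na(lab[begins]))
  rows <- lapply(runs, function(k) {
    idx <- begins[k]:ends[k]
    mem <- stats[idx, , drop = FALSE]
    mrows <- matrix$m[idx, , drop = FALSE]
    reg_mean1 <- colMeans(mrows[, group1, drop = FALSE])
    reg_mean2 <- colMeans(mrows[, group2, drop = FALSE])
    rp <- .pooled_t(matrix(reg_mean1, nrow = 1),
                    matrix(reg_mean2, nrow = 1))
    data.frame(chrom = mem$chrom[1],
               start = mem$start[1],
               end = mem$start[nrow(mem)] + mem$length[nrow(mem)],
               n_probes = nrow(mem),
               direction = as.integer(sign(mem$t_stat[1])),
               delta_m = mean(mem$delta_m),
               area = sum(abs(mem$t_stat)),
               region_p = rp$p,
               probe_ids = paste(mem$probe_id, collapse = ","))
  })
  regions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_probes = integer(), direction = integer(),
               delta_m = numeric(), area = numeric(), region_p = numeric(),
               probe_ids = character())
  rank_regions(regions)
}

#' Rank regions
#'
#' Orders by ascending region p, ties broken by descending area, then by
#' coordinates; assigns a 1-based `rank` and stable `region_id`s of the
#' form `TDMR_<rank>`.
#'
#' @param regions A `TDMR` data frame (with or without prior ranks).
#' @return The re-ordered, re-ranked `TDMR` data frame.
#' @export
rank_regions <- function(regions) {
  regions$rank <- NULL; regions$region_id <- NULL
  if (nrow(regions) > 0) {
    ord <- order(regions$region_p, -regions$area, regions$chrom,
                 regions$start)
    regions <- regions[ord, , drop = FALSE]
    rownames(regions) <- NULL
    regions$rank <- seq_len(nrow(regions))
    regions$region_id <- sprintf("TDMR_%d", regions$rank)
  } else {
    regions$rank <- integer(0)
    regions$region_id <- character(0)
  }
  first <- c("region_id", "rank", "chrom", "start", "end")
  regions <- regions[, c(first, setdiff(names(regions), first)),
                     drop = FALSE]
  class(regions) <- c("TDMR", "data.frame")
  regions
}
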