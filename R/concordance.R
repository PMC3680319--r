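# Concordance of region-level differential methylation between a reference
# (high-input) experiment and low-input experiments: correlation vs a
# shuffled null, and verified / dropout classification.

#' Region-level differential methylation
#'
#' Mean over a region's member probes of (mean M in group1 - mean M in
#' group2), computed on (smoothed) M values. Groups may hold a single
#' sample each, as in low-input 1-vs-1 comparisons.
#'
#' @param matrix A `MethylationMatrix`.
#' @param probe_ids Member probe ids of the region (character vector, or a
#'   single comma-separated string as stored in region tables).
#' @param group1,group2 Sample ids.
#' @return Scalar delta-M (group1 - group2).
#' @export
region_delta_m <- function(matrix, probe_ids, group1, group2) {
  if (length(probe_ids) == 1L && grepl(",", probe_ids)) {
    probe_ids <- strsplit(probe_ids, ",", fixed = TRUE)[[1]]
  }
  idx <- match(probe_ids, rownames(matrix$m))
  assert_that(!anyNA(idx), "probes absent from matrix: %s",
              paste(probe_ids[is.na(idx)], collapse = ", "))
  assert_that(length(idx) > 0, "no member probes")
  m <- matrix$m[idx, , drop = FALSE]
  mean(rowMeans(m[, group1, drop = FALSE]) -
         rowMeans(m[, group2, drop = FALSE]))
}

#' Delta-M of every region in a table
#' @param matrix A `MethylationMatrix`.
#' @param regions `TDMR` data frame with a `probe_ids` column.
#' @param group1,group2 Sample ids.
#' @return Numeric vector aligned to `regions` rows.
#' @export
regions_delta_m <- function(matrix, regions, group1, group2) {
  vapply(regions$probe_ids, function(p) {
    region_delta_m(matrix, p, group1, group2)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify regions as verified or dropout across low-input runs
#'
#' A region is `verified` when every low-input run reproduces the reference
#' delta-M sign; `dropout_1` when exactly one run disagrees; `dropout_2plus`
#' when two or more disagree. A low-run delta-M of exactly 0 has no
#' direction and counts as a (flagged) disagreement.
#'
#' @param region_id Region identifiers.
#' @param reference_dm Reference delta-M per region (nonzero).
#' @param low_dm Matrix of delta-M, regions in rows, one column per
#'   low-input run (no missing values).
#' @return `data.frame` of class `ConcordanceResult`: `region_id`,
#'   `delta_m_reference`, one `agree_<run>` flag per run, `n_disagree`,
#'   `tie_flag`, `label`; attribute `summary` holds label counts and
#'   fractions.
#' @export
classify_regions <- function(region_id, reference_dm, low_dm) {
  low_dm <- as.matrix(low_dm)
  assert_that(length(region_id) == length(reference_dm) &&
                length(reference_dm) == nrow(low_dm),
              "region_id, reference_dm and low_dm rows must align")
  assert_that(all(reference_dm != 0), "reference delta-M must be nonzero")
  if (anyNA(low_dm)) {
    bad <- which(is.na(low_dm), arr.ind = TRUE)
    stop(sprintf("missing delta-M for region '%s' in run %s",
                 region_id[bad[1, 1]],
                 colnames(low_dm)[bad[1, 2]] %||% bad[1, 2]), call. = FALSE)
  }
  if (is.null(colnames(low_dm))) {
    colnames(low_dm) <- paste0("run", seq_len(ncol(low_dm)))
  }
  agree <- sweep(sign(low_dm), 1, sign(reference_dm), "==") & low_dm != 0
  n_dis <- rowSums(!agree)
  label <- ifelse(n_dis == 0, "verified",
                  ifelse(n_dis == 1, "dropout_1", "dropout_2plus"))
  out <- data.frame(region_id = region_id,
                    delta_m_reference = reference_dm)
  for (j in colnames(low_dm)) out[[paste0("agree_", j)]] <- agree[, j]
  out$n_disagree <- n_dis
  out$tie_flag <- rowSums(low_dm == 0) > 0
  out$label <- label
  counts <- c(verified = sum(label == "verified"),
              dropout_1 = sum(label == "dropout_1"),
              dropout_2plus = sum(label == "dropout_2plus"))
  attr(out, "summary") <- data.frame(label = names(counts),
                                     count = as.integer(counts),
                                     fraction = as.numeric(counts) /
                                       length(label))
  class(out) <- c("ConcordanceResult", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation of paired region delta-M vectors
#'
#' @param reference_dm,low_dm Paired numeric vectors (length >= 3, finite).
#' @return Pearson correlation coefficient.
#' @export
delta_m_correlation <- function(reference_dm, low_dm) {
  assert_that(length(reference_dm) == length(low_dm),
              "vectors must be paired")
  assert_that(length(reference_dm) >= 3, "need >= 3 paired values")
  assert_that(all(is.finite(reference_dm)) && all(is.finite(low_dm)),
              "delta-M values must be finite")
  assert_that(sd(reference_dm) > 0 && sd(low_dm) > 0,
              "correlation undefined: zero variance")
  cor(reference_dm, low_dm)
}

#' Shuffled-pairing null for the delta-M correlation
#'
#' Permutes the pairing of the low-input delta-M vector against the
#' reference `n_perm` times (seeded), recording the Pearson correlation
#' each time, and reports the null's mean, SD and 2.5/97.5 percentiles plus
#' a one-sided empirical p for the observed correlation.
#'
#' @param reference_dm,low_dm Paired delta-M vectors.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List of class `CorrelationReport`: `observed`, `null_mean`,
#'   `null_sd`, `null_q025`, `null_q975`, `p_empirical`, `n_regions`,
#'   `n_perm`, `null_cc` (the full null vector).
#' @export
shuffled_null <- function(reference_dm, low_dm, n_perm = 1000L, seed = 1L) {
  assert_that(n_perm >= 100, "n_perm must be >= 100")
  obs <- delta_m_correlation(reference_dm, low_dm)
  null_cc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      cor(reference_dm, sample(low_dm))
    }, numeric(1))
  })
  structure(list(observed = obs,
                 null_mean = mean(null_cc),
                 null_sd = sd(null_cc),
                 null_q025 = quantile(null_cc, 0.025, names = FALSE),
                 null_q975 = quantile(null_cc, 0.975, names = FALSE),
                 p_empirical = (1 + sum(null_cc >= obs)) / (n_perm + 1),
                 n_regions = length(reference_dm),
                 n_perm = as.integer(n_perm),
                 null_cc = null_cc),
            class = "CorrelationReport")
}

#' @export
print.CorrelationReport <- function(x, ...) {
  cat(sprintf(
    "delta-M correlation %.3f over %d regions; null %.3f +/- %.3f (95%% [%.3f, %.3f]), empirical p = %.4g\n",
    x$observed, x$n_regions, x$null_mean, x$null_sd, x$null_q025,
    x$null_q975, x$p_empirical))
  invisible(x)
}
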