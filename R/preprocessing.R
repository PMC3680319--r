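# QC and normalization of raw two-channel intensities into the
# relative-methylation (M = log2 enriched/input) matrix.

#' Hybridization signal score
#'
#' Fraction of genomic probes whose input-channel intensity ranks above the
#' anti-genomic background: specifically, above the `background_quantile`
#' (default 0.90) of the anti-genomic input-channel intensities. Successful
#' hybridizations typically score above 0.85.
#'
#' @param sample An `ArraySample`.
#' @param probes The matching `ProbeSet`.
#' @param background_quantile Quantile of the anti-genomic intensity
#'   distribution used as the background cut, in (0, 1).
#' @return Fraction in `[0, 1]`.
#' @export
signal_score <- function(sample, probes, background_quantile = 0.9) {
  assert_that(background_quantile > 0 && background_quantile < 1,
              "background_quantile must be in (0, 1)")
  ag <- probes$is_antigenomic
  assert_that(any(ag), "signal score undefined: no anti-genomic probes")
  gen <- is_genomic_probe(probes)
  assert_that(any(gen), "no genomic probes")
  cut <- quantile(sample$input_intensity[ag], background_quantile,
                  names = FALSE, type = 7)
  mean(sample$input_intensity[gen] > cut)
}

#' Within-sample loess dye-bias correction
#'
#' Fits a local regression of M = log2(enriched/input) on
#' A = (1/2) log2(enriched * input) using the non-genomic control probes
#' only, then subtracts the fitted trend (evaluated at each probe's A) from
#' every probe's M by rescaling the enriched channel. After correction the
#' control probes' M is centered on zero across the intensity range.
#'
#' @param sample An `ArraySample`.
#' @param probes The matching `ProbeSet` (needs >= 50 control probes).
#' @param span Loess span in (0, 1], default 0.4, local degree 1.
#' @return The corrected `ArraySample` (enriched channel rescaled).
#' @export
loess_dye_correction <- function(sample, probes, span = 0.4) {
  assert_that(span > 0 && span <= 1, "span must be in (0, 1]")
  ctl <- probes$is_control
  assert_that(sum(ctl) >= 50,
              "need >= 50 control probes for a stable loess fit (got %d)",
              sum(ctl))
  m <- log2(sample$enriched_intensity / sample$input_intensity)
  a <- 0.5 * log2(sample$enriched_intensity * sample$input_intensity)
  fit <- loess(m[ctl] ~ a[ctl], span = span, degree = 1,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  # clamp evaluation to the fitted range; loess extrapolation is unreliable
  a_eval <- pmin(pmax(a, min(a[ctl])), max(a[ctl]))
  trend <- predict(fit, newdata = a_eval)
  out <- sample
  out$enriched_intensity <- sample$enriched_intensity * 2^(-trend)
  out
}

#' Between-sample quantile normalization
#'
#' Forces every sample's sorted value vector to the across-sample mean of
#' sorted vectors, preserving within-sample rank order; ties receive the
#' mean of the tied reference values. Thin wrapper over
#' `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param m Numeric matrix, probes in rows, one column per sample.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Normalize an experiment into a relative-methylation matrix
#'
#' Applies, in order: intensity floor, signal-score QC (samples below the
#' threshold are flagged, not dropped), per-sample loess dye correction on
#' control probes, and between-sample quantile normalization of
#' M = log2(enriched/input); returns the genomic-probe M matrix.
#'
#' @param bundle An `ExperimentBundle`.
#' @param span Loess span.
#' @param background_quantile Background quantile for [signal_score()].
#' @param signal_threshold QC flag threshold on the signal score.
#' @param intensity_floor Intensities below this are clamped before the log.
#' @param loess_correct Apply the loess stage (disable only for debugging).
#' @return Object of class `MethylationMatrix`: `m` (genomic probes x
#'   samples, dimnames set), `probes` (genomic `ProbeSet` rows), `samples`
#'   (data.frame with `sample_id`, `tissue`, `input_ng`, `replicate`,
#'   `signal_score`, `qc_flag`), `smoothed = FALSE`.
#' @export
relative_methylation <- function(bundle, span = 0.4,
                                 background_quantile = 0.9,
                                 signal_threshold = 0.85,
                                 intensity_floor = 1,
                                 loess_correct = TRUE) {
  probes <- bundle$probes
  gen <- is_genomic_probe(probes)
  assert_that(any(gen), "bundle has no genomic probes")
  assert_that(length(bundle$samples) >= 1, "bundle has no samples")

  samples <- lapply(bundle$samples, function(s) {
    n_low <- sum(s$input_intensity < intensity_floor |
                   s$enriched_intensity < intensity_floor)
    if (n_low > 0) {
      message(sprintf("sample %s: %d intensities clamped to floor %g",
                      s$sample_id, n_low, intensity_floor))
    }
    s$input_intensity <- pmax(s$input_intensity, intensity_floor)
    s$enriched_intensity <- pmax(s$enriched_intensity, intensity_floor)
    s
  })

  scores <- vapply(samples, signal_score, numeric(1),
                   probes = probes, background_quantile = background_quantile)
  flags <- scores < signal_threshold
  if (all(flags)) {
    stop("all samples fail signal-score QC (threshold ", signal_threshold,
         "); best score ", round(max(scores), 3), call. = FALSE)
  }
  if (any(flags)) {
    warning("samples flagged by signal-score QC (kept): ",
            paste(names(samples)[flags], collapse = ", "))
  }

  if (loess_correct) {
    samples <- lapply(samples, loess_dye_correction, probes = probes,
                      span = span)
  }

  m <- vapply(samples, function(s) {
    log2(s$enriched_intensity[gen] / s$input_intensity[gen])
  }, numeric(sum(gen)))
  m <- matrix(m, nrow = sum(gen),
              dimnames = list(probes$probe_id[gen],
                              vapply(samples, `[[`, "", "sample_id")))
  if (ncol(m) >= 2) m <- quantile_normalize(m)

  sample_df <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, tissue = s$tissue,
               input_ng = s$input_ng, replicate = s$replicate)
  }))
  rownames(sample_df) <- NULL
  sample_df$signal_score <- unname(scores)
  sample_df$qc_flag <- unname(flags)

  structure(list(m = m, probes = probes[gen, , drop = FALSE],
                 samples = sample_df, smoothed = FALSE),
            class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d probes x %d samples (%s)\n",
              nrow(x$m), ncol(x$m),
              if (isTRUE(x$smoothed)) "smoothed" else "unsmoothed"))
  invisible(x)
}
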