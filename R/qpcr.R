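# QPCR fold-enrichment QC: 2^dCt fold changes between tissues at control
# loci, used as wet-lab checkpoints for MBD enrichment.

#' Fold enrichment from replicate Ct values
#'
#' Mean threshold cycle (Ct) per tissue, dCt = mean(tissue1) -
#' mean(tissue2), and fold enrichment 2^dCt. With equal replicate counts
#' (>= 2) the SEM of replicate-wise fold changes is reported as well.
#' Orientation matters: with Ct measured after methylation enrichment, a
#' locus hypermethylated in tissue2 has the lower Ct there, so
#' dCt(tissue1 - tissue2) > 0 and fold > 1.
#'
#' @param ct_tissue1,ct_tissue2 Replicate Ct values (positive, finite,
#'   >= 1 each).
#' @param gene Locus label.
#' @param tissues Two group labels, order defining the dCt orientation.
#' @return List of class `QpcrMeasurement`: `gene`, `tissues`, `mean_ct`
#'   (length 2), `delta_ct`, `fold_enrichment`, `fold_sem` (`NA` unless
#'   computable).
#' @export
fold_enrichment <- function(ct_tissue1, ct_tissue2, gene = "",
                            tissues = c("tissue1", "tissue2")) {
  assert_that(length(ct_tissue1) >= 1 && length(ct_tissue2) >= 1,
              "need >= 1 Ct replicate per tissue")
  assert_that(all(is.finite(c(ct_tissue1, ct_tissue2))) &&
                all(c(ct_tissue1, ct_tissue2) > 0),
              "Ct values must be positive and finite")
  m1 <- mean(ct_tissue1); m2 <- mean(ct_tissue2)
  dct <- m1 - m2
  fold_sem <- NA_real_
  if (length(ct_tissue1) == length(ct_tissue2) && length(ct_tissue1) >= 2) {
    folds <- 2^(ct_tissue1 - ct_tissue2)
    fold_sem <- sd(folds) / sqrt(length(folds))
  }
  structure(list(gene = gene, tissues = tissues,
                 mean_ct = c(m1, m2), delta_ct = dct,
                 fold_enrichment = 2^dct, fold_sem = fold_sem),
            class = "QpcrMeasurement")
}

#' @export
print.QpcrMeasurement <- function(x, ...) {
  cat(sprintf("QPCR %s: dCt(%s - %s) = %.3f, fold = %.3f%s\n",
              x$gene, x$tissues[1], x$tissues[2], x$delta_ct,
              x$fold_enrichment,
              if (is.na(x$fold_sem)) "" else
                sprintf(" (SEM %.3f)", x$fold_sem)))
  invisible(x)
}

#' Does a measurement pass the enrichment check?
#'
#' For hypermethylated-control loci the rule is strict: fold enrichment
#' must exceed `threshold_fold` (default 2). For equal-methylation control
#' loci (imprinted H19-like), set `band = TRUE` to check instead that the
#' fold sits inside the symmetric band `|log2 fold| < log2(threshold_fold)`.
#'
#' @param measurement A `QpcrMeasurement` (or a bare fold-change number).
#' @param threshold_fold Fold threshold (> 0, default 2).
#' @param band Use the symmetric no-enrichment band check.
#' @return Logical flag.
#' @export
enrichment_passes <- function(measurement, threshold_fold = 2,
                              band = FALSE) {
  assert_that(threshold_fold > 0, "threshold_fold must be > 0")
  fold <- if (inherits(measurement, "QpcrMeasurement")) {
    measurement$fold_enrichment
  } else as.numeric(measurement)
  if (band) {
    abs(log2(fold)) < log2(threshold_fold)
  } else {
    fold > threshold_fold
  }
}

#' QPCR report from a long-format Ct table
#'
#' @param ct_table Data frame with columns `gene`, `tissue`, `replicate`,
#'   `ct`.
#' @param tissue1,tissue2 Group labels defining the dCt orientation.
#' @param threshold_fold Pass threshold.
#' @param band_genes Genes checked with the symmetric band rule instead of
#'   the strict enrichment rule (equal-methylation controls).
#' @return Data frame, one row per gene: `gene`, `delta_ct`,
#'   `fold_enrichment`, `fold_sem`, `rule`, `pass`.
#' @export
qpcr_report <- function(ct_table, tissue1, tissue2, threshold_fold = 2,
                        band_genes = character()) {
  need <- c("gene", "tissue", "replicate", "ct")
  assert_that(all(need %in% names(ct_table)),
              "ct_table lacks columns: %s",
              paste(setdiff(need, names(ct_table)), collapse = ", "))
  rows <- lapply(unique(ct_table$gene), function(g) {
    sub <- ct_table[ct_table$gene == g, , drop = FALSE]
    meas <- fold_enrichment(sub$ct[sub$tissue == tissue1],
                            sub$ct[sub$tissue == tissue2],
                            gene = g, tissues = c(tissue1, tissue2))
    band <- g %in% band_genes
    data.frame(gene = g, delta_ct = meas$delta_ct,
               fold_enrichment = meas$fold_enrichment,
               fold_sem = meas$fold_sem,
               rule = if (band) "band" else "enriched",
               pass = enrichment_passes(meas, threshold_fold, band = band))
  })
  do.call(rbind, rows)
}
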