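# CpG landscape annotation: observed/expected CpG ratio and triangular-
# weighted local CpG density from genome sequence.

#' Observed-to-expected CpG ratio of a sequence
#'
#' Computes `N_CpG / (N_C * N_G) * L`, where `N_CpG`, `N_C`, `N_G` are the
#' counts of CG dinucleotides, C and G nucleotides, and `L` is the sequence
#' length. `N` bases are excluded from all counts and from `L`. Values
#' above 0.6 are conventionally CpG-island-like.
#'
#' @param sequence Nucleotide string over A/C/G/T/N (length >= 2), or a
#'   `Biostrings::DNAString`.
#' @return The ratio (>= 0). If the sequence has no C or no G the ratio is
#'   undefined; 0 is returned with attribute `degenerate = TRUE`.
#' @export
cpg_oe <- function(sequence) {
  d <- if (is(sequence, "DNAString")) sequence else {
    assert_that(is.character(sequence) && length(sequence) == 1L,
                "sequence must be a single string")
    Biostrings::DNAString(sequence)
  }
  assert_that(length(d) >= 2, "sequence must have length >= 2")
  lf <- Biostrings::letterFrequency(d, letters = c("C", "G", "N"))
  n_c <- lf[["C"]]; n_g <- lf[["G"]]
  l <- length(d) - lf[["N"]]
  if (n_c == 0 || n_g == 0) {
    return(structure(0, degenerate = TRUE))
  }
  n_cpg <- Biostrings::countPattern("CG", d)
  n_cpg / (n_c * n_g) * l
}

#' Local weighted CpG density at a position
#'
#' Triangular-weighted count of CpG sites within `half_window` bases of a
#' nucleotide: a CpG at offset `d` (measured at its C) contributes weight
#' `1 - |d| / half_window` (1 at the center, 0 at the boundary); windows
#' truncated at chromosome ends simply use the in-bounds sites.
#'
#' @param genome A `GenomeSequence`.
#' @param position 0-based nucleotide position.
#' @param half_window Window half-width in bases (default 300, matching the
#'   experiment's average fragment size).
#' @param sites Optional precomputed [cpg_site_positions()] vector (saves
#'   rescanning the genome in loops).
#' @return Non-negative weighted count (dimensionless).
#' @export
local_cpg_density <- function(genome, position, half_window = 300L,
                              sites = NULL) {
  assert_that(half_window >= 1, "half_window must be >= 1")
  assert_that(position >= 0 && position < genome$length,
              "position %d outside genome [0, %d)",
              as.integer(position), genome$length)
  if (is.null(sites)) sites <- cpg_site_positions(genome)
  d <- sites - position
  d <- d[abs(d) <= half_window]
  sum(1 - abs(d) / half_window)
}

#' CpG statistics of one genomic region
#'
#' `local_density` is the mean of [local_cpg_density()] over every
#' nucleotide position in `[start, end)`; `cpg_oe` is computed on the
#' region's sequence.
#'
#' @param genome A `GenomeSequence`.
#' @param start,end Half-open 0-based region bounds within the genome.
#' @param half_window Density window half-width.
#' @param sites Optional precomputed CpG site vector.
#' @return List of class `CpGStats`: `n_cpg`, `n_c`, `n_g`, `length`,
#'   `cpg_oe`, `local_density`, `degenerate`.
#' @export
annotate_region <- function(genome, start, end, half_window = 300L,
                            sites = NULL) {
  assert_that(start >= 0 && end <= genome$length && start < end,
              "region [%d, %d) outside genome [0, %d)",
              as.integer(start), as.integer(end), genome$length)
  if (is.null(sites)) sites <- cpg_site_positions(genome)
  seqr <- Biostrings::DNAString(substr(genome$sequence, start + 1L, end))
  # a 1-base region cannot hold a dinucleotide: O/E degenerately 0
  oe <- if (end - start >= 2) cpg_oe(seqr) else structure(0, degenerate = TRUE)
  lf <- Biostrings::letterFrequency(seqr, letters = c("C", "G"))
  pos <- start:(end - 1L)
  near <- sites[sites >= start - half_window & sites <= end - 1L + half_window]
  dens <- if (length(near) == 0) 0 else {
    w <- 1 - abs(outer(pos, near, "-")) / half_window
    w[w < 0] <- 0
    mean(rowSums(w))
  }
  structure(list(n_cpg = Biostrings::countPattern("CG", seqr),
                 n_c = unname(lf[["C"]]), n_g = unname(lf[["G"]]),
                 length = end - start,
                 cpg_oe = as.numeric(oe),
                 local_density = dens,
                 degenerate = isTRUE(attr(oe, "degenerate"))),
            class = "CpGStats")
}

#' Annotate a table of regions with CpG statistics
#'
#' @param genome A `GenomeSequence`.
#' @param regions `TDMR` data frame (or any data frame with `start`, `end`).
#' @param half_window Density window half-width.
#' @return `regions` with `local_density`, `cpg_oe`, `n_cpg` and
#'   `is_island_like` (`cpg_oe > 0.6`) columns appended.
#' @export
annotate_regions <- function(genome, regions, half_window = 300L) {
  sites <- cpg_site_positions(genome)
  ann <- lapply(seq_len(nrow(regions)), function(i) {
    annotate_region(genome, regions$start[i], regions$end[i],
                    half_window = half_window, sites = sites)
  })
  regions$local_density <- vapply(ann, `[[`, numeric(1), "local_density")
  regions$cpg_oe <- vapply(ann, `[[`, numeric(1), "cpg_oe")
  regions$n_cpg <- vapply(ann, `[[`, numeric(1), "n_cpg")
  regions$is_island_like <- regions$cpg_oe > 0.6
  regions
}

#' Summarize the CpG landscape of called regions
#'
#' Range and mean of local CpG density and CpG O/E over annotated regions,
#' histogram tables for both, and the count of island-like regions
#' (O/E > 0.6).
#'
#' @param regions Annotated region data frame (from [annotate_regions()]).
#' @param density_binwidth,oe_binwidth Histogram bin widths.
#' @return List of class `landscape_summary`: `stats` (data.frame of
#'   metric/min/max/mean), `density_hist`, `oe_hist`, `n_regions`,
#'   `n_island_like`. Empty input yields empty tables.
#' @export
summarize_landscape <- function(regions, density_binwidth = 2,
                                oe_binwidth = 0.05) {
  if (nrow(regions) == 0) {
    return(structure(list(stats = data.frame(), density_hist = data.frame(),
                          oe_hist = data.frame(), n_regions = 0L,
                          n_island_like = 0L),
                     class = "landscape_summary"))
  }
  assert_that(all(c("local_density", "cpg_oe") %in% names(regions)),
              "regions must be annotated first (see annotate_regions)")
  stats <- data.frame(
    metric = c("local_density", "cpg_oe"),
    min = c(min(regions$local_density), min(regions$cpg_oe)),
    max = c(max(regions$local_density), max(regions$cpg_oe)),
    mean = c(mean(regions$local_density), mean(regions$cpg_oe)))
  hist_table <- function(x, bw) {
    breaks <- seq(0, (max(x) %/% bw + 1) * bw, by = bw)
    cnt <- table(cut(x, breaks, right = FALSE))
    data.frame(bin_start = breaks[-length(breaks)],
               bin_end = breaks[-1], count = as.integer(cnt))
  }
  structure(list(stats = stats,
                 density_hist = hist_table(regions$local_density,
                                           density_binwidth),
                 oe_hist = hist_table(regions$cpg_oe, oe_binwidth),
                 n_regions = nrow(regions),
                 n_island_like = sum(regions$cpg_oe > 0.6)),
            class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat(sprintf("CpG landscape over %d regions (%d island-like, O/E > 0.6)\n",
              x$n_regions, x$n_island_like))
  if (x$n_regions > 0) print(x$stats)
  invisible(x)
}
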