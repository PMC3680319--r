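# Synthetic data: genomes, probe tilings and two-channel intensities with
# known truth, emulating an MBD-enrichment tiling-array experiment.

#' Construct a genome sequence object
#'
#' A minimal single-chromosome container: a name, an A/C/G/T string, and an
#' optional table of CpG-island coordinates (populated by
#' [generate_genome()]). Coordinates are half-open, 0-based.
#'
#' @param name Chromosome label.
#' @param sequence Character scalar over the alphabet A/C/G/T (N is allowed
#'   for externally supplied genomes; the simulator never emits it).
#' @param islands Optional `data.frame(chrom, start, end)` of elevated-CpG
#'   segments.
#' @return An object of class `GenomeSequence` with fields `name`,
#'   `sequence`, `length`, `islands`.
#' @export
genome_sequence <- function(name, sequence, islands = NULL) {
  assert_that(is.character(sequence) && length(sequence) == 1L,
              "sequence must be a single character string")
  assert_that(!grepl("[^ACGTN]", sequence),
              "sequence contains characters outside A/C/G/T/N")
  if (is.null(islands)) {
    islands <- data.frame(chrom = character(), start = integer(),
                          end = integer())
  }
  structure(list(name = name, sequence = sequence,
                 length = nchar(sequence), islands = islands),
            class = "GenomeSequence")
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat(sprintf("GenomeSequence %s: %d bp, %d island segment(s)\n",
              x$name, x$length, nrow(x$islands)))
  invisible(x)
}

#' 0-based positions of the C of every CpG dinucleotide
#'
#' @param genome A `GenomeSequence` or a plain character sequence.
#' @return Sorted integer vector of 0-based offsets.
#' @export
cpg_site_positions <- function(genome) {
  s <- if (inherits(genome, "GenomeSequence")) genome$sequence else genome
  m <- Biostrings::matchPattern("CG", Biostrings::DNAString(s))
  as.integer(Biostrings::start(m)) - 1L
}

# First-order transition rows for the two-state (background/island) process.
# Rows indexed by previous base A,C,G,T; the C row carries the CpG propensity.
.markov_rows <- function() {
  bg <- rbind(A = c(0.29, 0.21, 0.21, 0.29),
              C = c(0.33, 0.23, 0.012, 0.428),
              G = c(0.29, 0.21, 0.21, 0.29),
              T = c(0.29, 0.21, 0.21, 0.29))
  isl <- rbind(A = c(0.21, 0.29, 0.29, 0.21),
               C = c(0.17, 0.29, 0.33, 0.21),
               G = c(0.21, 0.29, 0.29, 0.21),
               T = c(0.21, 0.29, 0.29, 0.21))
  list(background = bg, island = isl)
}

#' Generate a CpG-heterogeneous genome
#'
#' Emits a single chromosome from a two-state first-order nucleotide
#' process: "island" segments with elevated CpG propensity (target CpG
#' observed/expected ratio >= 0.6) embedded in a CpG-depleted background
#' (target O/E <= 0.3). Island coordinates are reported on the returned
#' object so downstream simulation can plant differential methylation on
#' CpG-dense sequence, mirroring the CpG-driven design of CHARM-style
#' arrays.
#'
#' @param length Genome length in bases; must be >= 1000 (shorter sequences
#'   cannot be tiled with probes).
#' @param island_fraction Fraction of the genome covered by island segments,
#'   in `[0, 1]`.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @param island_length_range Min/max island length in bases; island lengths
#'   are drawn uniformly from this range.
#' @param name Chromosome label.
#' @return A [genome_sequence()] object with island coordinates attached.
#' @export
generate_genome <- function(length, island_fraction = 0.05, seed = 1L,
                            island_length_range = c(800L, 2500L),
                            name = "chr1") {
  assert_that(length >= 1000, "genome length must be >= 1000 (got %d)",
              as.integer(length))
  assert_that(island_fraction >= 0 && island_fraction <= 1,
              "island_fraction must be in [0, 1]")
  length <- as.integer(length)

  with_seed(seed, {
    # place non-overlapping islands, one per equal-width block
    starts <- integer(0); lens <- integer(0)
    if (island_fraction > 0) {
      mean_len <- mean(island_length_range)
      n_isl <- max(1L, as.integer(round(length * island_fraction / mean_len)))
      block <- length %/% n_isl
      lens <- pmin(sample(island_length_range[1]:island_length_range[2],
                          n_isl, replace = TRUE), block)
      offmax <- pmax(1L, block - lens)
      starts <- (seq_len(n_isl) - 1L) * block +
        vapply(offmax, function(m) sample.int(m, 1L) - 1L, integer(1))
    }
    state <- rep(1L, length)               # 1 = background, 2 = island
    for (k in seq_along(starts)) {
      state[(starts[k] + 1L):(starts[k] + lens[k])] <- 2L
    }

    rows <- .markov_rows()
    # per (prev-base, state) cumulative thresholds for vector-free lookup
    cum <- array(0, dim = c(4L, 2L, 3L))
    for (st in 1:2) {
      mat <- if (st == 1L) rows$background else rows$island
      cs <- t(apply(mat, 1L, cumsum))
      cum[, st, ] <- cs[, 1:3]
    }
    T1 <- cum[, , 1L]; T2 <- cum[, , 2L]; T3 <- cum[, , 3L]

    u <- runif(length)
    bases <- integer(length)
    prev <- sample.int(4L, 1L)
    for (i in seq_len(length)) {
      st <- state[i]
      ui <- u[i]
      b <- 1L + (ui > T1[prev, st]) + (ui > T2[prev, st]) + (ui > T3[prev, st])
      bases[i] <- b
      prev <- b
    }
    seqstr <- paste(c("A", "C", "G", "T")[bases], collapse = "")
    islands <- data.frame(chrom = rep(name, base::length(starts)),
                          start = starts, end = starts + lens)
    genome_sequence(name, seqstr, islands)
  })
}

#' Tile probes over CpG-containing windows of a genome
#'
#' Candidate probe windows are laid down at fixed spacing; only windows
#' whose footprint fully contains at least one CG dinucleotide are kept
#' (CHARM-style CpG-driven design). Non-genomic normalization control
#' probes and anti-genomic background probes are appended after the
#' genomic probes.
#'
#' @param genome A `GenomeSequence`.
#' @param spacing Start-to-start spacing of candidate windows (bases).
#' @param probe_length Probe footprint length (bases, default 50).
#' @param n_control Number of non-genomic normalization control probes.
#' @param n_antigenomic Number of anti-genomic background probes.
#' @param seed Unused randomness hook (tiling is deterministic); kept so the
#'   generator API is uniformly seedable.
#' @return A `data.frame` of class `ProbeSet` with columns `probe_id`,
#'   `chrom`, `start` (0-based; `NA` for non-genomic probes), `length`,
#'   `is_control`, `is_antigenomic`, `cpg_count`. Genomic probes are sorted
#'   by (chrom, start).
#' @export
tile_probes <- function(genome, spacing = 35L, probe_length = 50L,
                        n_control = 500L, n_antigenomic = 500L, seed = 1L) {
  assert_that(spacing >= 1, "spacing must be >= 1")
  assert_that(probe_length >= 10, "probe_length must be >= 10")
  assert_that(probe_length <= genome$length,
              "probe_length (%d) exceeds genome length (%d)",
              as.integer(probe_length), genome$length)
  spacing <- as.integer(spacing); probe_length <- as.integer(probe_length)

  starts <- seq.int(0L, genome$length - probe_length, by = spacing)
  sites <- cpg_site_positions(genome)
  # CG fully inside footprint: C at position in [start, start+len-2]
  n_inside <- findInterval(starts + probe_length - 2L, sites) -
    findInterval(starts - 1L, sites)
  keep <- n_inside >= 1L
  starts <- starts[keep]
  counts <- n_inside[keep]

  gen <- data.frame(
    probe_id = sprintf("P%06d", seq_along(starts)),
    chrom = rep(genome$name, length(starts)),
    start = starts,
    length = probe_length,
    is_control = FALSE,
    is_antigenomic = FALSE,
    cpg_count = as.integer(counts))
  ctl <- data.frame(
    probe_id = sprintf("CTRL%04d", seq_len(n_control)),
    chrom = NA_character_, start = NA_integer_, length = probe_length,
    is_control = TRUE, is_antigenomic = FALSE, cpg_count = 0L)
  ag <- data.frame(
    probe_id = sprintf("AG%04d", seq_len(n_antigenomic)),
    chrom = NA_character_, start = NA_integer_, length = probe_length,
    is_control = FALSE, is_antigenomic = TRUE, cpg_count = 0L)
  probes <- rbind(gen, if (n_control > 0) ctl, if (n_antigenomic > 0) ag)
  rownames(probes) <- NULL
  class(probes) <- c("ProbeSet", "data.frame")
  probes
}

#' Default noise and dropout maps for the simulator
#'
#' Per-channel multiplicative log2-intensity noise SD and enriched-channel
#' dropout-to-background probability, by input DNA mass. Noise grows and
#' dropout appears as the input mass shrinks from the 250 ng reference to
#' the 10/25/50 ng low-input arrays.
#' @return Named list with `noise_sd` and `dropout_prob`, both named by ng.
#' @export
default_input_models <- function() {
  list(noise_sd = c("10" = 0.70, "25" = 0.55, "50" = 0.45, "250" = 0.25),
       dropout_prob = c("10" = 0.04, "25" = 0.02, "50" = 0.01, "250" = 0.0))
}

#' Plant tissue-specific methylation truth on a genome
#'
#' Selects `n_dmrs` island segments of the genome as differentially
#' methylated regions and assigns per-tissue methylation levels; direction
#' alternates randomly between tissues. Everything outside a planted DMR
#' sits at the shared baseline.
#'
#' @param genome A `GenomeSequence` produced by [generate_genome()] (its
#'   island table supplies candidate DMR locations).
#' @param n_dmrs Number of planted DMRs.
#' @param seed Integer seed.
#' @param meth_high,meth_low Methylation fractions of the hyper- and
#'   hypomethylated tissue inside a DMR.
#' @param baseline_methylation Methylation fraction everywhere else (both
#'   tissues).
#' @param tissues Two tissue-group labels.
#' @param noise_sd_by_input_ng Named numeric: per-channel log2 noise SD by
#'   input mass; must be non-increasing in ng.
#' @param dropout_prob_by_input_ng Named numeric: enriched-channel dropout
#'   probability by input mass.
#' @return Object of class `SimulationTruth`: `dmr_intervals` (data.frame
#'   with `chrom`, `start`, `end`, `meth_<tissue>` columns), `tissues`,
#'   `baseline_methylation`, `noise_sd_by_input_ng`,
#'   `dropout_prob_by_input_ng`, `seed`.
#' @export
simulate_truth <- function(genome, n_dmrs = 50L, seed = 1L,
                           meth_high = 0.85, meth_low = 0.10,
                           baseline_methylation = 0.10,
                           tissues = c("tissueA", "tissueB"),
                           noise_sd_by_input_ng = default_input_models()$noise_sd,
                           dropout_prob_by_input_ng = default_input_models()$dropout_prob) {
  assert_that(nrow(genome$islands) >= n_dmrs,
              "genome has %d islands but %d DMRs requested",
              nrow(genome$islands), as.integer(n_dmrs))
  assert_that(all(c(meth_high, meth_low, baseline_methylation) >= 0) &&
              all(c(meth_high, meth_low, baseline_methylation) <= 1),
              "methylation levels must be in [0, 1]")
  ord <- order(as.numeric(names(noise_sd_by_input_ng)))
  assert_that(all(diff(noise_sd_by_input_ng[ord]) <= 0),
              "noise SD must be non-increasing in input ng")
  with_seed(seed, {
    pick <- sort(sample.int(nrow(genome$islands), n_dmrs))
    iv <- genome$islands[pick, , drop = FALSE]
    # exactly balanced direction split (random assignment): keeps the two
    # tissues' M-value distributions matched so quantile normalization does
    # not shift null probes systematically between groups
    up_in_1 <- sample(rep(c(TRUE, FALSE), length.out = n_dmrs))
    m1 <- ifelse(up_in_1, meth_high, meth_low)
    m2 <- ifelse(up_in_1, meth_low, meth_high)
    iv[[paste0("meth_", tissues[1])]] <- m1
    iv[[paste0("meth_", tissues[2])]] <- m2
    rownames(iv) <- NULL
    structure(list(dmr_intervals = iv, tissues = tissues,
                   baseline_methylation = baseline_methylation,
                   noise_sd_by_input_ng = noise_sd_by_input_ng,
                   dropout_prob_by_input_ng = dropout_prob_by_input_ng,
                   seed = as.integer(seed)),
              class = "SimulationTruth")
  })
}

#' Per-probe planted methylation for one tissue
#'
#' A genomic probe takes the methylation level of the planted DMR whose
#' interval contains the probe's footprint midpoint, else the baseline.
#' @noRd
.probe_methylation <- function(probes, truth, tissue) {
  m <- rep(truth$baseline_methylation, nrow(probes))
  gen <- is_genomic_probe(probes)
  iv <- truth$dmr_intervals
  col <- paste0("meth_", tissue)
  assert_that(col %in% names(iv), "truth has no methylation for tissue '%s'",
              tissue)
  if (nrow(iv) > 0 && any(gen)) {
    mid <- probes$start[gen] + probes$length[gen] %/% 2L
    idx <- findInterval(mid, iv$start)
    hit <- idx > 0L & mid < iv$end[pmax(idx, 1L)] &
      probes$chrom[gen] == iv$chrom[pmax(idx, 1L)]
    mg <- m[gen]
    mg[hit] <- iv[[col]][idx[hit]]
    m[gen] <- mg
  }
  m
}

#' Saturating MBD-capture response
#'
#' Monotone bounded capture of methylated-CpG content: `g(x) = x / (x + k)`.
#' @param x Methylated-CpG content (methylation fraction times CpG count).
#' @param k Half-saturation constant.
#' @return Values in `[0, 1)`.
#' @export
capture_response <- function(x, k = 2) x / (x + k)

# quadratic intensity-dependent dye bias in M as a function of A; curvature
# kept gentle enough that a degree-1 loess at span 0.4 can remove it to
# well under 0.05 log2 units even at the sparse edges of the control range
.dye_bias <- function(a, strength) strength * (((a - 10) / 7)^2 - 0.5)

#' Simulate two-channel array samples
#'
#' For every requested replicate of every tissue, draws an input-channel
#' intensity (lognormal around a per-probe baseline abundance shared across
#' samples) and an enriched-channel intensity whose expectation is the input
#' times a saturating, monotone function of the probe's methylated-CpG
#' content. Control probes have unit expected enrichment over a wide
#' intensity range (so loess correction can be fitted on them); anti-genomic
#' probes receive background-only intensities in both channels. A smooth
#' intensity-dependent dye bias ("banana") is injected into the enriched
#' channel, and the per-channel noise SD (and a small enriched-channel
#' dropout probability) is looked up from the truth's input-mass maps.
#'
#' @param genome A `GenomeSequence` (carried for provenance; sequence is not
#'   re-read here).
#' @param probes A `ProbeSet`.
#' @param truth A `SimulationTruth`.
#' @param n_replicates_per_tissue Replicates per tissue group (>= 1).
#' @param input_ng Input DNA mass; must be a key of
#'   `truth$noise_sd_by_input_ng`.
#' @param seed Integer seed.
#' @param dye_bias_strength Amplitude of the injected dye bias in log2 units
#'   (0 disables it).
#' @param dynamic_range,capture_k,background_ratio Parameters of the
#'   enrichment response: expected enriched/input ratio is
#'   `background_ratio + dynamic_range * capture_response(meth * cpg_count,
#'   capture_k)`.
#' @param noise_sd Optional override of the per-channel log2 noise SD
#'   (e.g. 0 for noise-free checks); default looks up `input_ng`.
#' @return List of `ArraySample` objects: each a list with `sample_id`,
#'   `tissue`, `input_ng`, `replicate`, `probe_id`, `input_intensity`,
#'   `enriched_intensity` (aligned to `probes`).
#' @export
simulate_experiment <- function(genome, probes, truth,
                                n_replicates_per_tissue = 3L,
                                input_ng = 250, seed = 1L,
                                dye_bias_strength = 0.3,
                                dynamic_range = 4, capture_k = 2,
                                background_ratio = 0.2,
                                noise_sd = NULL) {
  assert_that(n_replicates_per_tissue >= 1,
              "n_replicates_per_tissue must be >= 1")
  key <- as.character(input_ng)
  assert_that(key %in% names(truth$noise_sd_by_input_ng),
              "unknown input_ng %s: truth defines {%s}", key,
              paste(names(truth$noise_sd_by_input_ng), collapse = ", "))
  sdv <- if (is.null(noise_sd)) truth$noise_sd_by_input_ng[[key]] else noise_sd
  pdrop <- truth$dropout_prob_by_input_ng[[key]]
  if (is.null(pdrop) || is.na(pdrop)) pdrop <- 0

  n <- nrow(probes)
  gen <- is_genomic_probe(probes)
  ctl <- probes$is_control
  ag <- probes$is_antigenomic

  with_seed(seed, {
    # per-probe baseline log2 abundance, shared across all samples
    mu <- numeric(n)
    mu[gen] <- rnorm(sum(gen), 10, 0.5)
    mu[ctl] <- rnorm(sum(ctl), 10, 1.5)
    mu[ag] <- rnorm(sum(ag), 5, 0.5)

    ratio <- matrix(1, n, 2,
                    dimnames = list(NULL, truth$tissues))
    for (t in truth$tissues) {
      meth <- .probe_methylation(probes, truth, t)
      x <- meth * probes$cpg_count
      r <- background_ratio + dynamic_range * capture_response(x, capture_k)
      r[!gen] <- 1   # controls and anti-genomic: unit expected ratio
      ratio[, t] <- r
    }

    samples <- list()
    for (t in truth$tissues) {
      lr <- log2(ratio[, t])
      a0 <- mu + lr / 2
      bias <- if (dye_bias_strength != 0) .dye_bias(a0, dye_bias_strength) else 0
      for (r in seq_len(n_replicates_per_tissue)) {
        eps_i <- if (sdv > 0) rnorm(n, 0, sdv) else numeric(n)
        eps_e <- if (sdv > 0) rnorm(n, 0, sdv) else numeric(n)
        e_log <- mu + lr + bias + eps_e
        if (pdrop > 0) {
          drop <- runif(n) < pdrop & gen
          if (any(drop)) e_log[drop] <- 5 + eps_e[drop]
        }
        sid <- sprintf("%s_%sng_rep%d", t, key, r)
        samples[[sid]] <- structure(
          list(sample_id = sid, tissue = t, input_ng = as.numeric(input_ng),
               replicate = r, probe_id = probes$probe_id,
               input_intensity = 2^(mu + eps_i),
               enriched_intensity = 2^e_log),
          class = "ArraySample")
      }
    }
    samples
  })
}
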