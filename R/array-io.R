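# On-disk formats: FASTA genome, probe tables (TSV + BED), per-sample
# intensity tables, sample manifests, called-region tables (TSV + BED).
# All coordinates half-open, 0-based, matching BED.

#' Write a genome to FASTA
#' @param genome A `GenomeSequence`.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(structure(genome$sequence,
                                            names = genome$name))
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}

#' Read a single-chromosome genome from FASTA
#' @param path FASTA path.
#' @return A `GenomeSequence` (first record; a warning is issued if the file
#'   holds more than one sequence).
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  assert_that(length(dss) >= 1L, "no sequences in %s", path)
  if (length(dss) > 1L) {
    warning("FASTA has ", length(dss), " sequences; using the first")
  }
  nm <- sub("\\s.*$", "", names(dss)[1])
  genome_sequence(nm, as.character(dss[[1]]))
}

#' Write a probe table as TSV (and companion BED)
#'
#' The TSV is the canonical on-disk form (all columns). A 6-column BED of
#' the genomic probes is written next to it (`name` in column 4,
#' `cpg_count` as score, strand `.`).
#'
#' @param probes A `ProbeSet` data frame.
#' @param path TSV output path; the BED path is derived by swapping the
#'   extension for `.bed`.
#' @export
write_probes <- function(probes, path) {
  write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gen <- probes[is_genomic_probe(probes), , drop = FALSE]
  bed <- data.frame(gen$chrom, gen$start, gen$start + gen$length,
                    gen$probe_id, gen$cpg_count, ".")
  bed_path <- sub("\\.[^.]*$", ".bed", path)
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a probe table written by [write_probes()]
#' @param path TSV path.
#' @return A `ProbeSet` data frame sorted with genomic probes first by
#'   (chrom, start).
#' @export
read_probes <- function(path) {
  probes <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "length", "is_control",
            "is_antigenomic", "cpg_count")
  assert_that(all(need %in% names(probes)),
              "probe table %s lacks columns: %s", path,
              paste(setdiff(need, names(probes)), collapse = ", "))
  gen <- is_genomic_probe(probes)
  ord <- c(which(gen)[order(probes$chrom[gen], probes$start[gen])],
           which(!gen))
  probes <- probes[ord, , drop = FALSE]
  rownames(probes) <- NULL
  class(probes) <- c("ProbeSet", "data.frame")
  probes
}

#' Write simulated samples, manifest and truth to a directory
#'
#' Layout: `genome.fa`, `probes.tsv` (+ `probes.bed`), `truth.tsv`,
#' `manifest.tsv` and `samples/<sample_id>.tsv` with columns `probe_id`,
#' `input_intensity`, `enriched_intensity`.
#'
#' @param genome A `GenomeSequence` (or `NULL` to skip).
#' @param probes A `ProbeSet`.
#' @param samples List of `ArraySample` objects.
#' @param outdir Output directory (created if needed).
#' @param truth Optional `SimulationTruth`.
#' @return Invisibly, the manifest path.
#' @export
write_experiment <- function(genome, probes, samples, outdir, truth = NULL) {
  dir.create(file.path(outdir, "samples"), recursive = TRUE,
             showWarnings = FALSE)
  if (!is.null(genome)) write_genome_fasta(genome, file.path(outdir, "genome.fa"))
  write_probes(probes, file.path(outdir, "probes.tsv"))
  if (!is.null(truth)) {
    write.table(truth$dmr_intervals, file.path(outdir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  man <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, tissue = s$tissue,
               input_ng = s$input_ng, replicate = s$replicate,
               path = file.path("samples", paste0(s$sample_id, ".tsv")))
  }))
  rownames(man) <- NULL
  for (s in samples) {
    write.table(
      data.frame(probe_id = s$probe_id,
                 input_intensity = s$input_intensity,
                 enriched_intensity = s$enriched_intensity),
      file.path(outdir, "samples", paste0(s$sample_id, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest_path <- file.path(outdir, "manifest.tsv")
  write.table(man, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest_path)
}

#' Assemble an experiment bundle from disk
#'
#' Reads the probe table, the sample manifest and every per-sample intensity
#' table, checks that each intensity file covers exactly the probe ids of
#' the probe set, aligns intensities to probe order, and optionally attaches
#' the genome. Non-positive intensities are clamped to `intensity_floor`
#' with a warning. Samples keep manifest order.
#'
#' @param probe_path Probe TSV path.
#' @param sample_manifest_path Manifest TSV path (columns `sample_id`,
#'   `tissue`, `input_ng`, `replicate`, `path`; `path` relative to the
#'   manifest's directory).
#' @param genome_path Optional FASTA path (`NULL` disables CpG annotation).
#' @param intensity_floor Clamp floor for non-positive intensities.
#' @return Object of class `ExperimentBundle`: `probes`, `samples` (list of
#'   `ArraySample`), `genome` (or `NULL`).
#' @export
read_experiment <- function(probe_path, sample_manifest_path,
                            genome_path = NULL, intensity_floor = 1) {
  probes <- read_probes(probe_path)
  man <- read.delim(sample_manifest_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "input_ng", "replicate", "path")
  assert_that(all(need %in% names(man)),
              "manifest lacks columns: %s",
              paste(setdiff(need, names(man)), collapse = ", "))
  base <- dirname(sample_manifest_path)
  clamped <- 0L
  samples <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    tab <- read.delim(file.path(base, man$path[i]), stringsAsFactors = FALSE)
    missing_ids <- setdiff(probes$probe_id, tab$probe_id)
    extra_ids <- setdiff(tab$probe_id, probes$probe_id)
    if (length(missing_ids) || length(extra_ids)) {
      stop(sprintf(
        "probe id mismatch in sample '%s': missing [%s], unexpected [%s]",
        man$sample_id[i],
        paste(head(missing_ids, 5), collapse = ", "),
        paste(head(extra_ids, 5), collapse = ", ")), call. = FALSE)
    }
    idx <- match(probes$probe_id, tab$probe_id)
    ii <- tab$input_intensity[idx]
    ee <- tab$enriched_intensity[idx]
    low <- ii <= 0 | ee <= 0
    if (any(low)) {
      clamped <- clamped + sum(low)
      ii[ii <= 0] <- intensity_floor
      ee[ee <= 0] <- intensity_floor
    }
    samples[[i]] <- structure(
      list(sample_id = man$sample_id[i], tissue = man$tissue[i],
           input_ng = man$input_ng[i], replicate = man$replicate[i],
           probe_id = probes$probe_id,
           input_intensity = ii, enriched_intensity = ee),
      class = "ArraySample")
  }
  names(samples) <- man$sample_id
  if (clamped > 0) {
    warning(clamped, " non-positive intensities clamped to the floor of ",
            intensity_floor)
  }
  genome <- if (!is.null(genome_path)) read_genome_fasta(genome_path) else NULL
  structure(list(probes = probes, samples = samples, genome = genome),
            class = "ExperimentBundle")
}

#' @export
print.ExperimentBundle <- function(x, ...) {
  cat(sprintf(
    "ExperimentBundle: %d probes (%d genomic), %d samples, genome %s\n",
    nrow(x$probes), sum(is_genomic_probe(x$probes)), length(x$samples),
    if (is.null(x$genome)) "absent" else x$genome$name))
  invisible(x)
}

#' Write called regions as TSV and BED
#'
#' The TSV carries every column of the region table (full float precision);
#' the BED (same path with a `.bed` extension) carries chrom, start, end,
#' name, score = -log10(region p) capped at 320, strand `.`.
#'
#' @param regions Region `data.frame` from [call_regions()] /
#'   [rank_regions()] (may have zero rows).
#' @param path Output TSV path.
#' @export
write_regions <- function(regions, path) {
  write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_path <- sub("\\.[^.]*$", ".bed", path)
  if (nrow(regions) > 0) {
    score <- -log10(regions$region_p)
    score[!is.finite(score) | score > 320] <- 320
    bed <- data.frame(regions$chrom, regions$start, regions$end,
                      regions$region_id, round(score, 4), ".")
  } else {
    bed <- data.frame()
  }
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a region TSV written by [write_regions()]
#' @param path TSV path.
#' @return Region `data.frame`.
#' @export
read_regions <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
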