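# Independent brute-force oracles. These deliberately share no code with
# the package: plain character loops and textbook formulas only.

# counts of CG dinucleotides, C, G and effective length (N excluded)
oracle_cpg_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n_cpg <- 0L
  for (i in seq_len(length(ch) - 1L)) {
    if (ch[i] == "C" && ch[i + 1L] == "G") n_cpg <- n_cpg + 1L
  }
  list(n_cpg = n_cpg, n_c = sum(ch == "C"), n_g = sum(ch == "G"),
       l = sum(ch != "N"))
}

oracle_cpg_oe <- function(s) {
  k <- oracle_cpg_counts(s)
  if (k$n_c == 0 || k$n_g == 0) return(0)
  k$n_cpg / (k$n_c * k$n_g) * k$l
}

# triangular-weighted CpG density at 0-based position, exhaustive offsets
oracle_density <- function(s, pos0, hw) {
  ch <- strsplit(s, "")[[1]]
  total <- 0
  for (d in (-hw):hw) {
    i <- pos0 + d            # 0-based C position of a putative CpG
    if (i >= 0 && i + 1L < length(ch)) {
      if (ch[i + 1L] == "C" && ch[i + 2L] == "G") {
        total <- total + (1 - abs(d) / hw)
      }
    }
  }
  total
}

# pooled-variance two-sample t, textbook formula on plain vectors
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  t <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# triangular-kernel weighted mean at each probe, exhaustive pair loop
oracle_smooth <- function(pos, m, window) {
  out <- numeric(length(pos))
  for (i in seq_along(pos)) {
    num <- 0; den <- 0
    for (j in seq_along(pos)) {
      w <- 1 - abs(pos[j] - pos[i]) / window
      if (w > 0) { num <- num + w * m[j]; den <- den + w }
    }
    out[i] <- num / den
  }
  out
}

# enumerate all maximal qualifying runs in one cluster: every [i, j] window
# whose probes are all significant with one t sign, not extendable, with at
# least min_probes members; returns a list of index vectors
oracle_enumerate_runs <- function(p, sgn, cutoff, min_probes) {
  n <- length(p)
  ok <- function(i, j) {
    idx <- i:j
    all(p[idx] < cutoff) && length(unique(sgn[idx])) == 1L
  }
  runs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!ok(i, j)) next
      extend_left <- i > 1 && ok(i - 1L, j)
      extend_right <- j < n && ok(i, j + 1L)
      if (!extend_left && !extend_right && (j - i + 1L) >= min_probes) {
        runs[[length(runs) + 1L]] <- i:j
      }
    }
  }
  runs
}

# Pearson correlation from the covariance/sd definition
oracle_cor <- function(x, y) {
  n <- length(x)
  cv <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cv / (sd(x) * sd(y))
}

# random A/C/G/T string
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
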