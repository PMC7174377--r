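# shared fixtures and independent oracles used across test files

# independent oracle: occupancy distribution by explicit enumeration of all
# R^n equal-probability placements of n cells into R replicates
occupancy_by_enumeration <- function(n, R) {
  placements <- expand.grid(rep(list(seq_len(R)), n))
  k <- apply(placements, 1, function(x) length(unique(x)))
  as.numeric(table(factor(k, levels = 0:R))) / nrow(placements)
}

# independent oracle: one-sided exact binomial tail P(X >= k | n, p)
binom_tail_oracle <- function(k, n, p) sum(dbinom(k:n, n, p))

# hand-written FASTQ writer (deliberately independent of the package's
# Biostrings-based writer)
write_fastq_lines <- function(path, seqs, quals, ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", quals))
  writeLines(lines, path)
  path
}

phred33 <- function(q, n) strrep(rawToChar(as.raw(33L + q)), n)

# annotate segments with het flag and median het major AF from a BAF/LRR
# profile, as the ploidy solver expects
annotate_segments <- function(prof, segs) {
  segs$lrr <- segs$mean
  segs$het <- NA
  segs$m_baf <- NA_real_
  for (i in seq_len(nrow(segs))) {
    sel <- prof$chrom == segs$chrom[i] & prof$pos >= segs$start[i] &
      prof$pos <= segs$end[i]
    h <- test_segment_heterozygosity(prof$major_af[sel])
    segs$het[i] <- h$het
    segs$m_baf[i] <- if (h$het) h$median_het_major_af else 1
  }
  segs
}

# balanced copy-number profiles whose median-coverage locus sits at the
# ploidy (the identifiability condition of median-LRR normalisation)
triploid_profile <- function(seed) {
  generate_snp_dataset(list(c(2, 0), c(2, 1), c(3, 0), c(2, 2)),
                       n_snps = c(200, 300, 300, 200), depth = 80,
                       psi_true = 3, seed = seed)
}

diploid_profile <- function(seed) {
  generate_snp_dataset(list(c(1, 0), c(1, 1), c(2, 1)),
                       n_snps = c(200, 600, 200), depth = 80,
                       psi_true = 2, seed = seed)
}

solve_ploidy_from_profile <- function(snp, seed) {
  prof <- compute_baf_lrr(snp, seed = seed)
  segs <- segment_signal(prof$lrr, prof$pos, prof$chrom,
                         segments = attr(snp, "truth"))
  solve_ploidy(annotate_segments(prof, segs))
}
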