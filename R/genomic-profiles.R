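#' Select SNVs enriched in treated lines over the baseline population
#'
#' Flags SNVs whose variant allele frequency (VAF) in a treated line is at
#' least `fold` times the baseline (POT) VAF, requiring a minimum coverage
#' in every sample. A baseline VAF of zero is floored at
#' `1 / (coverage + 1)` — the resolution limit of the observed depth — so
#' the fold change is defined.
#'
#' @param snv Data frame with columns `<sample>.vaf` and `<sample>.dp` for
#'   the baseline and every treated sample (plus any locus columns, which
#'   are carried through).
#' @param treated Character vector of treated sample names.
#' @param pot Baseline sample name (default `"POT"`).
#' @param fold Enrichment factor (default 10).
#' @param min_cov Minimum coverage required in all samples (default 10).
#' @return The input rows that pass, with logical columns
#'   `enriched_<sample>` per treated sample and `enriched` (any sample).
#' @export
vaf_enrichment <- function(snv, treated, pot = "POT", fold = 10,
                           min_cov = 10) {
  need <- c(paste0(c(pot, treated), ".vaf"), paste0(c(pot, treated), ".dp"))
  missing_cols <- setdiff(need, names(snv))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  dp <- as.matrix(snv[, paste0(c(pot, treated), ".dp"), drop = FALSE])
  covered <- rowSums(dp >= min_cov) == ncol(dp)
  pot_vaf <- snv[[paste0(pot, ".vaf")]]
  pot_floor <- ifelse(pot_vaf > 0, pot_vaf, 1 / (snv[[paste0(pot, ".dp")]] + 1))
  out <- snv
  any_enr <- rep(FALSE, nrow(snv))
  for (s in treated) {
    e <- covered & snv[[paste0(s, ".vaf")]] >= fold * pot_floor
    out[[paste0("enriched_", s)]] <- e
    any_enr <- any_enr | e
  }
  out$enriched <- any_enr
  out[out$enriched, , drop = FALSE]
}

#' Compute BAF and LRR from per-SNP base counts
#'
#' Restricts to SNPs with a global minor allele frequency between 0.1 and
#' 0.2 and genomic position of at least 100,000 bp, then computes the major
#' allele frequency (highest base count over total coverage), the B-allele
#' frequency (the major AF or its complement, flipped with probability 1/2
#' to emulate random A/B allele assignment), and the log R ratio
#' (log2 coverage, centred on its global median).
#'
#' @param profile Data frame with columns `chrom`, `pos`, `A`, `C`, `G`,
#'   `T` and `gmaf`.
#' @param seed Optional seed for the BAF flips.
#' @param apply_filters Apply the gmaf and position filters (default TRUE).
#' @return The filtered profile with added columns `coverage`, `major_af`,
#'   `baf` and `lrr`; zero-coverage SNPs are dropped with a warning.
#' @export
compute_baf_lrr <- function(profile, seed = NULL, apply_filters = TRUE) {
  stopifnot(all(c("chrom", "pos", "A", "C", "G", "T") %in% names(profile)))
  if (!is.null(seed)) set.seed(seed)
  if (apply_filters) {
    if (!"gmaf" %in% names(profile))
      stop("'gmaf' column required when filters are applied")
    profile <- profile[profile$gmaf >= 0.1 & profile$gmaf <= 0.2 &
                         profile$pos >= 100000, , drop = FALSE]
  }
  cnt <- as.matrix(profile[, c("A", "C", "G", "T")])
  coverage <- rowSums(cnt)
  if (any(coverage == 0)) {
    warning(sum(coverage == 0), " SNP(s) with zero coverage skipped")
    keep <- coverage > 0
    profile <- profile[keep, , drop = FALSE]
    cnt <- cnt[keep, , drop = FALSE]
    coverage <- coverage[keep]
  }
  major_af <- apply(cnt, 1, max) / coverage
  flip <- runif(nrow(profile)) < 0.5
  profile$coverage <- coverage
  profile$major_af <- major_af
  profile$baf <- ifelse(flip, 1 - major_af, major_af)
  l2 <- log2(coverage)
  profile$lrr <- l2 - median(l2)
  profile
}

# recursive binary split of one chromosome's signal on a t-like statistic
.segment_recursive <- function(values, lo, hi, min_snps, t_threshold) {
  n <- hi - lo + 1
  if (n < 2 * min_snps) return(c(lo, hi))
  x <- values[lo:hi]
  best_t <- 0; best_i <- NA
  for (i in min_snps:(n - min_snps)) {
    a <- x[1:i]; b <- x[(i + 1):n]
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) / (n - 2))
    if (!is.finite(sp)) sp <- 0
    tt <- if (sp == 0) {
      if (mean(a) != mean(b)) Inf else 0
    } else {
      abs(mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
    }
    if (tt > best_t) { best_t <- tt; best_i <- i }
  }
  if (is.na(best_i) || best_t < t_threshold) return(c(lo, hi))
  left <- .segment_recursive(values, lo, lo + best_i - 1, min_snps,
                             t_threshold)
  right <- .segment_recursive(values, lo + best_i, hi, min_snps,
                              t_threshold)
  c(left, right)
}

#' Segment a per-SNP signal into regions of constant level
#'
#' A simplified recursive change-point routine in the spirit of circular
#' binary segmentation: within each chromosome the split maximising a
#' pooled-variance t statistic is accepted when the statistic exceeds
#' `t_threshold`, then both halves are segmented recursively. Externally
#' computed segments can be passed through instead for exact reproduction
#' of a published segmentation.
#'
#' @param values Numeric signal (e.g. LRR), ordered by position within
#'   chromosome.
#' @param positions Genomic positions (must be sorted within chromosome).
#' @param chrom Chromosome label per SNP.
#' @param min_snps Minimum SNPs per segment.
#' @param t_threshold Acceptance threshold for the split statistic.
#' @param segments Optional externally supplied segment table with columns
#'   `chrom`, `start`, `end`; returned annotated, without re-segmentation.
#' @return Data frame `chrom`, `start`, `end` (1-based inclusive),
#'   `n_snps`, `mean` (mean signal in the segment).
#' @export
segment_signal <- function(values, positions, chrom, min_snps = 5,
                           t_threshold = 5, segments = NULL) {
  stopifnot(length(values) == length(positions),
            length(values) == length(chrom))
  if (!is.null(segments)) {
    segs <- segments
    segs$n_snps <- NA_integer_; segs$mean <- NA_real_
    for (i in seq_len(nrow(segs))) {
      sel <- chrom == segs$chrom[i] & positions >= segs$start[i] &
        positions <= segs$end[i]
      segs$n_snps[i] <- sum(sel)
      segs$mean[i] <- mean(values[sel])
    }
    return(segs)
  }
  out <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    pos <- positions[sel]
    if (is.unsorted(pos, strictly = FALSE))
      stop("positions are not sorted on ", ch)
    bounds <- .segment_recursive(values[sel], 1, length(sel), min_snps,
                                 t_threshold)
    bm <- matrix(bounds, ncol = 2, byrow = TRUE)
    out[[ch]] <- data.frame(
      chrom = ch, start = pos[bm[, 1]], end = pos[bm[, 2]],
      n_snps = bm[, 2] - bm[, 1] + 1L,
      mean = vapply(seq_len(nrow(bm)), function(i)
        mean(values[sel][bm[i, 1]:bm[i, 2]]), numeric(1)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exact binomial test for segment heterozygosity
#'
#' Distinguishes segments with genuine heterozygous SNPs from pure
#' loss-of-heterozygosity: SNPs with major allele frequency below
#' `het_threshold` are counted as heterozygous-looking, and a one-sided
#' exact binomial test asks whether their proportion exceeds `null_prop`
#' (the rate expected from noise alone). When heterozygosity is called, the
#' median major AF over the heterozygous SNPs summarises the segment's
#' allelic imbalance.
#'
#' @param major_af Major allele frequencies of the segment's SNPs.
#' @param het_threshold Major AF below which a SNP looks heterozygous
#'   (default 0.9).
#' @param null_prop Null heterozygous proportion (default 0.05).
#' @param alpha Significance level (default 0.05).
#' @return List with `n`, `k`, `p_value` (`P(X >= k | n, null_prop)`),
#'   `het` (`TRUE` when the null is rejected, i.e. the segment is
#'   heterozygous), and `median_het_major_af` (`NA` for LOH segments).
#' @export
test_segment_heterozygosity <- function(major_af, het_threshold = 0.9,
                                        null_prop = 0.05, alpha = 0.05) {
  n <- length(major_af)
  if (n < 1) stop("segment must contain at least one SNP")
  het_snp <- major_af < het_threshold
  k <- sum(het_snp)
  p <- binom.test(k, n, p = null_prop, alternative = "greater")$p.value
  het <- p < alpha
  list(n = n, k = k, p_value = p, het = het,
       median_het_major_af = if (het && k > 0) median(major_af[het_snp])
                             else NA_real_)
}

#' Solve sample ploidy by grid search over integer copy-number distance
#'
#' Assuming a pure sample (rho = 1), each candidate ploidy `psi` converts a
#' segment's mean LRR and major-allele balance into continuous copy
#' numbers: total = `psi * 2^LRR`, major = `mBAF * total`, minor = total -
#' major (with `mBAF = 1` for LOH segments). The ploidy minimising the
#' SNP-weighted sum of squared distances of major and minor copy numbers to
#' their nearest integers over a 0.01-step grid in [1.5, 5.5] is returned.
#'
#' @param segments Data frame with columns `n_snps`, `lrr`, `het`
#'   (logical) and `m_baf` (median heterozygous major AF; ignored for LOH
#'   segments, where 1 is used).
#' @param psi_grid Candidate ploidies (default `seq(1.5, 5.5, by = 0.01)`).
#' @param weighted Weight segments by SNP count (default TRUE).
#' @return List of class `ploidy_solution`: `psi`, `rho` (always 1),
#'   `distance`, and `grid` (data frame of psi and distance).
#' @export
solve_ploidy <- function(segments, psi_grid = seq(1.5, 5.5, by = 0.01),
                         weighted = TRUE) {
  if (is.null(segments) || nrow(segments) == 0)
    stop("no segments supplied")
  stopifnot(all(c("n_snps", "lrr", "het", "m_baf") %in% names(segments)))
  mbaf <- ifelse(segments$het, segments$m_baf, 1)
  w <- if (weighted) segments$n_snps else rep(1, nrow(segments))
  dist_of <- vapply(psi_grid, function(psi) {
    total <- psi * 2^segments$lrr
    major <- mbaf * total
    minor <- total - major
    sum(w * ((major - round(major))^2 + (minor - round(minor))^2))
  }, numeric(1))
  i <- which.min(dist_of)
  structure(list(psi = psi_grid[i], rho = 1, distance = dist_of[i],
                 grid = data.frame(psi = psi_grid, distance = dist_of)),
            class = "ploidy_solution")
}

#' @export
print.ploidy_solution <- function(x, ...) {
  cat(sprintf("ploidy solution: psi = %.2f (rho fixed at 1), distance %.4g\n",
              x$psi, x$distance))
  invisible(x)
}

#' Call copy-number status from depth ratios
#'
#' A segment's depth ratio (treated over baseline coverage) is called a
#' gain above 1.2 and a loss below 0.8; boundaries are exclusive.
#'
#' @param depth_ratio Positive numeric vector of segment depth ratios.
#' @param gain,loss Thresholds (defaults 1.2 and 0.8).
#' @return Factor with levels `loss`, `neutral`, `gain`.
#' @export
call_depth_ratio <- function(depth_ratio, gain = 1.2, loss = 0.8) {
  if (any(depth_ratio <= 0)) stop("depth ratios must be positive")
  out <- rep("neutral", length(depth_ratio))
  out[depth_ratio > gain] <- "gain"
  out[depth_ratio < loss] <- "loss"
  factor(out, levels = c("loss", "neutral", "gain"))
}
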