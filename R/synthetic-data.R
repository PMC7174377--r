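#' Default amplicon flanks for barcode reads
#'
#' The 80-bp barcode amplicon is primer + 30-bp barcode + primer. The
#' forward flank is the last 12 bases of the forward PCR primer
#' (ACTGACTGCAGTCTGAGTCTGACAG) and the reverse flank the first 12 bases of
#' the reverse complement of the reverse primer (CTAGCATAGAGTGCGTAGCTCTGCT),
#' i.e. the fixed 12-mers that bracket the barcode on the sequenced strand.
#'
#' @return List with elements `fwd` and `rev` (12-base strings).
#' @export
default_flanks <- function() {
  list(fwd = "TGAGTCTGACAG", rev = "AGCAGAGCTACG")
}

#' Define a clone for the synthetic experiment
#'
#' @param clone_id Identifier string.
#' @param phenotype One of `"DOUBLE_RESISTANT"`, `"GEF_RESISTANT"`,
#'   `"TRM_RESISTANT"`, `"DE_NOVO"`, `"SENSITIVE"`, `"UNDETERMINED"`.
#' @param initial_frequency Fraction of the POT population, in `[0, 1]`.
#' @param growth_rates Named numeric vector with entries `GEF`, `TRM`,
#'   `DMSO`: net growth rate of the clone's barcode frequencies, per week,
#'   under each condition.
#' @return A list of class `clone_definition`.
#' @export
clone_definition <- function(clone_id, phenotype, initial_frequency,
                             growth_rates) {
  phenos <- c("DOUBLE_RESISTANT", "GEF_RESISTANT", "TRM_RESISTANT",
              "DE_NOVO", "SENSITIVE", "UNDETERMINED")
  if (!phenotype %in% phenos)
    stop("unknown phenotype '", phenotype, "'")
  if (initial_frequency < 0 || initial_frequency > 1)
    stop("'initial_frequency' must be in [0, 1]")
  if (!all(c("GEF", "TRM", "DMSO") %in% names(growth_rates)))
    stop("'growth_rates' must name GEF, TRM and DMSO entries")
  g <- growth_rates["GEF"]; t <- growth_rates["TRM"]
  ok <- switch(phenotype,
    DOUBLE_RESISTANT = g > 0 && t > 0,
    GEF_RESISTANT = g > 0 && t <= 0,
    TRM_RESISTANT = t > 0 && g <= 0,
    SENSITIVE = g <= 0 && t <= 0,
    TRUE)
  if (!ok)
    stop("growth-rate signs of clone '", clone_id,
         "' are inconsistent with phenotype ", phenotype)
  structure(list(clone_id = clone_id, phenotype = phenotype,
                 initial_frequency = initial_frequency,
                 growth_rates = growth_rates),
            class = "clone_definition")
}

# Printed POT and final pooled clone frequencies of the study, used to
# derive self-consistent default growth rates: POT 2.4% / 0.91% / 0.57%
# for the gefitinib-resistant, double-resistant and trametinib-resistant
# clones; finals 32.8% / 22.4% in the gefitinib arm (4 weeks) and
# 86.1% / 4.2% in the trametinib arm (9 weeks). The small cross-arm finals
# and the sensitive remainder are chosen so each arm's finals sum to 1,
# which makes the planted rates equal the realised log-frequency slopes.
.default_freqs <- function() {
  pot <- c(gefitinib_resistant = 0.024, double_resistant = 0.0091,
           trametinib_resistant = 0.0057)
  pot <- c(pot, sensitive = 1 - sum(pot))
  gef <- c(gefitinib_resistant = 0.328, double_resistant = 0.224,
           trametinib_resistant = 0.001, sensitive = 0.447)
  trm <- c(gefitinib_resistant = 0.002, double_resistant = 0.861,
           trametinib_resistant = 0.042, sensitive = 0.095)
  list(pot = pot, gef = gef, trm = trm, gef_weeks = 4, trm_weeks = 9)
}

#' Default resistant clones of the synthetic experiment
#'
#' Three pre-existing resistant subclones at their POT frequencies (2.4%
#' gefitinib-resistant, 0.91% double-resistant, 0.57% trametinib-resistant)
#' with per-condition growth rates derived from the pooled frequencies the
#' clones reach after 4 weeks of gefitinib and 9 weeks of trametinib.
#'
#' @return List of [clone_definition()] objects.
#' @export
default_clones <- function() {
  f <- .default_freqs()
  mk <- function(id, pheno) {
    clone_definition(id, pheno, unname(f$pot[id]), c(
      GEF = unname(log(f$gef[id] / f$pot[id]) / f$gef_weeks),
      TRM = unname(log(f$trm[id] / f$pot[id]) / f$trm_weeks),
      DMSO = 0))
  }
  list(mk("gefitinib_resistant", "GEF_RESISTANT"),
       mk("double_resistant", "DOUBLE_RESISTANT"),
       mk("trametinib_resistant", "TRM_RESISTANT"))
}

#' Build a population specification for the synthetic experiment
#'
#' Combines the supplied resistant clones with a sensitive background clone
#' that fills the remaining POT frequency.
#'
#' @param clones List of [clone_definition()]s (the resistant clones).
#' @param n_lineages Number of uniquely barcoded founder cells.
#' @param barcode_length Barcode length in bases.
#' @param flank_fwd,flank_rev 12-base amplicon flanks.
#' @param ws_pattern Weak/strong pattern of the barcode.
#' @param sensitive_rates Growth rates of the sensitive background, per
#'   week, under `GEF`/`TRM`/`DMSO`.
#' @return A list of class `population_spec`.
#' @export
generate_population_spec <- function(clones = default_clones(),
                                     n_lineages = 2000,
                                     barcode_length = 30,
                                     flank_fwd = default_flanks()$fwd,
                                     flank_rev = default_flanks()$rev,
                                     ws_pattern = strrep("WS", 15),
                                     sensitive_rates = NULL) {
  stopifnot(all(vapply(clones, inherits, logical(1), "clone_definition")))
  freqs <- vapply(clones, `[[`, numeric(1), "initial_frequency")
  if (sum(freqs) > 1)
    stop("clone initial frequencies sum to more than 1")
  if (n_lineages < length(clones) + 1)
    stop("'n_lineages' must be at least the number of clones")
  if (nchar(ws_pattern) != barcode_length)
    stop("'ws_pattern' length must equal 'barcode_length'")
  if (is.null(sensitive_rates)) {
    f <- .default_freqs()
    sensitive_rates <- c(
      GEF = unname(log(f$gef["sensitive"] / f$pot["sensitive"]) / f$gef_weeks),
      TRM = unname(log(f$trm["sensitive"] / f$pot["sensitive"]) / f$trm_weeks),
      DMSO = 0)
  }
  background <- clone_definition("sensitive", "SENSITIVE",
                                 1 - sum(freqs), sensitive_rates)
  structure(list(clones = c(clones, list(background)),
                 n_lineages = as.integer(n_lineages),
                 barcode_length = as.integer(barcode_length),
                 flank_fwd = flank_fwd, flank_rev = flank_rev,
                 ws_pattern = ws_pattern),
            class = "population_spec")
}

#' Random barcodes following the weak/strong pattern
#'
#' @param n Number of distinct barcodes.
#' @param pattern Weak/strong pattern string.
#' @return Character vector of `n` unique sequences.
#' @export
random_barcodes <- function(n, pattern = strrep("WS", 15)) {
  pat <- strsplit(pattern, "")[[1]]
  draw <- function(m) {
    mat <- vapply(pat, function(sym) {
      sample(if (sym == "W") c("A", "T") else c("G", "C"), m, replace = TRUE)
    }, character(m))
    if (m == 1) paste(mat, collapse = "") else
      apply(mat, 1, paste, collapse = "")
  }
  bc <- draw(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

#' Design parameters of the synthetic experiment
#'
#' Defaults mirror the study conditions at a computationally scaled lineage
#' count: replicate flasks seeded with 12 million cells, barcode sequencing
#' at 3e5 reads per sample (the lower end of the study's 300,000-600,000x
#' depth), 4 weeks of gefitinib in GEF1-3 and 9 weeks of trametinib in
#' TRM4-6, with weekly floating (dead-cell) samples per drug replicate.
#'
#' @param b,d Birth/death rates per cell per hour for the POT outgrowth.
#' @param t_grow POT outgrowth duration, hours.
#' @param seed_cells Cells seeded per replicate flask.
#' @param sampling_depth Reads sampled per census.
#' @param gef_weeks,trm_weeks Drug exposure durations, weeks.
#' @param n_gef,n_trm Numbers of drug-treated replicates.
#' @param death_weight_resistant Relative contribution of a drug-resistant
#'   clone to the floating (dying) compartment while under that drug, on a
#'   scale where drug-sensitive clones contribute weight 1.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(b = 0.032, d = 0.002, t_grow = 173,
                              seed_cells = 12e6, sampling_depth = 3e5,
                              gef_weeks = 4, trm_weeks = 9,
                              n_gef = 3, n_trm = 3,
                              death_weight_resistant = 0.3) {
  structure(list(b = b, d = d, t_grow = t_grow, seed_cells = seed_cells,
                 sampling_depth = sampling_depth, gef_weeks = gef_weeks,
                 trm_weeks = trm_weeks, n_gef = n_gef, n_trm = n_trm,
                 death_weight_resistant = death_weight_resistant),
            class = "experiment_design")
}

#' Simulate the full barcoded evolution experiment
#'
#' Generates a POT census by per-lineage Gillespie birth-death outgrowth,
#' seeds two DMSO control replicates and the drug-treated replicates by
#' multinomial sampling of the POT (drift only), evolves each drug
#' replicate's barcode frequencies along its clone's exponential
#' expectation, samples sequencing-depth multinomial censuses at harvest,
#' and routes dying cells into weekly floating censuses.
#'
#' @param spec A [generate_population_spec()].
#' @param design An [experiment_design()].
#' @param seed Integer seed; fixed seed makes the dataset reproducible.
#' @return A list of class `experiment_dataset` with `censuses` (named list
#'   of [barcode_census()]: `POT`, `DMSO7`, `DMSO8`, `GEF1`-`GEF3`,
#'   `TRM4`-`TRM6`, plus weekly floating samples `GEF1_F1`, ...), `truth`
#'   (per-barcode clone, phenotype and planted growth rates), `spec` and
#'   `design`.
#' @export
simulate_experiment <- function(spec = generate_population_spec(),
                                design = experiment_design(),
                                seed = NULL) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(design, "experiment_design"))
  if (!is.null(seed)) set.seed(seed)

  clones <- spec$clones
  freqs <- vapply(clones, `[[`, numeric(1), "initial_frequency")
  ids <- vapply(clones, `[[`, character(1), "clone_id")
  # lineage allocation proportional to clone frequency, >= 1 per clone
  n_per <- pmax(1L, round(freqs * spec$n_lineages))
  n_per[length(n_per)] <- spec$n_lineages - sum(n_per[-length(n_per)])
  clone_of <- rep.int(seq_along(clones), n_per)

  barcodes <- random_barcodes(spec$n_lineages, spec$ws_pattern)

  # POT outgrowth: per-lineage birth-death; extinct lineages drop out
  w <- bd_final_sizes_cpp(spec$n_lineages, design$b, design$d,
                          design$t_grow, 1L)
  keep <- w > 0L
  if (!any(keep)) stop("all lineages went extinct in the POT outgrowth")
  barcodes <- barcodes[keep]; clone_of <- clone_of[keep]; w <- w[keep]
  # within-clone weights scaled to the clone's POT frequency
  pot_freq <- numeric(length(w))
  for (ci in seq_along(clones)) {
    sel <- clone_of == ci
    if (!any(sel)) stop("clone '", ids[ci], "' lost all lineages")
    pot_freq[sel] <- freqs[ci] * w[sel] / sum(w[sel])
  }
  pot_freq <- pot_freq / sum(pot_freq)
  names(pot_freq) <- barcodes

  r_gef <- vapply(clones, function(cl) unname(cl$growth_rates["GEF"]),
                  numeric(1))[clone_of]
  r_trm <- vapply(clones, function(cl) unname(cl$growth_rates["TRM"]),
                  numeric(1))[clone_of]

  depth <- design$sampling_depth
  sample_census <- function(f, sample_id, condition, timepoint = NA,
                            compartment = "attached") {
    counts <- as.integer(rmultinom(1, depth, f))
    names(counts) <- names(f)
    counts <- counts[counts > 0]
    cen <- barcode_census(counts, sample_id, condition, timepoint,
                          compartment)
    # pre-sampling frequencies, so read emission does not sample twice
    attr(cen, "true_frequencies") <- f
    cen
  }
  seeded_freq <- function() {
    s <- as.numeric(rmultinom(1, design$seed_cells, pot_freq))
    setNames(s / sum(s), names(pot_freq))
  }

  censuses <- list(POT = sample_census(pot_freq, "POT", "POT", 0))
  censuses$DMSO7 <- sample_census(seeded_freq(), "DMSO7", "DMSO")
  censuses$DMSO8 <- sample_census(seeded_freq(), "DMSO8", "DMSO")

  drug_replicate <- function(sample_id, condition, r, weeks) {
    f0 <- seeded_freq()
    out <- list()
    death_w <- ifelse(r > 0, design$death_weight_resistant, 1)
    for (wk in seq_len(weeks)) {
      fl <- f0 * exp(r * (wk - 0.5)) * death_w
      out[[paste0(sample_id, "_F", wk)]] <-
        sample_census(fl / sum(fl), paste0(sample_id, "_F", wk),
                      condition, wk, "floating")
    }
    fT <- f0 * exp(r * weeks)
    out[[sample_id]] <- sample_census(fT / sum(fT), sample_id, condition,
                                      weeks, "attached")
    out
  }
  for (i in seq_len(design$n_gef)) {
    censuses <- c(censuses,
                  drug_replicate(paste0("GEF", i), "GEF", r_gef,
                                 design$gef_weeks))
  }
  for (i in seq_len(design$n_trm)) {
    censuses <- c(censuses,
                  drug_replicate(paste0("TRM", i + design$n_gef), "TRM",
                                 r_trm, design$trm_weeks))
  }

  truth <- data.frame(barcode = barcodes,
                      clone_id = ids[clone_of],
                      phenotype = vapply(clones, `[[`, character(1),
                                         "phenotype")[clone_of],
                      r_gef = r_gef, r_trm = r_trm,
                      pot_frequency = unname(pot_freq),
                      stringsAsFactors = FALSE)

  structure(list(censuses = censuses, truth = truth, spec = spec,
                 design = design),
            class = "experiment_dataset")
}

#' Emit FASTQ amplicon reads from a barcode census
#'
#' Draws `depth` reads multinomially from the census frequencies, builds
#' each read as forward flank + barcode + reverse flank, applies per-base
#' substitution errors at `error_rate`, and assigns Phred+33 qualities so
#' that a configurable fraction of reads fails the strict everywhere-above-
#' Q20 filter (failing reads carry exactly one base at Q = 20, the boundary
#' of the filter; all other bases are Q = 37).
#'
#' @param census A [barcode_census()].
#' @param path Output FASTQ path.
#' @param depth Number of reads to emit.
#' @param error_rate Per-base substitution probability, in `[0, 0.1]`.
#' @param fail_q_fraction Fraction of reads that should fail the Q>20
#'   filter.
#' @param flank_fwd,flank_rev 12-base flanks.
#' @param seed Optional integer seed.
#' @return Invisibly, a list with `path`, `n_reads`, `n_error_reads` and
#'   `n_qfail_reads`.
#' @export
emit_barcode_reads <- function(census, path, depth = 3e5, error_rate = 1e-3,
                               fail_q_fraction = 0.01,
                               flank_fwd = default_flanks()$fwd,
                               flank_rev = default_flanks()$rev,
                               seed = NULL) {
  stopifnot(inherits(census, "barcode_census"))
  if (error_rate < 0 || error_rate > 0.1)
    stop("'error_rate' must be in [0, 0.1]")
  if (!is.null(seed)) set.seed(seed)
  if (depth == 0) {
    warning("zero depth requested: writing an empty FASTQ")
    file.create(path)
    return(invisible(list(path = path, n_reads = 0L, n_error_reads = 0L,
                          n_qfail_reads = 0L)))
  }
  f <- census$frequencies
  if (is.null(f)) f <- census_to_frequencies(census)$frequencies
  nb <- as.integer(rmultinom(1, depth, f))
  templates <- paste0(flank_fwd, names(f), flank_rev)
  reads <- rep.int(templates, nb)
  L <- nchar(reads[1])
  n <- length(reads)

  n_err_per_read <- rbinom(n, L, error_rate)
  err_idx <- which(n_err_per_read > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in err_idx) {
    pos <- sample.int(L, n_err_per_read[i])
    s <- reads[i]
    for (p in pos) {
      orig <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(bases, orig), 1)
    }
    reads[i] <- s
  }

  q_high <- strrep(rawToChar(as.raw(33L + 37L)), L)
  quals <- rep.int(q_high, n)
  n_fail <- rbinom(1, n, fail_q_fraction)
  if (n_fail > 0) {
    fail_idx <- sample.int(n, n_fail)
    pos <- sample.int(L, n_fail, replace = TRUE)
    q20 <- rawToChar(as.raw(33L + 20L))
    for (j in seq_len(n_fail)) {
      i <- fail_idx[j]
      substr(quals[i], pos[j], pos[j]) <- q20
    }
  }

  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- paste0("read", seq_len(n))
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(list(path = path, n_reads = n, n_error_reads = length(err_idx),
                 n_qfail_reads = n_fail))
}

#' Generate per-SNP allele counts for a genome with known copy numbers
#'
#' For each segment with integer major/minor copy numbers, SNP coverage is
#' Poisson with mean proportional to total copy number over true ploidy,
#' and the major-allele count is binomial with success probability
#' major / (major + minor). LOH segments (minor = 0) therefore produce
#' homozygous-looking SNPs.
#'
#' @param cn_segments List of `c(major, minor)` integer pairs (or a
#'   two-column matrix), one per segment.
#' @param n_snps SNPs per segment (recycled).
#' @param depth Mean coverage of a segment whose total copy number equals
#'   the true ploidy.
#' @param psi_true True sample ploidy, in `[1.5, 5.5]`.
#' @param chrom Chromosome label per segment (recycled; default all
#'   `"chr1"`, giving multi-segment chromosomes for segmentation tests).
#' @param seed Optional integer seed.
#' @return Data frame with columns `chrom`, `pos`, `A`, `C`, `G`, `T`,
#'   `gmaf` and `segment` (true segment index), plus attributes
#'   `truth` (segment table with true copy numbers) and `psi_true`.
#' @export
generate_snp_dataset <- function(cn_segments, n_snps = 200, depth = 80,
                                 psi_true = 3, chrom = "chr1", seed = NULL) {
  if (is.matrix(cn_segments))
    cn_segments <- split(cn_segments, seq_len(nrow(cn_segments)))
  ns <- length(cn_segments)
  if (psi_true < 1.5 || psi_true > 5.5)
    stop("'psi_true' must lie in [1.5, 5.5]")
  n_snps <- rep_len(n_snps, ns)
  chrom <- rep_len(chrom, ns)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", ns)
  truth <- vector("list", ns)
  pos_next <- setNames(rep(100000, length(unique(chrom))), unique(chrom))
  bases <- c("A", "C", "G", "T")
  for (s in seq_len(ns)) {
    cn <- as.integer(cn_segments[[s]])
    if (length(cn) != 2 || any(cn < 0) || cn[1] < cn[2])
      stop("each segment needs integer copy numbers c(major, minor) with ",
           "major >= minor >= 0")
    tot <- sum(cn)
    if (tot == 0) stop("segment ", s, " has total copy number 0")
    m <- n_snps[s]
    pos <- pos_next[chrom[s]] + seq_len(m) * 5000
    pos_next[chrom[s]] <- pos[m]
    cov <- rpois(m, depth * tot / psi_true)
    cov <- pmax(cov, 1L)
    major_n <- rbinom(m, cov, cn[1] / tot)
    cnt <- matrix(0L, m, 4, dimnames = list(NULL, bases))
    ab <- t(vapply(seq_len(m), function(i) sample.int(4, 2), integer(2)))
    cnt[cbind(seq_len(m), ab[, 1])] <- major_n
    cnt[cbind(seq_len(m), ab[, 2])] <- cov - major_n
    rows[[s]] <- data.frame(chrom = chrom[s], pos = pos,
                            A = cnt[, 1], C = cnt[, 2], G = cnt[, 3],
                            T = cnt[, 4], gmaf = runif(m, 0.1, 0.2),
                            segment = s)
    truth[[s]] <- data.frame(segment = s, chrom = chrom[s],
                             start = pos[1], end = pos[m],
                             major = cn[1], minor = cn[2])
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "psi_true") <- psi_true
  out
}

#' Generate drug-screen plate readings with known inhibition effects
#'
#' Each plate carries 14 drug-free positive-control wells (cells, no drug),
#' 14 empty negative-control wells, and one well per compound with
#' intensity `cneg + (1 - inhibition) * (cpos - cneg) + noise`.
#'
#' @param effects Data frame with columns `compound`, `concentration` and
#'   `inhibition` (true fractional inhibition in `[0, 1]`).
#' @param n_replicates Replicate plates per concentration.
#' @param noise_sd Gaussian noise SD on intensities.
#' @param cpos_mean,cneg_mean Control intensity levels.
#' @param n_pos,n_neg Numbers of control wells per plate.
#' @param plate_prefix Prefix for plate identifiers.
#' @param seed Optional integer seed.
#' @return Data frame of wells: `plate_id`, `well`, `role`, `compound`,
#'   `conc_nM`, `replicate`, `intensity`.
#' @export
generate_screen_plates <- function(effects, n_replicates = 3, noise_sd = 0,
                                   cpos_mean = 10000, cneg_mean = 2000,
                                   n_pos = 14, n_neg = 14,
                                   plate_prefix = "P", seed = NULL) {
  stopifnot(all(c("compound", "concentration", "inhibition") %in%
                  names(effects)))
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (conc in unique(effects$concentration)) {
    eff <- effects[effects$concentration == conc, ]
    for (r in seq_len(n_replicates)) {
      plate_id <- paste0(plate_prefix, "_c", conc, "_r", r)
      nw <- nrow(eff)
      ctrl <- data.frame(
        plate_id = plate_id,
        well = c(paste0("POS", seq_len(n_pos)), paste0("NEG", seq_len(n_neg))),
        role = rep(c("positive_control", "empty"), c(n_pos, n_neg)),
        compound = NA_character_, conc_nM = NA_real_, replicate = r,
        intensity = c(cpos_mean + rnorm(n_pos, 0, noise_sd),
                      cneg_mean + rnorm(n_neg, 0, noise_sd)))
      cmpd <- data.frame(
        plate_id = plate_id, well = paste0("W", seq_len(nw)),
        role = "compound", compound = eff$compound, conc_nM = conc,
        replicate = r,
        intensity = cneg_mean + (1 - eff$inhibition) *
          (cpos_mean - cneg_mean) + rnorm(nw, 0, noise_sd))
      out[[plate_id]] <- rbind(ctrl, cmpd)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
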