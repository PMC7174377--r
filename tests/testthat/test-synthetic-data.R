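test_that("population spec defaults carry the pre-existing resistant clones", {
  spec <- generate_population_spec()
  freqs <- vapply(spec$clones, `[[`, numeric(1), "initial_frequency")
  phenos <- vapply(spec$clones, `[[`, character(1), "phenotype")
  resistant_sum <- sum(freqs[phenos != "SENSITIVE"])
  expect_equal(resistant_sum, 0.039, tolerance = 0.03)  # prints as 3.9%
  expect_equal(sum(freqs), 1)
  # no resistant clones: pure sensitive background
  s0 <- generate_population_spec(clones = list())
  expect_equal(s0$clones[[1]]$initial_frequency, 1)
  # over-allocated frequencies rejected
  big <- lapply(1:2, function(i)
    clone_definition(paste0("c", i), "GEF_RESISTANT", 0.6,
                     c(GEF = 1, TRM = -1, DMSO = 0)))
  expect_error(generate_population_spec(clones = big), "sum")
  # phenotype / growth-rate sign consistency enforced
  expect_error(clone_definition("bad", "DOUBLE_RESISTANT", 0.01,
                                c(GEF = 1, TRM = -1, DMSO = 0)),
               "inconsistent")
})

test_that("simulated experiment is deterministic and its censuses normalised", {
  a <- simulate_experiment(generate_population_spec(n_lineages = 400),
                           experiment_design(sampling_depth = 2e4),
                           seed = 11)
  b <- simulate_experiment(generate_population_spec(n_lineages = 400),
                           experiment_design(sampling_depth = 2e4),
                           seed = 11)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$censuses, `[[`, "counts"),
                   lapply(b$censuses, `[[`, "counts"))
  for (cen in a$censuses) {
    expect_equal(sum(cen$frequencies), 1, tolerance = 1e-9)
  }
  # expected samples exist: 2 DMSO, 3+3 drug finals, weekly floating
  nm <- names(a$censuses)
  expect_true(all(c("POT", "DMSO7", "DMSO8", "GEF1", "TRM4") %in% nm))
  expect_length(grep("^GEF[0-9]+_F", nm), 3 * 4)
  expect_length(grep("^TRM[0-9]+_F", nm), 3 * 9)
})

test_that("selection moves clone frequencies in the planted directions", {
  ds <- simulate_experiment(seed = 12)
  truth <- ds$truth
  pooled <- function(census, barcodes) {
    f <- census$frequencies
    sum(f[names(f) %in% barcodes])
  }
  gefr <- truth$barcode[truth$clone_id == "gefitinib_resistant"]
  pot_f <- pooled(ds$censuses$POT, gefr)
  for (r in c("GEF1", "GEF2", "GEF3")) {
    expect_gt(pooled(ds$censuses[[r]], gefr), pot_f)
  }
  for (r in c("TRM4", "TRM5", "TRM6")) {
    expect_lt(pooled(ds$censuses[[r]], gefr), pot_f)
  }
  # final floating sample mirrors the harvested attached census
  for (r in c("GEF1", "TRM4")) {
    at <- ds$censuses[[r]]
    fl <- ds$censuses[[paste0(r, "_F", at$timepoint)]]
    expect_identical(names(which.max(at$frequencies)),
                     names(which.max(fl$frequencies)))
    expect_gt(census_similarity(at, fl), 0.8)
  }
})

test_that("read emission conserves depth and follows the error model", {
  cen <- barcode_census(c(TGTGTGTGTGTGTGTGTGTGTGTGTGTGTG = 100),
                        "S1", "POT")
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq))
  # error-free emission of a single barcode: identical reads
  emit_barcode_reads(cen, fq, depth = 500, error_rate = 0,
                     fail_q_fraction = 0, seed = 21)
  lines <- readLines(fq)
  seqs <- lines[seq(2, length(lines), by = 4)]
  expect_length(seqs, 500)
  expect_length(unique(seqs), 1)
  expect_identical(substr(seqs[1], 13, 42), names(cen$counts))
  # error fraction in the barcode region ~ 1 - (1 - e)^30
  emit_barcode_reads(cen, fq, depth = 30000, error_rate = 0.001,
                     fail_q_fraction = 0, seed = 22)
  raw <- read_and_filter_fastq(fq)
  extracted <- sum(raw)
  wrong <- sum(raw[names(raw) != names(cen$counts)])
  p_expect <- 1 - (1 - 0.001)^30
  se <- sqrt(p_expect * (1 - p_expect) / extracted)
  expect_lt(abs(wrong / extracted - p_expect), 4 * se)
  # requested fraction of reads fails the strict Q>20 filter
  emit_barcode_reads(cen, fq, depth = 5000, error_rate = 0,
                     fail_q_fraction = 0.2, seed = 23)
  kept <- sum(read_and_filter_fastq(fq))
  expect_lt(abs(kept / 5000 - 0.8), 4 * sqrt(0.2 * 0.8 / 5000))
  expect_warning(emit_barcode_reads(cen, fq, depth = 0), "empty")
})

test_that("SNP generator reproduces the allele model of known copy numbers", {
  snp <- generate_snp_dataset(list(c(1, 1), c(2, 0)), n_snps = 400,
                              depth = 5000, psi_true = 2, seed = 31)
  prof <- compute_baf_lrr(snp, seed = 32)
  het <- prof[prof$segment == 1, ]
  loh <- prof[prof$segment == 2, ]
  # (1,1): major AF -> 0.5 at deep coverage (max/cov has a small + bias)
  expect_equal(mean(het$major_af), 0.5, tolerance = 0.02)
  # (2,0): homozygous-looking
  expect_true(all(loh$major_af > 0.99))
  expect_error(generate_snp_dataset(list(c(0, 0))), "copy number 0")
})

test_that("screen plate generator places controls and effects as designed", {
  eff <- expand.grid(compound = paste0("cmp", 1:485),
                     concentration = c(20, 200, 800))
  eff$inhibition <- 0
  plates <- generate_screen_plates(eff, n_replicates = 3, noise_sd = 0)
  expect_equal(sum(plates$role == "compound"), 485 * 3 * 3)
  expect_equal(sum(plates$role == "positive_control"), 14 * 9)
  expect_equal(sum(plates$role == "empty"), 14 * 9)
  one <- plates[plates$plate_id == plates$plate_id[1], ]
  cpos <- mean(one$intensity[one$role == "positive_control"])
  expect_true(all(one$intensity[one$role == "compound"] == cpos))
  # full inhibition lands on the negative control level
  eff$inhibition <- 1
  p2 <- generate_screen_plates(eff[eff$concentration == 20, ],
                               n_replicates = 1, noise_sd = 0)
  cneg <- mean(p2$intensity[p2$role == "empty"])
  expect_true(all(p2$intensity[p2$role == "compound"] == cneg))
})
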