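test_that("baseline frequency is the conservative DMSO maximum", {
  expect_equal(baseline_frequency(0.01, 0.02), 0.02)
  expect_equal(baseline_frequency(0.005, 0.005), 0.005)
  expect_equal(baseline_frequency(0.003, 0), 0.003)
  expect_true(is.na(baseline_frequency(0, 0)))
  expect_true(is.na(baseline_frequency(NA, NA)))
  expect_equal(baseline_frequency(c(0.1, 0), c(0.2, 0.3)), c(0.2, 0.3))
})

test_that("growth rate reproduces the study's printed clone dynamics", {
  expect_equal(growth_rate(0.01, 0.01, 4), 0)
  # double-resistant clone: 0.91% in POT, 86.1% after 9 weeks trametinib
  expect_equal(growth_rate(0.861, 0.0091, 9), log(0.861 / 0.0091) / 9)
  expect_equal(growth_rate(0.861, 0.0091, 9), 0.505, tolerance = 2e-3)
  # gefitinib-resistant clone: 2.4% in POT, 32.8% after 4 weeks gefitinib
  expect_equal(growth_rate(0.328, 0.024, 4), 0.654, tolerance = 1e-3)
  expect_identical(growth_rate(0, 0.01, 4), -Inf)
  expect_true(is.na(growth_rate(0.1, NA, 4)))
  expect_error(growth_rate(0.1, 0.01, 0), "positive")
})

test_that("growth rate is antisymmetric, scale-invariant, and conservative", {
  set.seed(41)
  for (i in 1:20) {
    f0 <- runif(1, 1e-4, 0.5); fR <- runif(1, 1e-4, 0.5)
    T_wk <- sample(c(4, 9), 1); c_scale <- runif(1, 0.1, 10)
    expect_equal(growth_rate(fR, f0, T_wk), -growth_rate(f0, fR, T_wk))
    expect_equal(growth_rate(fR * c_scale, f0 * c_scale, T_wk),
                 growth_rate(fR, f0, T_wk))
    # Max-based baseline never exceeds the Min-based growth rate
    g <- runif(1, 1e-4, 0.5)
    expect_lte(growth_rate(fR, max(f0, g), T_wk),
               growth_rate(fR, min(f0, g), T_wk))
  }
})

test_that("phenotype rules follow the replicate positivity logic", {
  arms <- c("GEF", "GEF", "GEF", "TRM", "TRM", "TRM")
  r <- function(...) matrix(c(...), nrow = 1)
  expect_equal(assign_phenotypes(r(1, -1, -1, 1, -1, -1), arms),
               "DOUBLE_RESISTANT")
  expect_equal(assign_phenotypes(r(0.5, 0.2, -1, -1, -2, -Inf), arms),
               "GEF_RESISTANT")
  expect_equal(assign_phenotypes(r(-1, -1, -1, 0.3, 0.2, -1), arms),
               "TRM_RESISTANT")
  expect_equal(assign_phenotypes(r(-1, -1, -1, 0.3, -1, -1), arms),
               "DE_NOVO")
  expect_equal(assign_phenotypes(r(0.4, -1, -1, -1, -1, -1), arms),
               "DE_NOVO")
  expect_equal(assign_phenotypes(r(-1, -1, -1, -1, -Inf, -1), arms),
               "SENSITIVE")
  expect_equal(assign_phenotypes(r(NA, NA, NA, NA, NA, NA), arms),
               "UNDETERMINED")
  expect_error(assign_phenotypes(r(1, 1, 1, 1, 1, 1),
                                 c("GEF", "GEF", "GEF", "TRM", "TRM", "X")),
               "unknown replicate label")
  # every barcode gets exactly one class (partition property)
  set.seed(42)
  m <- matrix(rnorm(600), ncol = 6)
  ph <- assign_phenotypes(m, arms)
  expect_length(ph, 100)
  expect_true(all(ph %in% c("DOUBLE_RESISTANT", "GEF_RESISTANT",
                            "TRM_RESISTANT", "DE_NOVO", "SENSITIVE",
                            "UNDETERMINED")))
})

test_that("phenotype proportions partition the barcode set", {
  rec <- data.frame(barcode = c("b1", "b2", "b3", "b4"),
                    phenotype = c("SENSITIVE", "SENSITIVE",
                                  "GEF_RESISTANT", "DE_NOVO"))
  pp <- phenotype_proportions(rec)
  expect_equal(sum(pp$proportions), 1)
  expect_equal(unname(pp$proportions["SENSITIVE"]), 0.5)
  all_sens <- data.frame(barcode = "b", phenotype = "SENSITIVE")
  expect_equal(unname(phenotype_proportions(all_sens)$proportions),
               c(0, 0, 0, 0, 1, 0))
})

test_that("floating trajectories and similarity capture the selective sweep", {
  ds <- simulate_experiment(generate_population_spec(n_lineages = 600),
                            experiment_design(sampling_depth = 1e5),
                            seed = 44)
  tr <- floating_trajectories(ds$censuses)
  expect_true(all(c("replicate", "week", "barcode", "frequency") %in%
                    names(tr)))
  # resistant barcodes rise monotonically in pooled floating frequency
  res_bc <- ds$truth$barcode[ds$truth$phenotype == "DOUBLE_RESISTANT"]
  w <- tr[tr$replicate == "TRM4", ]
  pooled <- tapply(w$frequency * (w$barcode %in% res_bc), w$week, sum)
  expect_true(all(diff(pooled) > 0))
  # no floating censuses -> empty table, no error
  empty <- floating_trajectories(ds$censuses["POT"])
  expect_equal(nrow(empty), 0)
})

test_that("end-to-end inference recovers planted phenotypes and rates", {
  ds <- simulate_experiment(seed = 45)
  rec <- infer_growth(ds$censuses)
  m <- match(rec$barcode, ds$truth$barcode)
  known <- !is.na(m) & !is.na(rec$f0) & rec$f0 >= 1e-4
  agree <- mean(ds$truth$phenotype[m[known]] == rec$phenotype[known])
  expect_gte(agree, 0.95)
  # subclone grouping puts same-clone barcodes together on clean rates
  sub <- functional_subclones(rec, h = 0.3)
  dbl <- rec$barcode %in%
    ds$truth$barcode[ds$truth$phenotype == "DOUBLE_RESISTANT"]
  grp <- sub[dbl & !is.na(sub)]
  if (length(grp) > 2) {
    expect_equal(length(unique(grp)), 1)
  }
})

test_that("log-linear fitting recovers exponential growth rates", {
  t <- 0:10
  # suppressed: summary.lm warns about the deliberately exact fit
  fit <- suppressWarnings(fit_log_linear_growth(t, exp(0.2 * t)))
  expect_equal(fit$rate, 0.2, tolerance = 1e-10)
  expect_equal(suppressWarnings(fit_log_linear_growth(t, rep(3, 11)))$rate, 0)
  set.seed(46)
  tt <- seq(0, 8, length.out = 50)
  noisy <- exp(0.35 * tt + rnorm(50, 0, 0.1))
  nf <- fit_log_linear_growth(tt, noisy)
  expect_lt(abs(nf$rate - 0.35), 3 * nf$se)
  expect_error(fit_log_linear_growth(tt, c(-1, noisy[-1])), "positive")
  expect_error(fit_log_linear_growth(0:1, c(1, 2)), "3 points")
})
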