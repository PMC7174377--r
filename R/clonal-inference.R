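#' Conservative baseline frequency of a barcode
#'
#' The DMSO replicates stand in for the pre-drug frequency of each barcode.
#' Taking the maximum of the two DMSO frequencies gives a conservative
#' (never inflated) growth-rate estimate downstream. A barcode absent from
#' both DMSO samples has no defined baseline and is returned as `NA`
#' (mapped to the UNDETERMINED phenotype downstream).
#'
#' @param fD7,fD8 Frequencies in DMSO7 and DMSO8 (0 or `NA` when absent).
#' @return `pmax(fD7, fD8)`, with `NA` where the barcode is absent from
#'   both.
#' @export
baseline_frequency <- function(fD7, fD8) {
  fD7[is.na(fD7)] <- 0
  fD8[is.na(fD8)] <- 0
  f0 <- pmax(fD7, fD8)
  f0[f0 == 0] <- NA_real_
  f0
}

#' Per-week growth rate of a barcode from frequency change
#'
#' `r = (1/T) * log(fR / f0)` with natural logarithm, where `fR` is the
#' barcode frequency after `T` weeks of drug exposure and `f0` the baseline
#' frequency. A barcode that disappeared (`fR = 0`) gets `r = -Inf`, a
#' definite negative rate for the phenotype rules. An undefined baseline
#' (`f0` zero or `NA`) yields `NA`.
#'
#' @param fR Final frequency (>= 0).
#' @param f0 Baseline frequency (> 0 for a defined rate).
#' @param T_weeks Time between drug exposure and harvest, weeks (4 for
#'   gefitinib, 9 for trametinib in the study design).
#' @return Growth rate per week (vectorised).
#' @export
growth_rate <- function(fR, f0, T_weeks) {
  if (any(T_weeks <= 0)) stop("'T_weeks' must be positive")
  if (any(fR < 0, na.rm = TRUE)) stop("'fR' must be non-negative")
  r <- log(fR / f0) / T_weeks
  r[is.na(f0) | f0 <= 0] <- NA_real_
  r
}

#' Assign resistance phenotypes from per-replicate growth-rate signs
#'
#' Rules, applied in order, based on the replicates where the barcode shows
#' a strictly positive growth rate:
#' 1. positive in at least one GEF and at least one TRM replicate:
#'    `DOUBLE_RESISTANT`;
#' 2. positive in two or more GEF replicates and no TRM replicate:
#'    `GEF_RESISTANT`;
#' 3. positive in two or more TRM replicates and no GEF replicate:
#'    `TRM_RESISTANT`;
#' 4. positive in exactly one replicate overall: `DE_NOVO` (putative de
#'    novo resistance);
#' 5. any other barcode with measured rates: `SENSITIVE`;
#' 6. no measurable rate (absent from both DMSO controls): `UNDETERMINED`.
#'
#' `-Inf` rates (extinct in a replicate) are simply non-positive; `NA`
#' rates (barcode undetected in that replicate's census while the baseline
#' exists) are also treated as non-positive evidence.
#'
#' @param rates Matrix or data frame of growth rates, barcodes in rows,
#'   replicates in columns.
#' @param arms Character vector labelling each column `"GEF"` or `"TRM"`.
#' @return Character vector of phenotypes, one per row.
#' @export
assign_phenotypes <- function(rates, arms) {
  rates <- as.matrix(rates)
  if (length(arms) != ncol(rates))
    stop("'arms' must label every replicate column")
  if (!all(arms %in% c("GEF", "TRM")))
    stop("unknown replicate label: arms must be 'GEF' or 'TRM'")
  pos <- !is.na(rates) & rates > 0
  measured <- rowSums(!is.na(rates)) > 0
  n_gef <- rowSums(pos[, arms == "GEF", drop = FALSE])
  n_trm <- rowSums(pos[, arms == "TRM", drop = FALSE])
  out <- rep("SENSITIVE", nrow(rates))
  out[n_gef >= 1 & n_trm >= 1] <- "DOUBLE_RESISTANT"
  out[n_gef >= 2 & n_trm == 0] <- "GEF_RESISTANT"
  out[n_trm >= 2 & n_gef == 0] <- "TRM_RESISTANT"
  out[(n_gef + n_trm) == 1] <- "DE_NOVO"
  out[!measured] <- "UNDETERMINED"
  out
}

#' Infer growth records from an experiment's censuses
#'
#' Builds the per-barcode growth table: baseline frequency from the two
#' DMSO censuses, per-replicate growth rate from each drug-treated census,
#' and the assigned phenotype.
#'
#' @param censuses Named list of [barcode_census()] objects including
#'   `DMSO7`, `DMSO8` and the attached final censuses of the drug
#'   replicates (conditions `GEF`/`TRM`).
#' @param gef_weeks,trm_weeks Drug exposure times in weeks.
#' @return A data frame of class `growth_records`: `barcode`, `f0`, one
#'   `r_<replicate>` column per drug replicate, and `phenotype`; the arm of
#'   each rate column is stored in `attr(, "arms")`.
#' @export
infer_growth <- function(censuses, gef_weeks = 4, trm_weeks = 9) {
  if (!all(c("DMSO7", "DMSO8") %in% names(censuses)))
    stop("censuses must include DMSO7 and DMSO8")
  finals <- censuses[vapply(censuses, function(x)
    x$condition %in% c("GEF", "TRM") && x$compartment == "attached",
    logical(1))]
  if (!length(finals)) stop("no drug-treated attached censuses found")
  barcodes <- sort(unique(c(
    unlist(lapply(censuses[c("DMSO7", "DMSO8")],
                  function(x) names(x$counts)), use.names = FALSE),
    unlist(lapply(finals, function(x) names(x$counts)),
           use.names = FALSE))))
  freq_of <- function(census) {
    f <- census$frequencies
    out <- setNames(numeric(length(barcodes)), barcodes)
    out[names(f)] <- f
    out
  }
  f0 <- baseline_frequency(freq_of(censuses$DMSO7), freq_of(censuses$DMSO8))
  arms <- vapply(finals, `[[`, character(1), "condition")
  rmat <- vapply(seq_along(finals), function(i) {
    T_wk <- if (arms[i] == "GEF") gef_weeks else trm_weeks
    growth_rate(freq_of(finals[[i]]), f0, T_wk)
  }, numeric(length(barcodes)))
  colnames(rmat) <- names(finals)
  phenotype <- assign_phenotypes(rmat, arms)
  out <- data.frame(barcode = barcodes, f0 = unname(f0),
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(rmat))) out[[paste0("r_", colnames(rmat)[j])]] <-
    unname(rmat[, j])
  out$phenotype <- phenotype
  attr(out, "arms") <- unname(arms)
  class(out) <- c("growth_records", "data.frame")
  out
}

#' Phenotype proportions and pooled frequencies
#'
#' @param records A `growth_records` table from [infer_growth()].
#' @param censuses Optional named list of censuses; when given, the pooled
#'   frequency of each phenotype class in each census is reported.
#' @return A list with `proportions` (unique-barcode proportion per
#'   phenotype class, summing to 1) and, when censuses are supplied,
#'   `pooled_frequency` (class-by-sample matrix of summed frequencies).
#' @export
phenotype_proportions <- function(records, censuses = NULL) {
  classes <- c("DOUBLE_RESISTANT", "GEF_RESISTANT", "TRM_RESISTANT",
               "DE_NOVO", "SENSITIVE", "UNDETERMINED")
  tab <- table(factor(records$phenotype, levels = classes))
  props <- as.numeric(tab) / nrow(records)
  names(props) <- classes
  out <- list(proportions = props)
  if (!is.null(censuses)) {
    pooled <- vapply(censuses, function(census) {
      f <- census$frequencies
      cls <- records$phenotype[match(names(f), records$barcode)]
      vapply(classes, function(k) sum(f[!is.na(cls) & cls == k]),
             numeric(1))
    }, numeric(length(classes)))
    rownames(pooled) <- classes
    out$pooled_frequency <- pooled
  }
  out
}

#' Tidy time series of floating barcode frequencies
#'
#' @param censuses Named list of censuses; floating samples are recognised
#'   by `compartment == "floating"` and grouped by replicate (the sample id
#'   prefix before `_F<week>`).
#' @param min_frequency Barcodes never reaching this frequency in a
#'   replicate's series are dropped (0 keeps everything).
#' @return Data frame `replicate`, `week`, `barcode`, `frequency`, ordered
#'   by week. Replicates with no floating samples contribute no rows.
#' @export
floating_trajectories <- function(censuses, min_frequency = 0) {
  fl <- censuses[vapply(censuses, function(x) x$compartment == "floating",
                        logical(1))]
  if (!length(fl)) {
    return(data.frame(replicate = character(0), week = numeric(0),
                      barcode = character(0), frequency = numeric(0)))
  }
  rows <- lapply(fl, function(x) {
    data.frame(replicate = sub("_F[0-9]+$", "", x$sample_id),
               week = x$timepoint, barcode = names(x$frequencies),
               frequency = as.numeric(x$frequencies),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$replicate, out$week, out$barcode), ]
  if (min_frequency > 0) {
    keymax <- tapply(out$frequency,
                     paste(out$replicate, out$barcode, sep = "\r"), max)
    keep <- keymax[paste(out$replicate, out$barcode, sep = "\r")] >=
      min_frequency
    out <- out[keep, ]
  }
  rownames(out) <- NULL
  out
}

#' Similarity between two censuses
#'
#' Cosine similarity or total-variation distance over the union of
#' barcodes, e.g. to compare a replicate's final floating sample with its
#' harvested attached census.
#'
#' @param a,b Two [barcode_census()] objects.
#' @param method `"cosine"` (1 = identical direction) or `"tvd"`
#'   (total-variation distance, 0 = identical).
#' @return Numeric scalar.
#' @export
census_similarity <- function(a, b, method = c("cosine", "tvd")) {
  method <- match.arg(method)
  keys <- union(names(a$frequencies), names(b$frequencies))
  fa <- setNames(numeric(length(keys)), keys)
  fb <- fa
  fa[names(a$frequencies)] <- a$frequencies
  fb[names(b$frequencies)] <- b$frequencies
  if (method == "cosine") {
    sum(fa * fb) / sqrt(sum(fa^2) * sum(fb^2))
  } else {
    sum(abs(fa - fb)) / 2
  }
}

#' Growth rate from log-linear fit of a confluence time series
#'
#' Ordinary least-squares slope of `log(value)` against time, the standard
#' estimate of exponential growth rate from imaging confluence curves.
#'
#' @param time Time points (e.g. days).
#' @param value Positive confluence/abundance values.
#' @return List with `rate` (slope, per unit of `time`), `se`, `r_squared`
#'   and the underlying `lm` fit.
#' @export
fit_log_linear_growth <- function(time, value) {
  if (length(time) < 3) stop("need at least 3 points")
  if (any(value <= 0)) stop("values must be positive for log transformation")
  fit <- lm(log(value) ~ time)
  sm <- summary(fit)
  list(rate = unname(coef(fit)[2]), se = sm$coefficients[2, 2],
       r_squared = sm$r.squared, fit = fit)
}

#' Group barcodes into functional subclones by growth dynamics
#'
#' Barcodes of one physical subclone share growth behaviour across
#' replicates. Complete-linkage hierarchical clustering on the Euclidean
#' distance between per-replicate growth-rate vectors, cut at `h`, groups
#' such barcodes. Barcodes with any unmeasured or infinite rate are left
#' ungrouped (subclone `NA`).
#'
#' @param records A `growth_records` table.
#' @param h Dendrogram cut height (growth-rate units, per week).
#' @return Integer vector of subclone ids aligned with `records` rows.
#' @export
functional_subclones <- function(records, h = 0.2) {
  rcols <- grep("^r_", names(records), value = TRUE)
  rmat <- as.matrix(records[, rcols, drop = FALSE])
  usable <- rowSums(!is.finite(rmat)) == 0
  out <- rep(NA_integer_, nrow(records))
  if (sum(usable) == 1) {
    out[usable] <- 1L
    return(out)
  }
  if (!any(usable)) return(out)
  hc <- stats::hclust(stats::dist(rmat[usable, , drop = FALSE]),
                      method = "complete")
  out[usable] <- stats::cutree(hc, h = h)
  out
}
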