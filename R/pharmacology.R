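#' Percent inhibition of compound wells on a screening plate
#'
#' Converts raw fluorescence intensities into an estimated percentage of
#' inhibition, `PCI = 100 * (cpos - I) / (cpos - cneg)`, where `cpos` is
#' the mean of the plate's drug-free positive-control wells and `cneg` the
#' mean of its empty wells.
#'
#' @param plate Data frame of one plate's wells with columns `role`
#'   (`"positive_control"`, `"empty"`, `"compound"`), `intensity`, and for
#'   compound wells `compound` and `conc_nM`.
#' @return The compound-well rows with an added `pci` column; the control
#'   means are attached as attributes `cpos` and `cneg`.
#' @export
plate_percent_inhibition <- function(plate) {
  stopifnot(all(c("role", "intensity") %in% names(plate)))
  cpos <- mean(plate$intensity[plate$role == "positive_control"])
  cneg <- mean(plate$intensity[plate$role == "empty"])
  if (!is.finite(cpos) || !is.finite(cneg))
    stop("plate must contain positive-control and empty wells")
  if (cpos == cneg) stop("degenerate plate: cpos equals cneg")
  out <- plate[plate$role == "compound", , drop = FALSE]
  out$pci <- 100 * (cpos - out$intensity) / (cpos - cneg)
  attr(out, "cpos") <- cpos
  attr(out, "cneg") <- cneg
  out
}

#' Rank PCI changes and identify screening hits
#'
#' For every (concentration, replicate) pair, compounds with a PCI change
#' below `min_change` percentage points are excluded, the rest are ranked
#' by descending PCI change, and the top `top_k` kept (compounds tied with
#' the rank-`top_k` value are all kept and flagged). Hits are compounds
#' appearing in the top list of more than one (concentration, replicate)
#' pair.
#'
#' @param pci_changes Data frame with columns `compound`, `concentration`,
#'   `replicate` and `pci_change` (mean PCI change versus the control
#'   line, matched on concentration and replicate).
#' @param min_change Exclusion threshold in PCI percentage points
#'   (default 5).
#' @param top_k Size of each top list (default 6).
#' @return List with `top_lists` (kept rows with `rank` and `tied` flag)
#'   and `hits` (character vector of hit compounds).
#' @export
rank_and_identify_hits <- function(pci_changes, min_change = 5, top_k = 6) {
  stopifnot(all(c("compound", "concentration", "replicate", "pci_change")
                %in% names(pci_changes)))
  groups <- split(pci_changes,
                  list(pci_changes$concentration, pci_changes$replicate),
                  drop = TRUE)
  tops <- lapply(groups, function(g) {
    g <- g[g$pci_change >= min_change, , drop = FALSE]
    if (!nrow(g)) return(g[0, ])
    g <- g[order(-g$pci_change, g$compound), , drop = FALSE]
    g$rank <- rank(-g$pci_change, ties.method = "min")
    g$tied <- FALSE
    if (nrow(g) > top_k) {
      cutoff <- g$pci_change[top_k]
      g <- g[g$pci_change >= cutoff, , drop = FALSE]
      # flag boundary ties kept beyond the nominal list size
      if (nrow(g) > top_k) g$tied <- g$pci_change == cutoff
    }
    g
  })
  top_lists <- do.call(rbind, tops)
  rownames(top_lists) <- NULL
  if (is.null(top_lists) || !nrow(top_lists))
    return(list(top_lists = pci_changes[0, ], hits = character(0)))
  n_lists <- tapply(rep(1, nrow(top_lists)), top_lists$compound, sum)
  hits <- names(n_lists)[n_lists > 1]
  list(top_lists = top_lists, hits = sort(hits))
}

#' Fit a two-parameter log-logistic dose-response curve
#'
#' Responses are first normalised to percent growth using the plate's
#' drug-free positive and empty negative control wells, then the model
#' `y(x) = 100 / (1 + (x / ec50)^hill)` — upper asymptote 100, lower 0 —
#' is fitted by nonlinear least squares on `log(ec50)`, with `ec50`
#' bounded to `[min(dose)/100, max(dose)*100]`. The starting `ec50` is the
#' dose whose response is nearest 50%.
#'
#' @param dose Positive dose vector (nM), at least 4 distinct levels.
#' @param response Raw responses (e.g. OD), or percent growth when
#'   `controls` is `NULL`.
#' @param controls Optional list with vectors `pos` (drug-free growth) and
#'   `neg` (empty wells) used to normalise: `100 * (response - mean(neg)) /
#'   (mean(pos) - mean(neg))`.
#' @return List of class `dose_response_fit`: `ec50` (nM), `hill`,
#'   `residuals`, `rss`, `converged`, `non_identifiable` (`TRUE` when the
#'   optimum sits on the ec50 bound, e.g. for flat all-growth data), and
#'   `data` (dose and normalised response).
#' @export
fit_dose_response <- function(dose, response, controls = NULL) {
  if (length(unique(dose)) < 4) stop("need at least 4 dose levels")
  if (any(dose <= 0)) stop("doses must be positive")
  if (!is.null(controls)) {
    cpos <- mean(controls$pos); cneg <- mean(controls$neg)
    if (cpos == cneg) stop("degenerate controls")
    response <- 100 * (response - cneg) / (cpos - cneg)
  }
  lo <- log(min(dose) / 100); hi <- log(max(dose) * 100)
  start_ec50 <- dose[which.min(abs(response - 50))]
  df <- data.frame(x = dose, y = response)
  if (diff(range(response)) < 1) {
    # flat curve: no dose dependence to fit; EC50 runs to a bound
    bound <- if (mean(response) > 50) exp(hi) else exp(lo)
    return(structure(list(ec50 = bound, hill = NA_real_,
                          residuals = response - mean(response),
                          rss = sum((response - mean(response))^2),
                          converged = TRUE, non_identifiable = TRUE,
                          data = df, fit = NULL),
                     class = "dose_response_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 100 / (1 + exp(hill * (log(x) - le))), data = df,
      start = list(le = log(start_ec50), hill = 1),
      lower = c(lo, 1e-3), upper = c(hi, 50),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("dose-response fit did not converge: ", conditionMessage(fit))
  cf <- coef(fit)
  ec50 <- exp(unname(cf["le"]))
  on_bound <- unname(cf["le"]) >= hi - 1e-8 || unname(cf["le"]) <= lo + 1e-8
  structure(list(ec50 = ec50, hill = unname(cf["hill"]),
                 residuals = unname(resid(fit)),
                 rss = sum(resid(fit)^2), converged = TRUE,
                 non_identifiable = on_bound, data = df, fit = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("log-logistic fit: ec50 = %.4g nM, hill = %.4g (rss %.4g)%s\n",
              x$ec50, x$hill, x$rss,
              if (x$non_identifiable) " [non-identifiable: ec50 on bound]"
              else ""))
  invisible(x)
}

#' Predicted percent growth from a dose-response fit
#'
#' @param object A `dose_response_fit`.
#' @param newdata Optional data frame with column `x` (dose, nM).
#' @param ... Unused.
#' @return Numeric vector of predicted percent growth.
#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x
  100 / (1 + (x / object$ec50)^object$hill)
}

#' Fold change between two fitted EC50 values
#'
#' Reports `fit_b$ec50 / fit_a$ec50`, e.g. the IC50 shift of a resistant
#' line relative to its parental control.
#'
#' @param fit_a,fit_b Two `dose_response_fit` objects.
#' @return Numeric ratio.
#' @export
ic50_fold_change <- function(fit_a, fit_b) {
  if (!inherits(fit_a, "dose_response_fit") ||
      !inherits(fit_b, "dose_response_fit"))
    stop("both arguments must be dose_response_fit objects")
  if (!fit_a$converged || !fit_b$converged) stop("invalid fit supplied")
  fit_b$ec50 / fit_a$ec50
}
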