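#' Fit a qPCR standard curve
#'
#' Ordinary least-squares regression of quantification cycle (Cq) on
#' log10(template input) over a dilution series. Amplification efficiency is
#' derived from the slope as \code{E = 10^(-1/slope) - 1}; perfect doubling
#' per cycle corresponds to slope -1/log10(2) = -3.3219 and E = 1 (100\%).
#' Curves with non-negative slope are flagged invalid.
#'
#' @param dilution_log10 log10 of template input (copies or dilution factor),
#'   at least 3 distinct points.
#' @param cq Measured Cq values, same length.
#' @param primer_pair Optional primer-pair label carried into the result.
#' @return An object of class \code{standard_curve}: list with
#'   \code{primer_pair}, \code{slope}, \code{intercept}, \code{r2},
#'   \code{efficiency}, \code{valid}.
#' @export
fit_standard_curve <- function(dilution_log10, cq, primer_pair = NA_character_) {
  if (length(dilution_log10) < 3L) stop("need >= 3 dilution points")
  if (length(dilution_log10) != length(cq)) stop("length mismatch")
  if (anyDuplicated(dilution_log10) && length(unique(dilution_log10)) < 3L) {
    stop("need >= 3 distinct dilution levels")
  }
  fit <- stats::lm(cq ~ dilution_log10)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  valid <- is.finite(slope) && slope < 0
  structure(
    list(
      primer_pair = primer_pair,
      slope = slope,
      intercept = intercept,
      r2 = r2,
      efficiency = if (valid) 10^(-1 / slope) - 1 else NA_real_,
      valid = valid
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve [%s]: slope %.4f, intercept %.2f, R2 %.4f, ",
              x$primer_pair, x$slope, x$intercept, x$r2))
  if (x$valid) cat(sprintf("efficiency %.1f%%\n", 100 * x$efficiency))
  else cat("INVALID (non-negative slope)\n")
  invisible(x)
}

#' Efficiency-corrected relative expression
#'
#' Reference-gene-normalized relative quantity:
#' \code{(1+E_target)^(-Cq_target) / (1+E_ref)^(-Cq_ref)}. With both
#' efficiencies at 100\% this reduces to the familiar \code{2^(-dCq)} model.
#'
#' @param cq_target Target-assay Cq.
#' @param cq_ref Reference-assay Cq (e.g. ribosomal 28S).
#' @param eff_target,eff_ref Amplification efficiencies as fractions
#'   (1 = 100\%). Values outside [0.8, 1.1] are rejected unless
#'   \code{check_eff = FALSE}.
#' @param check_eff Enforce the plausible-efficiency window (default TRUE).
#' @return Relative expression (arbitrary units).
#' @export
relative_expression <- function(cq_target, cq_ref, eff_target = 1,
                                eff_ref = 1, check_eff = TRUE) {
  if (check_eff &&
      (any(eff_target < 0.8 | eff_target > 1.1) ||
       any(eff_ref < 0.8 | eff_ref > 1.1))) {
    stop("efficiency outside [0.8, 1.1]; pass check_eff = FALSE to override")
  }
  (1 + eff_target)^(-cq_target) / (1 + eff_ref)^(-cq_ref)
}

#' Absolute copy number from a standard curve
#'
#' Inverts the fitted line: \code{copies = 10^((cq - intercept) / slope)}.
#'
#' @param cq Observed Cq.
#' @param curve A valid \code{\link{fit_standard_curve}} result.
#' @return Estimated template copies.
#' @export
copies_from_curve <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$valid) stop("cannot quantify from an invalid standard curve")
  10^((cq - curve$intercept) / curve$slope)
}

#' Aggregate replicate Cq measurements
#'
#' Arithmetic mean of Cq per sample x primer pair; Cq values at or above the
#' detection limit are treated as non-detected and dropped before averaging
#' (a cell where all replicates are non-detected stays non-detected, NA).
#'
#' @param measurements data.frame with columns \code{sample_id},
#'   \code{primer_pair}, \code{replicate}, \code{cq}.
#' @param detection_limit Cq at/above which a well is non-detected
#'   (default 40).
#' @return data.frame \code{sample_id}, \code{primer_pair}, \code{cq}
#'   (mean), \code{n_detected}.
#' @export
aggregate_cq <- function(measurements, detection_limit = 40) {
  need <- c("sample_id", "primer_pair", "cq")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  }
  m <- measurements
  m$detected <- is.finite(m$cq) & m$cq < detection_limit
  agg <- stats::aggregate(
    cbind(cq_sum = ifelse(m$detected, m$cq, 0),
          n_detected = as.integer(m$detected)) ~ sample_id + primer_pair,
    data = m, FUN = sum)
  agg$cq <- ifelse(agg$n_detected > 0, agg$cq_sum / agg$n_detected, NA_real_)
  agg[, c("sample_id", "primer_pair", "cq", "n_detected")]
}

#' Validate isoform primer specificity on plasmid mixtures
#'
#' For each mixture of known isoform plasmid copies, estimates WT copies
#' (inclusion-junction primers), skipping-isoform copies (skipping-junction
#' primers) and total copies (common-exon primers) from their standard
#' curves, and reports recovery ratios (estimated / expected) with a pass
#' flag at a configurable tolerance. The common-exon estimate is compared
#' against the summed design copies.
#'
#' @param designs data.frame \code{mixture_id}, \code{copies_wt},
#'   \code{copies_de4}.
#' @param measurements data.frame \code{sample_id} (= mixture_id),
#'   \code{primer_pair} (one of \code{"E3"}, \code{"E3-E4"}, \code{"E3-E5"}),
#'   \code{replicate}, \code{cq}.
#' @param curves Named list of \code{standard_curve} objects keyed by primer
#'   pair, covering the three assays.
#' @param tolerance Allowed relative deviation of recovery from 1
#'   (default 0.2 = ±20\%).
#' @param detection_limit Non-detection Cq threshold (default 40).
#' @return data.frame per mixture with expected and estimated copies for the
#'   three assays, recovery ratios (NA when the expected count is 0) and
#'   logical \code{pass}.
#' @export
validate_mixture <- function(designs, measurements, curves, tolerance = 0.2,
                             detection_limit = 40) {
  primers <- c("E3", "E3-E4", "E3-E5")
  if (!all(primers %in% names(curves))) {
    stop("curves must cover primer pairs: ", paste(primers, collapse = ", "))
  }
  agg <- aggregate_cq(measurements, detection_limit)
  rows <- lapply(seq_len(nrow(designs)), function(i) {
    d <- designs[i, ]
    got <- agg[agg$sample_id == d$mixture_id, ]
    miss <- setdiff(primers, got$primer_pair)
    if (length(miss)) {
      stop("mixture ", d$mixture_id, " missing primer pair(s): ",
           paste(miss, collapse = ", "))
    }
    est <- vapply(primers, function(p) {
      cq <- got$cq[got$primer_pair == p]
      if (is.na(cq)) 0 else copies_from_curve(cq, curves[[p]])
    }, numeric(1))
    exp_tot <- d$copies_wt + d$copies_de4
    recov <- function(est, expd) if (expd > 0) est / expd else NA_real_
    r_wt <- recov(est[["E3-E4"]], d$copies_wt)
    r_de4 <- recov(est[["E3-E5"]], d$copies_de4)
    r_tot <- recov(est[["E3"]], exp_tot)
    ok <- function(r) is.na(r) || abs(r - 1) <= tolerance
    # a species absent from the design must come back non-detected-ish:
    # below tolerance * total copies
    absent_ok <- (d$copies_wt > 0 || est[["E3-E4"]] <= tolerance * exp_tot) &&
      (d$copies_de4 > 0 || est[["E3-E5"]] <= tolerance * exp_tot)
    data.frame(
      mixture_id = d$mixture_id,
      copies_wt = d$copies_wt, copies_de4 = d$copies_de4,
      est_wt = est[["E3-E4"]], est_de4 = est[["E3-E5"]],
      est_total = est[["E3"]],
      recovery_wt = r_wt, recovery_de4 = r_de4, recovery_total = r_tot,
      pass = ok(r_wt) && ok(r_de4) && ok(r_tot) && absent_ok,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
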