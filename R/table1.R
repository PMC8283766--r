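#' Administrative censoring at a follow-up horizon
#'
#' Samples still under observation beyond the horizon are censored at the
#' horizon; events after the horizon are not counted (10-year retrospective
#' analysis = horizon 120 months).
#'
#' @param time,event Follow-up and event indicator.
#' @param horizon Months; \code{Inf} disables truncation.
#' @return List \code{time}, \code{event} after truncation.
#' @export
truncate_followup <- function(time, event, horizon = 120) {
  over <- time > horizon
  event[over] <- 0
  time[over] <- horizon
  list(time = time, event = event)
}

#' Univariate survival report over markers and cohort strata
#'
#' For each marker (median-split expression or the dual signature) crossed
#' with each cohort stratum (whole cohort and the molecular subtypes),
#' computes the two-group log-rank test and the univariate Cox hazard ratio
#' (high vs low) with its Wald 95\% CI, after optional administrative
#' censoring at a follow-up horizon. Cells where the Cox fit hits a monotone
#' likelihood (e.g. no events in the low group) are reported as N/A with the
#' reason; strata with fewer than two samples per group are skipped with a
#' reason. Log-rank p and Cox HR/CI are reported side by side and are not
#' reconciled into a single test.
#'
#' @param expr data.frame: \code{sample_id}, marker expression columns among
#'   \code{e3_expr}, \code{wt_expr}, \code{de4_expr}.
#' @param clinical data.frame: \code{sample_id}, \code{er}, \code{pr},
#'   \code{her2}, \code{rfs_time}, \code{event}.
#' @param markers Character subset of \code{c("e3", "wt", "de4", "dual")}.
#' @param strata Character subset of \code{c("all", "Luminal",
#'   "HER2-enriched", "TripleNegative")}.
#' @param horizon Follow-up truncation in months (default 120; Inf = none).
#' @param alpha Significance level for the NS flag (default 0.05).
#' @param scope Dichotomization scope, \code{"cohort"} or \code{"stratum"}
#'   (see \code{\link{signature_assign}}).
#' @return data.frame with one row per marker x stratum: group sizes,
#'   events, \code{logrank_chi2}, \code{logrank_p}, \code{hr},
#'   \code{ci_low}, \code{ci_high}, \code{cox_p}, \code{significant},
#'   \code{na_reason} (empty when the cell is complete).
#' @export
table1_report <- function(expr, clinical,
                          markers = c("e3", "wt", "de4", "dual"),
                          strata = c("all", "Luminal", "HER2-enriched",
                                     "TripleNegative"),
                          horizon = 120, alpha = 0.05,
                          scope = c("cohort", "stratum")) {
  scope <- match.arg(scope)
  markers <- match.arg(markers, c("e3", "wt", "de4", "dual"),
                       several.ok = TRUE)
  dat <- merge(expr, clinical, by = "sample_id")
  if (nrow(dat) == 0L) stop("expression and clinical tables share no samples")
  asg <- signature_assign(dat, dat, scope = scope)
  dat <- cbind(dat, asg[match(dat$sample_id, asg$sample_id),
                        setdiff(names(asg), "sample_id"), drop = FALSE])
  ev <- if (is.numeric(dat$event)) dat$event else
    as.integer(as.character(dat$event) %in% c("relapse", "1"))
  tr <- truncate_followup(dat$rfs_time, ev, horizon)
  dat$.time <- tr$time; dat$.event <- tr$event

  label_col <- c(e3 = "e3_label", wt = "wt_label", de4 = "de4_label",
                 dual = "dual")
  rows <- list()
  for (st in strata) {
    sub <- if (st == "all") dat else dat[!is.na(dat$subtype) &
                                           dat$subtype == st, ]
    for (mk in markers) {
      col <- label_col[[mk]]
      cell <- list(marker = mk, stratum = st, n_low = NA_integer_,
                   n_high = NA_integer_, events = NA_integer_,
                   logrank_chi2 = NA_real_, logrank_p = NA_real_,
                   hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   cox_p = NA_real_, significant = NA, na_reason = "")
      if (!col %in% names(sub)) {
        cell$na_reason <- paste0("marker '", mk, "' not in expression table")
        rows[[length(rows) + 1L]] <- cell; next
      }
      g <- sub[[col]]
      keep <- !is.na(g) & is.finite(sub$.time)
      s <- sub[keep, ]; g <- droplevels(factor(g[keep],
                                               levels = c("low", "high")))
      tab <- table(g)
      cell$n_low <- if ("low" %in% names(tab)) unname(tab[["low"]]) else 0L
      cell$n_high <- if ("high" %in% names(tab)) unname(tab[["high"]]) else 0L
      cell$events <- sum(s$.event)
      if (nlevels(g) < 2L || min(tab) < 2L) {
        cell$na_reason <- "stratum has < 2 samples per group; skipped"
        rows[[length(rows) + 1L]] <- cell; next
      }
      if (sum(s$.event) == 0L) {
        cell$na_reason <- "no events in stratum"
        rows[[length(rows) + 1L]] <- cell; next
      }
      lr <- logrank_test(s$.time, s$.event, g)
      cell$logrank_chi2 <- lr$chi2
      cell$logrank_p <- lr$p
      cx <- cox_fit(s$.time, s$.event,
                    matrix(as.integer(g == "high"), ncol = 1,
                           dimnames = list(NULL, "high")))
      if (cx$na_reason == "") {
        cell$hr <- cx$hr; cell$ci_low <- cx$ci_low
        cell$ci_high <- cx$ci_high; cell$cox_p <- cx$p
      } else {
        cell$na_reason <- cx$na_reason
      }
      cell$significant <- lr$p < alpha
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  attr(out, "alpha") <- alpha
  attr(out, "horizon") <- horizon
  attr(out, "scope") <- scope
  out
}

#' Multivariate Cox model over named covariates
#'
#' Simultaneous-entry multivariate Cox model (no stepwise selection) on a
#' joined expression/clinical table; binary factors are coded 0/1 with the
#' second level as the risk level.
#'
#' @param dat Joined data.frame with \code{rfs_time}, \code{event} and the
#'   covariate columns.
#' @param covariates Character vector of column names to enter.
#' @param horizon Follow-up truncation (months).
#' @return \code{\link{cox_fit}} result.
#' @export
cox_multivariate <- function(dat, covariates, horizon = 120) {
  ev <- if (is.numeric(dat$event)) dat$event else
    as.integer(as.character(dat$event) %in% c("relapse", "1"))
  tr <- truncate_followup(dat$rfs_time, ev, horizon)
  X <- sapply(covariates, function(cv) {
    v <- dat[[cv]]
    if (is.null(v)) stop("covariate not found: ", cv)
    if (is.numeric(v)) v else {
      f <- as.factor(v)
      if (nlevels(f) != 2L) stop("non-binary factor covariate: ", cv)
      as.integer(f == levels(f)[2])
    }
  })
  cox_fit(tr$time, tr$event, as.matrix(X))
}
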