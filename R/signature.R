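#' Molecular subtype from receptor status
#'
#' St Gallen-style surrogate subtypes from immunohistochemistry receptor
#' calls: Luminal when ER+ and/or PR+; HER2-enriched when ER-/PR-/HER2+;
#' TripleNegative when ER-/PR-/HER2-.
#'
#' @param er,pr,her2 Receptor statuses, each \code{"+"} or \code{"-"}
#'   (vectorized). \code{NA} in any status yields \code{NA} subtype (the
#'   sample is excluded from subtype analyses).
#' @return Character vector: \code{"Luminal"}, \code{"HER2-enriched"},
#'   \code{"TripleNegative"} or \code{NA}.
#' @export
assign_subtype <- function(er, pr, her2) {
  chk <- function(x, nm) {
    x <- as.character(x)
    if (any(!x %in% c("+", "-", NA))) stop(nm, " status must be '+' or '-'")
    x
  }
  er <- chk(er, "ER"); pr <- chk(pr, "PR"); her2 <- chk(her2, "HER2")
  out <- ifelse(er == "+" | pr == "+", "Luminal",
         ifelse(her2 == "+", "HER2-enriched", "TripleNegative"))
  out[is.na(er) | is.na(pr) | is.na(her2)] <- NA_character_
  # ER-,PR unknown cannot rule out Luminal
  out[is.na(er) & !is.na(pr) & pr == "+"] <- "Luminal"
  out[!is.na(er) & er == "+"] <- "Luminal"
  out
}

#' Median dichotomization of a continuous marker
#'
#' Splits samples at the median of \code{values} within the stated scope:
#' \code{"high"} strictly above the median, \code{"low"} at or below (ties
#' at the median are low, so "high" always means strictly above). With all
#' values identical every sample is low and a warning is raised.
#'
#' @param values Numeric marker values (>= 2 finite values required).
#' @param scope_values Values over which the median is computed (defaults to
#'   \code{values}; pass the whole-cohort values to label a subclass at the
#'   cohort-wide median).
#' @return List with \code{labels} (factor low/high, NA where the value is
#'   missing) and \code{median} (the split point used).
#' @export
median_dichotomize <- function(values, scope_values = values) {
  fin <- is.finite(scope_values)
  if (sum(fin) < 2L) stop("need >= 2 finite values to dichotomize")
  med <- stats::median(scope_values[fin])
  if (all(scope_values[fin] == scope_values[fin][1])) {
    warning("all values identical; every sample labelled 'low'")
  }
  lab <- ifelse(values > med, "high", "low")
  lab[!is.finite(values)] <- NA_character_
  list(labels = factor(lab, levels = c("low", "high")), median = med)
}

#' Dual-isoform group assignment
#'
#' Maps per-isoform low/high labels to the 3-group classification
#' (1 = both low, 3 = both high, 2 = discordant) and the 2-group dual
#' signature (low only when both markers are low; high when either is high).
#'
#' @param wt_label,de4_label low/high labels (vectorized; character or
#'   factor).
#' @return data.frame with integer \code{group3} (1/2/3) and factor
#'   \code{dual} (low/high); NA labels propagate.
#' @export
assign_groups <- function(wt_label, de4_label) {
  wt <- as.character(wt_label); de4 <- as.character(de4_label)
  bad <- stats::na.omit(setdiff(unique(c(wt, de4)), c("low", "high")))
  if (length(bad)) stop("labels must be 'low'/'high', got: ",
                        paste(bad, collapse = ", "))
  group3 <- ifelse(wt == "low" & de4 == "low", 1L,
            ifelse(wt == "high" & de4 == "high", 3L, 2L))
  dual <- factor(ifelse(group3 == 1L, "low", "high"),
                 levels = c("low", "high"))
  data.frame(group3 = group3, dual = dual)
}

#' Fraction of samples with concordant isoform labels
#'
#' Fraction of samples in group 1 or group 3 (both markers low or both
#' high); under independent markers this tends to 0.5, under perfectly
#' correlated markers to 1.
#'
#' @param group3 Integer group labels (1/2/3), NAs dropped.
#' @return Fraction in [0, 1].
#' @export
concordance_fraction <- function(group3) {
  g <- group3[!is.na(group3)]
  if (!length(g)) stop("no group assignments supplied")
  mean(g %in% c(1L, 3L))
}

#' Build per-sample signature assignments for a cohort
#'
#' Convenience wrapper chaining subtype assignment, median dichotomization
#' of each marker and group assignment.
#'
#' @param expr data.frame with \code{sample_id}, \code{wt_expr},
#'   \code{de4_expr} and optionally \code{e3_expr}.
#' @param clinical Optional data.frame with \code{sample_id}, \code{er},
#'   \code{pr}, \code{her2} for subtype assignment.
#' @param scope \code{"cohort"} (default; medians over all samples) or
#'   \code{"stratum"} (medians within each molecular subtype; requires
#'   \code{clinical}).
#' @return data.frame: sample_id, labels per marker, group3, dual, subtype,
#'   with the medians used stored in \code{attr(x, "medians")}.
#' @export
signature_assign <- function(expr, clinical = NULL,
                             scope = c("cohort", "stratum")) {
  scope <- match.arg(scope)
  out <- data.frame(sample_id = expr$sample_id, stringsAsFactors = FALSE)
  subtype <- rep(NA_character_, nrow(expr))
  if (!is.null(clinical)) {
    idx <- match(expr$sample_id, clinical$sample_id)
    subtype <- assign_subtype(clinical$er[idx], clinical$pr[idx],
                              clinical$her2[idx])
  }
  if (scope == "stratum" && is.null(clinical)) {
    stop("scope = 'stratum' requires a clinical table with receptor status")
  }
  markers <- intersect(c("e3_expr", "wt_expr", "de4_expr"), names(expr))
  medians <- list()
  for (m in markers) {
    lab <- rep(NA_character_, nrow(expr))
    if (scope == "cohort") {
      d <- median_dichotomize(expr[[m]])
      lab <- as.character(d$labels)
      medians[[m]] <- d$median
    } else {
      for (s in unique(stats::na.omit(subtype))) {
        in_s <- which(!is.na(subtype) & subtype == s)
        if (length(in_s) >= 2L) {
          d <- median_dichotomize(expr[[m]][in_s])
          lab[in_s] <- as.character(d$labels)
          medians[[paste(m, s, sep = ".")]] <- d$median
        }
      }
    }
    out[[sub("_expr$", "_label", m)]] <- factor(lab, levels = c("low", "high"))
  }
  grp <- assign_groups(out$wt_label, out$de4_label)
  out$group3 <- grp$group3
  out$dual <- grp$dual
  out$subtype <- subtype
  attr(out, "medians") <- medians
  attr(out, "scope") <- scope
  out
}
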