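#' Quantify isoform expression for a set of samples
#'
#' Chains junction counting, skipping-ratio computation and isoform
#' expression partitioning for every sample in a sample sheet, writes a
#' per-sample TSV and a JSON run manifest, and returns the table. Samples
#' whose alignment file fails to parse are skipped and listed in the
#' manifest; the run continues.
#'
#' @param samples data.frame with columns \code{sample_id}, \code{path}
#'   (SAM/BAM) and \code{gene_deseq} (gene-level normalized expression);
#'   optional \code{exon3_reads} and \code{total_reads} trigger exon-scaled
#'   normalization via \code{\link{exon3_deseq}}, otherwise
#'   \code{gene_deseq} is used directly.
#' @param model A \code{\link{gene_model}}.
#' @param cutoff Positivity cutoff on the skipping-isoform expression
#'   (default 1000).
#' @param min_anchor Junction anchor requirement (default 3).
#' @param out_dir Output directory (created); \code{NULL} skips writing.
#' @return data.frame: sample_id, n_e3e4, n_e3e5, skip_ratio, norm_expr,
#'   wt_expr, de4_expr, rel_level, positive.
#' @export
run_quantify <- function(samples, model, cutoff = 1000, min_anchor = 3L,
                         out_dir = NULL) {
  stopifnot(inherits(model, "gene_model"))
  failed <- character(0)
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    res <- tryCatch({
      n_incl <- count_junction_reads(s$path, model$junction_inclusion,
                                     min_anchor, model$reference_name)
      n_skip <- count_junction_reads(s$path, model$junction_skip,
                                     min_anchor, model$reference_name)
      sr <- skip_ratio(n_incl, n_skip)
      norm <- if (all(c("exon3_reads", "total_reads") %in% names(samples)) &&
                  is.finite(s$exon3_reads) && is.finite(s$total_reads)) {
        exon3_deseq(s$exon3_reads, s$total_reads, s$gene_deseq)
      } else {
        s$gene_deseq
      }
      iso <- isoform_expression(sr, norm, cutoff, s$sample_id)
      cbind(data.frame(sample_id = s$sample_id, n_e3e4 = n_incl,
                       n_e3e5 = n_skip, norm_expr = norm,
                       stringsAsFactors = FALSE),
            iso[, c("skip_ratio", "wt_expr", "de4_expr", "rel_level",
                    "positive")])
    }, error = function(e) {
      warning("sample ", s$sample_id, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, s$sample_id) else
      rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(out, file.path(out_dir, "isoform_expression.tsv"))
    write_manifest(file.path(out_dir, "manifest_quantify.json"),
                   stage = "quantify",
                   config = list(cutoff = cutoff, min_anchor = min_anchor,
                                 reference = model$reference_name),
                   n_samples = nrow(out), failed_samples = failed)
  }
  attr(out, "failed_samples") <- failed
  out
}

#' Clinical report stage: signature, survival table and association stats
#'
#' Joins the expression and clinical tables, builds the median-split and
#' dual signatures, and writes the univariate survival report, per-stratum
#' Kaplan-Meier curve coordinates, and the cohort association statistics
#' (Pearson correlation of the two isoforms, Kruskal-Wallis of each isoform
#' across molecular subtypes).
#'
#' @param expr Expression table (see \code{\link{table1_report}}).
#' @param clinical Clinical table.
#' @param horizon,alpha,scope Passed to \code{\link{table1_report}}.
#' @param markers,strata Passed to \code{\link{table1_report}}.
#' @param out_dir Output directory; \code{NULL} skips writing.
#' @return List: \code{table1}, \code{pearson}, \code{kruskal_wt},
#'   \code{kruskal_de4}, \code{assignments}, \code{km_curves} (per marker x
#'   stratum x group).
#' @export
run_clinical <- function(expr, clinical, horizon = 120, alpha = 0.05,
                         scope = "cohort",
                         markers = c("e3", "wt", "de4", "dual"),
                         strata = c("all", "Luminal", "HER2-enriched",
                                    "TripleNegative"),
                         out_dir = NULL) {
  dat <- merge(expr, clinical, by = "sample_id")
  if (nrow(dat) == 0L) stop("expression and clinical tables share no samples")
  markers <- intersect(markers,
                       c(sub("_expr$", "", grep("_expr$", names(expr),
                                                value = TRUE)), "dual"))
  tab1 <- table1_report(expr, clinical, markers = markers, strata = strata,
                        horizon = horizon, alpha = alpha, scope = scope)
  asg <- signature_assign(dat, dat, scope = if (scope == "cohort")
    "cohort" else "stratum")
  pear <- pearson_corr(dat$wt_expr, dat$de4_expr)
  kw_ok <- length(unique(stats::na.omit(asg$subtype))) >= 2
  kw_wt <- if (kw_ok) kruskal_wallis(dat$wt_expr, asg$subtype) else NULL
  kw_de4 <- if (kw_ok) kruskal_wallis(dat$de4_expr, asg$subtype) else NULL

  ev <- if (is.numeric(dat$event)) dat$event else
    as.integer(as.character(dat$event) %in% c("relapse", "1"))
  tr <- truncate_followup(dat$rfs_time, ev, horizon)
  km <- list()
  for (mk in markers) {
    col <- c(e3 = "e3_label", wt = "wt_label", de4 = "de4_label",
             dual = "dual")[[mk]]
    if (!col %in% names(asg)) next
    for (g in c("low", "high")) {
      sel <- which(!is.na(asg[[col]]) & asg[[col]] == g)
      if (length(sel) >= 1L) {
        cv <- km_estimate(tr$time[sel], tr$event[sel])
        cv$marker <- mk; cv$group <- g
        km[[paste(mk, g, sep = ".")]] <- cv
      }
    }
  }
  res <- list(table1 = tab1, pearson = pear, kruskal_wt = kw_wt,
              kruskal_de4 = kw_de4, assignments = asg,
              km_curves = km)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(tab1, file.path(out_dir, "table1.tsv"))
    write_tsv(asg, file.path(out_dir, "signature_assignments.tsv"))
    write_tsv(do.call(rbind, km), file.path(out_dir, "km_curves.tsv"))
    stats_json <- list(
      pearson = pear,
      kruskal_wt = kw_wt, kruskal_de4 = kw_de4)
    jsonlite::write_json(stats_json, file.path(out_dir, "association.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(file.path(out_dir, "manifest_clinical.json"),
                   stage = "clinical",
                   config = list(horizon = horizon, alpha = alpha,
                                 scope = scope, markers = markers,
                                 strata = strata),
                   n_samples = nrow(dat))
  }
  res
}

#' @keywords internal
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @keywords internal
write_manifest <- function(path, stage, config, ...) {
  jsonlite::write_json(
    list(stage = stage,
         package_version = as.character(utils::packageVersion("exonsig")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config, ...),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
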