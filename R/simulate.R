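#' Simulate spliced alignments across a cassette-exon event
#'
#' Writes a coordinate-sorted SAM file of junction-spanning reads over a
#' gene model. Binomial(depth, skip_fraction) reads span the skipping
#' junction, the remainder the inclusion junction; each read carries an
#' \code{N} gap operator whose reference boundaries equal its junction
#' exactly, with the read offset drawn uniformly among positions leaving at
#' least \code{anchor_min} aligned bases on each side of the gap.
#' Deterministic under a fixed seed (byte-identical output).
#'
#' @param model A \code{\link{gene_model}}.
#' @param out Output SAM path.
#' @param depth Number of junction-spanning reads.
#' @param skip_fraction True skipping fraction in [0, 1].
#' @param read_length Read length in bases (default 100).
#' @param anchor_min Minimum anchor on each side of the gap (default 6).
#' @param n_exonic Additional ungapped reads placed inside the upstream
#'   flanking exon (default 0); counted in total depth but never at a
#'   junction.
#' @param seed Integer seed.
#' @return Invisible list of true counts: \code{n_incl}, \code{n_skip},
#'   \code{n_exonic}, plus the \code{path} written.
#' @export
simulate_alignments <- function(model, out, depth, skip_fraction,
                                read_length = 100L, anchor_min = 6L,
                                n_exonic = 0L, seed = 1L) {
  stopifnot(inherits(model, "gene_model"))
  if (skip_fraction < 0 || skip_fraction > 1) stop("skip_fraction in [0,1]")
  if (read_length < 2L * anchor_min + 1L) {
    stop("read_length must be >= 2*anchor_min + 1")
  }
  set.seed(seed)
  depth <- as.integer(depth)
  n_skip <- as.integer(stats::rbinom(1L, depth, skip_fraction))
  n_incl <- depth - n_skip
  ref <- model$reference_name
  ref_len <- max(model$exons$end) + 1000L

  junc_read <- function(id, junction) {
    donor <- junction[["donor"]]; acceptor <- junction[["acceptor"]]
    left <- sample(seq.int(anchor_min, read_length - anchor_min), 1L)
    right <- read_length - left
    pos <- donor - left + 1L  # SAM 1-based leftmost
    gap <- acceptor - donor
    cigar <- sprintf("%dM%dN%dM", left, gap, right)
    c(id, "0", ref, as.character(pos), "60", cigar, "*", "0", "0",
      strrep("A", read_length), "*")
  }
  exon_read <- function(id) {
    e3 <- model$exons[1, ]
    span <- e3$end - e3$start
    rl <- min(read_length, span)
    pos0 <- e3$start + sample.int(span - rl + 1L, 1L) - 1L
    c(id, "0", ref, as.character(pos0 + 1L), "60", sprintf("%dM", rl), "*",
      "0", "0", strrep("A", rl), "*")
  }

  recs <- vector("list", n_incl + n_skip + n_exonic)
  i <- 0L
  for (r in seq_len(n_incl)) {
    i <- i + 1L
    recs[[i]] <- junc_read(sprintf("incl_%06d", r), model$junction_inclusion)
  }
  for (r in seq_len(n_skip)) {
    i <- i + 1L
    recs[[i]] <- junc_read(sprintf("skip_%06d", r), model$junction_skip)
  }
  for (r in seq_len(n_exonic)) {
    i <- i + 1L
    recs[[i]] <- exon_read(sprintf("exon_%06d", r))
  }
  pos <- vapply(recs, function(x) as.integer(x[4]), integer(1))
  nm <- vapply(recs, function(x) x[1], character(1))
  recs <- recs[order(pos, nm)]  # coordinate sort, name tiebreak: reproducible
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", ref, ref_len),
    vapply(recs, paste, character(1), collapse = "\t")
  )
  writeLines(lines, out)
  invisible(list(n_incl = n_incl, n_skip = n_skip, n_exonic = n_exonic,
                 path = out))
}

#' Simulate a breast-tumor cohort with correlated isoform expression and
#' relapse outcomes
#'
#' Log-expression of the two isoforms is drawn from a bivariate normal with
#' correlation \code{rho} and exponentiated (log-normal marginals: right-
#' skewed, zero-bounded, as observed for junction-level expression).
#' Molecular subtype is sampled from \code{subtype_probs} and shifts both
#' log-means additively; receptor statuses are derived deterministically
#' from the subtype (Luminal = ER+/PR+/HER2-, HER2-enriched = ER-/PR-/HER2+,
#' TripleNegative = all negative) so subtype assignment is exactly
#' invertible. The true dual-signature label compares each sample's
#' expression to the subtype-marginal true medians \code{exp(mu)}; relapse
#' times are exponential with hazard \code{baseline_hazard *
#' hr_signature^(dual == "high")}, administratively censored at
#' \code{censor_time}.
#'
#' Defaults describe the stated world of the target cohort: n = 107 tumors
#' split ~72/15/20 across Luminal / HER2-enriched / TripleNegative, isoform
#' log-correlation 0.85, skipping isoform ~7-fold below the inclusion
#' isoform, dual-signature hazard ratio 5, 120-month follow-up.
#'
#' @param n Cohort size.
#' @param rho Pearson correlation of the log-expressions, in (-1, 1).
#' @param mu_wt,sigma_wt,mu_de4,sigma_de4 Log-scale location and scale of
#'   the inclusion (WT) and skipping isoform expressions.
#' @param subtype_probs Probability simplex over (Luminal, HER2-enriched,
#'   TripleNegative).
#' @param subtype_shifts Additive log-scale shifts per subtype, same order.
#' @param hr_signature True hazard ratio of dual-high vs dual-low (> 0).
#' @param baseline_hazard Relapse hazard of the dual-low group, events per
#'   month.
#' @param censor_time Administrative censoring horizon in months.
#' @param seed Integer seed.
#' @return List of data.frames: \code{expression} (sample_id, wt_expr,
#'   de4_expr, e3_expr = their sum), \code{clinical} (sample_id, age,
#'   sbr_grade, lymph_node, tumor_size, er, pr, her2, rfs_time, event) and
#'   \code{truth} (subtype, log-expressions, true dual label, true hazard,
#'   uncensored relapse time, plus the generating parameters as attributes).
#' @export
simulate_cohort <- function(n = 107L, rho = 0.85,
                            mu_wt = log(6300), sigma_wt = 1.0,
                            mu_de4 = log(6300) - log(7), sigma_de4 = 1.0,
                            subtype_probs = c(Luminal = 0.673,
                                              `HER2-enriched` = 0.140,
                                              TripleNegative = 0.187),
                            subtype_shifts = c(Luminal = 0.3,
                                               `HER2-enriched` = 0.0,
                                               TripleNegative = -0.4),
                            hr_signature = 5, baseline_hazard = 0.002,
                            censor_time = 120, seed = 1L) {
  if (abs(rho) >= 1) stop("rho must be in (-1, 1)")
  if (abs(sum(subtype_probs) - 1) > 1e-8) stop("subtype_probs must sum to 1")
  if (hr_signature <= 0) stop("hr_signature must be > 0")
  set.seed(seed)
  subtypes <- c("Luminal", "HER2-enriched", "TripleNegative")
  subtype <- sample(subtypes, n, replace = TRUE, prob = subtype_probs)
  shift <- subtype_shifts[subtype]

  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  log_wt <- mu_wt + shift + sigma_wt * z1
  log_de4 <- mu_de4 + shift + sigma_de4 * z2

  # true dual label: against subtype-conditional true medians exp(mu + shift)
  dual_true <- ifelse(log_wt > mu_wt + shift | log_de4 > mu_de4 + shift,
                      "high", "low")
  hazard <- baseline_hazard * hr_signature^(dual_true == "high")
  t_relapse <- stats::rexp(n, rate = hazard)
  event <- as.integer(t_relapse <= censor_time)
  rfs_time <- pmin(t_relapse, censor_time)

  er <- ifelse(subtype == "Luminal", "+", "-")
  pr <- er
  her2 <- ifelse(subtype == "HER2-enriched", "+", "-")
  ids <- sprintf("S%04d", seq_len(n))

  expression <- data.frame(
    sample_id = ids,
    wt_expr = exp(log_wt),
    de4_expr = exp(log_de4),
    e3_expr = exp(log_wt) + exp(log_de4),
    stringsAsFactors = FALSE
  )
  clinical <- data.frame(
    sample_id = ids,
    age = round(stats::rnorm(n, 58, 11)),
    sbr_grade = sample(c("I", "II", "III"), n, replace = TRUE,
                       prob = c(0.1, 0.32, 0.58)),
    lymph_node = sample(c("negative", "positive"), n, replace = TRUE),
    tumor_size = round(stats::rlnorm(n, log(22), 0.4)),
    er = er, pr = pr, her2 = her2,
    rfs_time = rfs_time, event = event,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    sample_id = ids, subtype = subtype, log_wt = log_wt, log_de4 = log_de4,
    dual_true = factor(dual_true, levels = c("low", "high")),
    hazard = hazard, t_relapse = t_relapse,
    stringsAsFactors = FALSE
  )
  attr(truth, "params") <- list(
    n = n, rho = rho, mu_wt = mu_wt, sigma_wt = sigma_wt, mu_de4 = mu_de4,
    sigma_de4 = sigma_de4, subtype_probs = subtype_probs,
    subtype_shifts = subtype_shifts, hr_signature = hr_signature,
    baseline_hazard = baseline_hazard, censor_time = censor_time, seed = seed)
  list(expression = expression, clinical = clinical, truth = truth)
}

#' Simulate qPCR plates: dilution series and isoform plasmid mixtures
#'
#' Generates, per primer pair, a 10-fold dilution-series table for standard
#' curves and a long-format Cq table over the supplied mixture designs.
#' Cq is \code{intercept + slope * log10(copies) + N(0, noise_sd)} with
#' \code{slope = -1/log10(1 + efficiency)}; zero template is reported as
#' non-detected (Cq 40).
#'
#' @param designs data.frame \code{mixture_id}, \code{copies_wt},
#'   \code{copies_de4}.
#' @param efficiencies Named numeric vector of amplification efficiencies in
#'   (0.5, 1.2] for primer pairs \code{E3}, \code{E3-E4}, \code{E3-E5} (a
#'   \code{REF28S} entry is allowed and gets a dilution series only).
#' @param noise_sd Cq noise standard deviation in cycles (default 0).
#' @param intercept Cq at 1 template copy (default 38).
#' @param dilution_copies Copy numbers of the standard-curve points
#'   (default 10^(2:7)).
#' @param n_replicates Replicate wells per mixture x primer (default 3).
#' @param dilution_replicates Replicate wells per dilution point (default 3,
#'   the usual plate design; curve error otherwise dominates recovery).
#' @param detection_limit Reported Cq for zero template (default 40).
#' @param seed Integer seed.
#' @return List: \code{measurements} (sample_id, primer_pair, replicate,
#'   cq), \code{dilutions} (primer_pair, copies, log10_copies, cq),
#'   \code{truth} (per primer: slope, intercept, efficiency).
#' @export
simulate_qpcr <- function(designs,
                          efficiencies = c(E3 = 0.98, `E3-E4` = 0.95,
                                           `E3-E5` = 0.97),
                          noise_sd = 0, intercept = 38,
                          dilution_copies = 10^(2:7), n_replicates = 3L,
                          dilution_replicates = 3L,
                          detection_limit = 40, seed = 1L) {
  if (any(efficiencies <= 0.5 | efficiencies > 1.2)) {
    stop("efficiencies must lie in (0.5, 1.2]")
  }
  set.seed(seed)
  slope <- -1 / log10(1 + efficiencies)
  cq_of <- function(primer, copies, nrep) {
    out <- numeric(length(copies) * nrep)
    k <- 0L
    for (cp in copies) for (r in seq_len(nrep)) {
      k <- k + 1L
      out[k] <- if (cp <= 0) detection_limit else
        intercept + slope[[primer]] * log10(cp) +
          (if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0)
    }
    out
  }
  dil <- do.call(rbind, lapply(names(efficiencies), function(p) {
    cp <- rep(dilution_copies, each = dilution_replicates)
    data.frame(primer_pair = p, copies = cp,
               log10_copies = log10(cp),
               cq = cq_of(p, cp, 1L),
               stringsAsFactors = FALSE)
  }))
  template <- function(primer, d) switch(primer,
    "E3" = d$copies_wt + d$copies_de4,
    "E3-E4" = d$copies_wt,
    "E3-E5" = d$copies_de4)
  primers <- intersect(c("E3", "E3-E4", "E3-E5"), names(efficiencies))
  meas <- do.call(rbind, lapply(seq_len(nrow(designs)), function(i) {
    d <- designs[i, ]
    do.call(rbind, lapply(primers, function(p) {
      data.frame(sample_id = d$mixture_id, primer_pair = p,
                 replicate = seq_len(n_replicates),
                 cq = cq_of(p, rep(template(p, d), n_replicates), 1L),
                 stringsAsFactors = FALSE)
    }))
  }))
  truth <- data.frame(primer_pair = names(efficiencies),
                      slope = as.numeric(slope), intercept = intercept,
                      efficiency = as.numeric(efficiencies),
                      stringsAsFactors = FALSE)
  list(measurements = meas, dilutions = dil, truth = truth)
}

#' Default three-exon gene model used by the simulators
#'
#' A synthetic stand-in gene model (not real genome coordinates): exons of
#' realistic sizes on a stub reference, the cassette exon 133 bp long.
#'
#' @return A \code{\link{gene_model}}.
#' @export
example_gene_model <- function() {
  gene_model(
    reference_name = "ref1", strand = "+",
    exons = data.frame(label = c("E3", "E4", "E5"),
                       start = c(1000L, 2000L, 3000L),
                       end = c(1400L, 2133L, 3500L)),
    exon_labels = c("E3", "E4", "E5")
  )
}
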