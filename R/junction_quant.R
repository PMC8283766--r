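#' Count splice-junction reads supporting an exact junction
#'
#' Counts primary, non-duplicate, mapped alignments whose CIGAR contains an
#' intron gap (\code{N} operator) with reference boundaries exactly equal to
#' the requested junction, with at least \code{min_anchor} aligned bases on
#' each side of that gap. Junction coordinates are 0-based half-open: the
#' donor is the reference position immediately after the last exonic base of
#' the upstream exon; the acceptor is the first base of the downstream exon.
#'
#' SAM input is converted to BAM on the fly with \code{Rsamtools::asBam};
#' the file is scanned in a single streaming pass (no index required).
#' Alignments in either orientation are counted (library strandedness is not
#' assumed).
#'
#' @param path Path to a SAM or BAM file of spliced alignments.
#' @param junction Numeric length-2 vector \code{c(donor, acceptor)} in
#'   0-based reference coordinates, or a \code{gene_model} junction field.
#' @param min_anchor Minimum aligned reference bases flanking the gap on each
#'   side for a read to count (default 3).
#' @param reference_name Optional reference name the junction lives on; if
#'   supplied, alignments on other references are ignored.
#' @return Integer count of supporting reads.
#' @export
count_junction_reads <- function(path, junction, min_anchor = 3L,
                                 reference_name = NULL) {
  stopifnot(length(junction) == 2L)
  donor <- as.numeric(junction[[1]])
  acceptor <- as.numeric(junction[[2]])
  if (acceptor <= donor) stop("junction acceptor must exceed donor")
  ga <- .read_spliced_alignments(path)
  if (length(ga) == 0L) return(0L)
  if (!is.null(reference_name)) {
    ga <- ga[as.character(GenomicAlignments::seqnames(ga)) == reference_name]
    if (length(ga) == 0L) return(0L)
  }
  # all intron gaps across reads, with their read index (vectorized; a
  # per-read [[i]] loop over the gap list is quadratic and unusable at depth)
  gaps <- GenomicAlignments::junctions(ga)  # per-read intron ranges, 1-based
  ridx <- rep(seq_along(ga), S4Vectors::elementNROWS(gaps))
  u <- unlist(gaps, use.names = FALSE)
  if (!length(u)) return(0L)
  # intron [start, end] 1-based inclusive <-> (donor, acceptor) =
  # (start - 1, end) in 0-based half-open coordinates
  hit <- IRanges::start(u) - 1L == donor & IRanges::end(u) == acceptor
  cand <- unique(ridx[hit])
  if (!length(cand)) return(0L)
  cig <- GenomicAlignments::cigar(ga)[cand]
  pos <- GenomicAlignments::start(ga)[cand]
  op_l <- GenomicAlignments::explodeCigarOps(cig)
  len_l <- GenomicAlignments::explodeCigarOpLengths(cig)
  total <- 0L
  for (k in seq_along(cand)) {
    if (.anchor_ok(op_l[[k]], len_l[[k]], pos[k], donor, acceptor,
                   min_anchor)) {
      total <- total + 1L
    }
  }
  total
}

# aligned (M/=/X) reference bases immediately flanking the matching N gap
.anchor_ok <- function(ops, lens, pos, donor, acceptor, min_anchor) {
  ref_pos <- pos - 1L  # 0-based cursor
  left <- 0L
  n <- length(ops)
  i <- 1L
  while (i <= n) {
    op <- ops[i]; len <- lens[i]
    if (op == "M" || op == "=" || op == "X") {
      left <- left + len
      ref_pos <- ref_pos + len
    } else if (op == "D") {
      ref_pos <- ref_pos + len
      left <- 0L
    } else if (op == "N") {
      if (ref_pos == donor && ref_pos + len == acceptor) {
        # right anchor: aligned bases until the next gap/deletion
        right <- 0L
        j <- i + 1L
        while (j <= n && ops[j] %in% c("M", "=", "X", "I", "S")) {
          if (ops[j] %in% c("M", "=", "X")) right <- right + lens[j]
          j <- j + 1L
        }
        return(left >= min_anchor && right >= min_anchor)
      }
      ref_pos <- ref_pos + len
      left <- 0L
    }
    # I, S, H, P consume no reference
    i <- i + 1L
  }
  FALSE
}

.read_spliced_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE)
  GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flags))
}

#' Count primary mapped alignments in a SAM/BAM file
#'
#' Library-size proxy used when total mapped reads are not supplied
#' externally. Same record filters as \code{\link{count_junction_reads}}.
#'
#' @param path SAM or BAM file path.
#' @return Integer count.
#' @export
count_total_reads <- function(path) {
  length(.read_spliced_alignments(path))
}

#' Skipping fraction from junction read counts
#'
#' The fraction of junction evidence supporting the skipping isoform:
#' \code{n_skip / (n_incl + n_skip)}, the complement of PSI (percent spliced
#' in) for the cassette exon.
#'
#' @param n_e3e4 Inclusion-junction read count.
#' @param n_e3e5 Skipping-junction read count.
#' @return Fraction in [0, 1]; \code{NA} (undefined, distinct from 0) when
#'   both counts are zero.
#' @export
skip_ratio <- function(n_e3e4, n_e3e5) {
  if (any(n_e3e4 < 0) || any(n_e3e5 < 0)) stop("junction counts must be >= 0")
  out <- n_e3e5 / (n_e3e4 + n_e3e5)
  out[(n_e3e4 + n_e3e5) == 0] <- NA_real_
  out
}

#' Exon-scaled normalized expression
#'
#' Scales a gene-level library-size-normalized expression value by the
#' fraction of the sample's reads falling in the constitutive exon:
#' \code{(exon3_reads / total_reads) * gene_deseq}.
#'
#' @param exon3_reads Reads overlapping the constitutive exon.
#' @param total_reads Total mapped reads in the sample (> 0).
#' @param gene_deseq Gene-level normalized expression (arbitrary units).
#' @return Scaled expression in the same units as \code{gene_deseq}.
#' @export
exon3_deseq <- function(exon3_reads, total_reads, gene_deseq) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0")
  if (any(exon3_reads < 0) || any(gene_deseq < 0)) {
    stop("exon3_reads and gene_deseq must be >= 0")
  }
  (exon3_reads / total_reads) * gene_deseq
}

#' Partition normalized expression into isoform expression values
#'
#' Splits a sample's normalized gene expression between the inclusion (WT)
#' and skipping isoforms in proportion to the junction-read skipping
#' fraction, computes the skipping/WT relative level, and flags positivity
#' for the skipping isoform at an expression cutoff (inclusive, default
#' 1000 normalized units).
#'
#' @param skip_ratio Skipping fraction in [0, 1] (may be NA = undefined).
#' @param norm_expr Normalized gene expression (>= 0).
#' @param cutoff Positivity cutoff on the skipping-isoform expression.
#' @param sample_id Optional sample identifier.
#' @return data.frame with one row: \code{sample_id}, \code{skip_ratio},
#'   \code{wt_expr}, \code{de4_expr}, \code{rel_level} (NA when WT
#'   expression is 0), \code{positive}.
#' @export
isoform_expression <- function(skip_ratio, norm_expr, cutoff = 1000,
                               sample_id = NA_character_) {
  if (!is.na(skip_ratio) && (skip_ratio < 0 || skip_ratio > 1)) {
    stop("skip_ratio must be in [0, 1]")
  }
  if (norm_expr < 0) stop("norm_expr must be >= 0")
  de4 <- skip_ratio * norm_expr
  wt <- (1 - skip_ratio) * norm_expr
  data.frame(
    sample_id = sample_id,
    skip_ratio = skip_ratio,
    wt_expr = wt,
    de4_expr = de4,
    rel_level = if (!is.na(wt) && wt > 0) de4 / wt else NA_real_,
    positive = if (is.na(de4)) NA else de4 >= cutoff,
    stringsAsFactors = FALSE
  )
}

#' Cohort-level summaries of isoform expression
#'
#' Histogram counts of both isoform expressions in fixed-width bins
#' (default: bins of thousands), the fraction of skip-positive samples, and
#' the distribution of the relative skipping/WT level across intervals.
#'
#' @param expr data.frame with columns \code{wt_expr}, \code{de4_expr},
#'   \code{rel_level}, \code{positive} (one row per sample).
#' @param bin_width Histogram bin width in expression units (default 1000).
#' @param rel_breaks Interior breakpoints for the relative-level intervals
#'   (default \code{c(0.10, 0.20)}, i.e. <10\%, 10-20\%, >20\%).
#' @return List with \code{wt_hist}, \code{de4_hist} (data.frames bin_lo,
#'   bin_hi, count), \code{positive_fraction}, and \code{rel_fractions}
#'   (named fractions per interval; intervals closed on the left).
#' @export
cohort_summary <- function(expr, bin_width = 1000, rel_breaks = c(0.10, 0.20)) {
  if (nrow(expr) == 0L) stop("empty cohort")
  hist1 <- function(x) {
    x <- x[is.finite(x)]
    hi <- max(x, 0)
    breaks <- seq(0, (floor(hi / bin_width) + 1) * bin_width, by = bin_width)
    cnt <- as.integer(table(cut(x, breaks, right = FALSE,
                                include.lowest = TRUE)))
    data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
               count = cnt)
  }
  rel <- expr$rel_level[is.finite(expr$rel_level)]
  breaks <- c(-Inf, rel_breaks, Inf)
  labs <- c(paste0("<", rel_breaks[1]),
            if (length(rel_breaks) > 1)
              paste0(rel_breaks[-length(rel_breaks)], "-", rel_breaks[-1]),
            paste0(">", rel_breaks[length(rel_breaks)]))
  frac <- as.numeric(table(cut(rel, breaks, right = FALSE)) / length(rel))
  names(frac) <- labs
  list(
    wt_hist = hist1(expr$wt_expr),
    de4_hist = hist1(expr$de4_expr),
    positive_fraction = mean(expr$positive, na.rm = TRUE),
    rel_fractions = frac,
    n = nrow(expr)
  )
}
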