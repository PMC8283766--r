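#' Gene model for a cassette-exon trio
#'
#' A \code{gene_model} describes the three exons involved in a cassette-exon
#' skipping event (the flanking exons and the skipped exon) on one strand of
#' one reference sequence, together with the two splice junctions they define:
#' the inclusion junction (donor of the upstream exon to acceptor of the
#' cassette exon) and the skipping junction (same donor to acceptor of the
#' downstream exon). Coordinates are stored 0-based half-open; all readers
#' normalize on input.
#'
#' @param reference_name Reference sequence name (e.g. \code{"chr20"}).
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons data.frame with columns \code{label}, \code{start}, \code{end}
#'   (0-based half-open), one row per exon, any order.
#' @param exon_labels Character vector of length 3 naming, in transcript
#'   order on the + strand, the upstream flanking exon, the cassette exon and
#'   the downstream flanking exon (default \code{c("E3","E4","E5")}).
#'
#' @return An object of class \code{gene_model} with fields
#'   \code{reference_name}, \code{strand}, \code{exons},
#'   \code{junction_inclusion} (donor, acceptor) and \code{junction_skip}.
#' @export
gene_model <- function(reference_name, strand = "+", exons,
                       exon_labels = c("E3", "E4", "E5")) {
  stopifnot(is.character(reference_name), length(reference_name) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- as.data.frame(exons)
  need <- c("label", "start", "end")
  if (!all(need %in% names(exons))) {
    stop("exons must have columns: ", paste(need, collapse = ", "))
  }
  if (length(exon_labels) != 3L) stop("exactly three exon labels required")
  missing <- setdiff(exon_labels, exons$label)
  if (length(missing)) {
    stop("exon(s) not found in gene model: ", paste(missing, collapse = ", "))
  }
  exons <- exons[match(exon_labels, exons$label), need, drop = FALSE]
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)
  if (any(!is.finite(exons$start)) || any(!is.finite(exons$end)) ||
      any(exons$end <= exons$start)) {
    stop("exon coordinates must be finite with end > start")
  }
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  # non-overlap in coordinate order
  if (any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("overlapping exons in gene model")
  }
  if (!identical(exons$label, exon_labels)) {
    stop("exons ", paste(exon_labels, collapse = "<"),
         " must be in coordinate order on the reference")
  }
  donor <- exons$end[1]
  obj <- structure(
    list(
      reference_name = reference_name,
      strand = strand,
      exons = exons,
      junction_inclusion = c(donor = donor, acceptor = exons$start[2]),
      junction_skip = c(donor = donor, acceptor = exons$start[3])
    ),
    class = "gene_model"
  )
  stopifnot(obj$junction_skip[["acceptor"]] > obj$junction_inclusion[["acceptor"]])
  obj
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model on", x$reference_name, "(", x$strand, ")\n")
  print(x$exons)
  cat(sprintf("inclusion junction: (%d, %d)\n",
              x$junction_inclusion[["donor"]], x$junction_inclusion[["acceptor"]]))
  cat(sprintf("skipping  junction: (%d, %d)\n",
              x$junction_skip[["donor"]], x$junction_skip[["acceptor"]]))
  invisible(x)
}

#' Load a gene model from GFF3, BED12 or a JSON exon table
#'
#' Reads exon coordinates for one gene from a standard annotation file and
#' derives the inclusion and skipping junctions from exon boundaries.
#' GFF3 exon records (1-based inclusive) and BED12 blocks (0-based half-open)
#' are converted to the internal 0-based half-open convention. The JSON
#' dialect is an object with \code{reference_name}, \code{strand} and an
#' \code{exons} array of \code{{label, start, end}} objects already 0-based
#' half-open.
#'
#' @param path Path to a \code{.gff3}/\code{.gff}, \code{.bed} or \code{.json}
#'   file; format inferred from extension.
#' @param gene_id Gene (GFF3 \code{Parent}/\code{gene_id} attribute, or BED
#'   \code{name} field) whose exons to extract. Ignored for JSON.
#' @param exon_labels Three exon labels in transcript order; for GFF3 these
#'   match the exon \code{Name}/\code{ID} attribute, for BED12 the blocks are
#'   labelled \code{E1, E2, ...} in coordinate order so labels select blocks.
#' @return A \code{\link{gene_model}}.
#' @export
load_gene_model <- function(path, gene_id = NULL,
                            exon_labels = c("E3", "E4", "E5")) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  exons <- switch(ext,
    json = return(.gene_model_from_json(path, exon_labels)),
    gff3 = ,
    gff = .exons_from_gff3(path, gene_id),
    bed = .exons_from_bed12(path, gene_id),
    stop("unsupported gene model format: .", ext,
         " (expected .json, .gff3/.gff or .bed)")
  )
  gene_model(exons$reference_name[1], exons$strand[1],
             exons[, c("label", "start", "end")], exon_labels)
}

.gene_model_from_json <- function(path, exon_labels) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("reference_name", "exons")) {
    if (is.null(j[[f]])) stop("JSON gene model missing field: ", f)
  }
  gene_model(j$reference_name, if (is.null(j$strand)) "+" else j$strand,
             as.data.frame(j$exons), exon_labels)
}

.exons_from_gff3 <- function(path, gene_id) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!is.null(gene_id)) {
    meta <- S4Vectors::mcols(ex)
    hit <- rep(FALSE, length(ex))
    for (col in intersect(c("Parent", "gene_id", "gene"), names(meta))) {
      v <- meta[[col]]
      if (methods::is(v, "List")) v <- vapply(v, function(z)
        paste(as.character(z), collapse = ","), character(1))
      hit <- hit | grepl(gene_id, as.character(v), fixed = TRUE)
    }
    ex <- ex[hit]
  }
  if (length(ex) == 0L) {
    stop("no exon records found in ", path,
         if (!is.null(gene_id)) paste0(" for gene '", gene_id, "'"))
  }
  meta <- S4Vectors::mcols(ex)
  lab <- NULL
  for (col in c("Name", "ID", "exon_id")) {
    if (col %in% names(meta) && !all(is.na(meta[[col]]))) {
      lab <- as.character(meta[[col]]); break
    }
  }
  if (is.null(lab)) lab <- paste0("E", seq_along(ex))
  data.frame(
    reference_name = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    label = lab,
    start = GenomicRanges::start(ex) - 1L,  # 1-based inclusive -> 0-based
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE
  )
}

.exons_from_bed12 <- function(path, gene_id) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(gene_id) && "name" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[gr$name == gene_id]
  }
  if (length(gr) == 0L) stop("gene '", gene_id, "' not found in ", path)
  if (length(gr) > 1L) stop("gene_id matches multiple BED records")
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks)) stop("BED record has no block structure (need BED12)")
  bl <- blocks[[1]]
  abs_start <- GenomicRanges::start(gr) - 1L + IRanges::start(bl) - 1L
  abs_end <- GenomicRanges::start(gr) - 1L + IRanges::end(bl)
  data.frame(
    reference_name = as.character(GenomicRanges::seqnames(gr)),
    strand = {
      s <- as.character(GenomicRanges::strand(gr))
      if (s == "*") "+" else s
    },
    label = paste0("E", seq_along(abs_start)),
    start = abs_start,
    end = abs_end,
    stringsAsFactors = FALSE
  )
}
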