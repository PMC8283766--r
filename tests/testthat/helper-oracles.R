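# Independent brute-force oracles and fixture builders.
# The SAM oracle below parses text records and walks CIGARs itself; it shares
# no code with the package's Rsamtools/GenomicAlignments-backed reader.

# Brute-force junction-read counter over a SAM text file.
oracle_count_junction <- function(sam_path, donor, acceptor, min_anchor = 3L) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  total <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 0x4) != 0 || bitwAnd(flag, 0x100) != 0 ||
        bitwAnd(flag, 0x400) != 0 || bitwAnd(flag, 0x800) != 0) next
    pos <- as.integer(f[4])
    cigar <- f[6]
    lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
    ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
    ref <- pos - 1L  # 0-based cursor
    left <- 0L
    matched <- FALSE
    for (k in seq_along(ops)) {
      op <- ops[k]; len <- lens[k]
      if (op %in% c("M", "=", "X")) {
        left <- left + len; ref <- ref + len
      } else if (op == "D") {
        ref <- ref + len; left <- 0L
      } else if (op == "N") {
        if (ref == donor && ref + len == acceptor) {
          right <- 0L
          for (j in seq_along(ops)[-seq_len(k)]) {
            if (ops[j] %in% c("M", "=", "X")) right <- right + lens[j]
            else if (ops[j] %in% c("D", "N")) break
          }
          if (left >= min_anchor && right >= min_anchor) matched <- TRUE
          break
        }
        ref <- ref + len; left <- 0L
      }
    }
    if (matched) total <- total + 1L
  }
  total
}

# Write a SAM file from explicit records (list of character vectors of the
# 11 mandatory fields), with a minimal header.
write_sam <- function(records, path, ref = "ref1", ref_len = 10000L) {
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", ref, ref_len),
    vapply(records, paste, character(1), collapse = "\t")
  ), path)
  path
}

sam_record <- function(qname, pos, cigar, flag = 0L, ref = "ref1",
                       seqlen = 100L) {
  c(qname, as.character(flag), ref, as.character(pos), "60", cigar, "*",
    "0", "0", strrep("A", seqlen), "*")
}

# Small three-exon fixture model: exons [100,200), [300,433), [500,600).
fixture_model <- function() {
  gene_model("ref1", "+",
             data.frame(label = c("E3", "E4", "E5"),
                        start = c(100L, 300L, 500L),
                        end = c(200L, 433L, 600L)))
}

# Closed-form simple-regression slope/intercept (oracle for lm-backed fits).
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = b, intercept = mean(y) - b * mean(x))
}
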