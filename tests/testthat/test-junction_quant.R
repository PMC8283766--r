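test_that("count_junction_reads: empty file, exact boundaries, flags", {
  gm <- fixture_model()
  empty <- write_sam(list(), withr::local_tempfile(fileext = ".sam"))
  expect_identical(count_junction_reads(empty, gm$junction_skip), 0L)

  # donor at 0-based 200 -> last exonic base is position 200 (1-based).
  # 50M300N50M starting at 1-based 151 gaps (200, 500); off-by-one gaps miss.
  recs <- list(
    sam_record("exact", 151, "50M300N50M"),
    sam_record("off_acceptor", 151, "50M299N50M"),   # gap (200, 499)
    sam_record("off_donor", 152, "50M300N50M"),      # gap (201, 501)
    sam_record("secondary", 151, "50M300N50M", flag = 0x100),
    sam_record("duplicate", 151, "50M300N50M", flag = 0x400),
    sam_record("unmapped", 151, "50M300N50M", flag = 0x4),
    sam_record("thin_anchor", 199, "2M300N98M")      # 2-base left anchor
  )
  p <- write_sam(recs, withr::local_tempfile(fileext = ".sam"))
  expect_identical(count_junction_reads(p, c(200, 500), min_anchor = 3), 1L)
  # relaxing the anchor admits the 2-base-overhang read
  expect_identical(count_junction_reads(p, c(200, 500), min_anchor = 2), 2L)
  expect_identical(count_junction_reads(p, c(200, 499), min_anchor = 3), 1L)
})

test_that("simulated 7-vs-13 file counts match the generator and oracle", {
  gm <- fixture_model()
  recs <- c(
    lapply(1:7, function(i)
      sam_record(sprintf("skip%02d", i), 161 + i, sprintf("%dM300N%dM",
                 40 - i, 60 + i))),
    lapply(1:13, function(i)
      sam_record(sprintf("incl%02d", i), 151 + i, sprintf("%dM100N%dM",
                 50 - i, 50 + i)))
  )
  p <- write_sam(recs, withr::local_tempfile(fileext = ".sam"))
  expect_identical(count_junction_reads(p, c(200, 500)), 7L)
  expect_identical(count_junction_reads(p, c(200, 300)), 13L)
  expect_identical(oracle_count_junction(p, 200, 500), 7L)
  expect_identical(oracle_count_junction(p, 200, 300), 13L)
})

test_that("counting is invariant to record order", {
  gm <- fixture_model()
  t1 <- withr::local_tempfile(fileext = ".sam")
  simulate_alignments(gm, t1, depth = 150, skip_fraction = 0.3, seed = 5)
  lines <- readLines(t1)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  t2 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(sub("SO:coordinate", "SO:unsorted", hdr), rev(body)), t2)
  expect_identical(count_junction_reads(t1, gm$junction_skip),
                   count_junction_reads(t2, gm$junction_skip))
})

test_that("skip_ratio arithmetic and undefined case", {
  expect_equal(skip_ratio(10, 0), 0)
  expect_equal(skip_ratio(0, 10), 1)
  expect_equal(skip_ratio(80, 20), 0.2)
  expect_true(is.na(skip_ratio(0, 0)))
  expect_error(skip_ratio(-1, 5), ">= 0")
})

test_that("exon3_deseq evaluates the scaling formula exactly", {
  expect_equal(exon3_deseq(0, 1000, 2000), 0)
  expect_equal(exon3_deseq(1000, 1000, 2000), 2000)
  expect_equal(exon3_deseq(50, 1000, 2000), 100)
  expect_error(exon3_deseq(10, 0, 500), "total_reads")
})

test_that("isoform_expression partitions expression and flags positivity", {
  a <- isoform_expression(0.0, 5000, 1000)
  expect_equal(a$wt_expr, 5000)
  expect_equal(a$de4_expr, 0)
  expect_false(a$positive)
  # boundary case: cutoff applied inclusively
  b <- isoform_expression(0.2, 5000, 1000)
  expect_equal(b$wt_expr, 4000)
  expect_equal(b$de4_expr, 1000)
  expect_true(b$positive)
  cc <- isoform_expression(0.5, 800, 1000)
  expect_equal(cc$de4_expr, 400)
  expect_false(cc$positive)
  expect_error(isoform_expression(1.2, 100), "\\[0, 1\\]")
})

test_that("conservation: wt + de4 equals normalized expression", {
  set.seed(42)
  for (i in 1:50) {
    sr <- runif(1)
    ne <- rlnorm(1, 8, 1)
    x <- isoform_expression(sr, ne)
    expect_equal(x$wt_expr + x$de4_expr, ne, tolerance = 1e-9)
  }
})

test_that("estimated skip_ratio converges to the simulated fraction", {
  gm <- fixture_model()
  sf <- 0.3
  prev <- -Inf
  for (depth in c(100L, 1000L, 10000L)) {
    p <- withr::local_tempfile(fileext = ".sam")
    simulate_alignments(gm, p, depth, sf, seed = 99)
    ni <- count_junction_reads(p, gm$junction_inclusion)
    ns <- count_junction_reads(p, gm$junction_skip)
    est <- skip_ratio(ni, ns)
    se <- sqrt(sf * (1 - sf) / depth)
    expect_lt(abs(est - sf), 3 * se)
  }
})

test_that("cohort_summary tabulates relative levels and positivity", {
  expr <- data.frame(wt_expr = c(2000, 2000), de4_expr = c(100, 300),
                     rel_level = c(0.05, 0.15), positive = c(FALSE, FALSE))
  s <- cohort_summary(expr, rel_breaks = c(0.10, 0.20))
  expect_equal(unname(s$rel_fractions), c(0.5, 0.5, 0.0))
  expr$positive <- TRUE
  expect_equal(cohort_summary(expr)$positive_fraction, 1.0)
  expect_error(cohort_summary(expr[0, ]), "empty")
  # histogram bins of thousands: counts land in the right bins
  h <- s$wt_hist
  expect_equal(sum(h$count), 2L)
  expect_equal(h$count[h$bin_lo == 2000], 2L)
})

test_that("positivity fraction recovers the generator's target rate", {
  # parameterize the skipping-isoform marginal so P(de4 >= 1000) = 0.42
  target <- 0.42
  sigma <- 1
  mu <- log(1000) - sigma * qnorm(1 - target)
  no_shift <- c(Luminal = 0, `HER2-enriched` = 0, TripleNegative = 0)
  sim <- simulate_cohort(n = 2000, mu_de4 = mu, sigma_de4 = sigma,
                         subtype_shifts = no_shift, seed = 55)
  e <- sim$expression
  expr <- data.frame(wt_expr = e$wt_expr, de4_expr = e$de4_expr,
                     rel_level = e$de4_expr / e$wt_expr,
                     positive = e$de4_expr >= 1000)
  s <- cohort_summary(expr)
  se <- sqrt(target * (1 - target) / 2000)
  expect_lt(abs(s$positive_fraction - target), 3 * se)
})
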