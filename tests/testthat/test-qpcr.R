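test_that("standard curve: perfect doubling gives 100% efficiency", {
  lg <- 2:6
  cq <- 38 - (1 / log10(2)) * lg  # slope -3.321928...
  sc <- fit_standard_curve(lg, cq)
  expect_equal(sc$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(sc$efficiency, 1.0, tolerance = 1e-9)
  expect_true(sc$valid)
  expect_equal(sc$r2, 1.0)
})

test_that("degenerate and noisy curves", {
  expect_false(fit_standard_curve(2:6, rep(25, 5))$valid)
  expect_error(fit_standard_curve(1:2, c(30, 27)), ">= 3")
  set.seed(8)
  lg <- 2:7
  cq <- 40 - 3.6 * lg + rnorm(6, 0, 0.15)
  sc <- fit_standard_curve(lg, cq)
  o <- oracle_ols(lg, cq)  # closed-form least squares
  expect_equal(sc$slope, unname(o["slope"]), tolerance = 1e-12)
  expect_equal(sc$intercept, unname(o["intercept"]), tolerance = 1e-12)
  expect_equal(sc$efficiency, 10^(-1 / sc$slope) - 1, tolerance = 1e-12)
  expect_lt(abs(sc$efficiency - (10^(1 / 3.6) - 1)), 0.05)
})

test_that("relative_expression: identities and efficiency correction", {
  expect_equal(relative_expression(20, 20), 1.0)
  expect_equal(relative_expression(21, 20), 0.5)  # one doubling behind
  expect_equal(relative_expression(21, 20, eff_target = 0.9, eff_ref = 1.0),
               1.9^(-21) / 2^(-20))
  expect_error(relative_expression(20, 20, eff_target = 0.5),
               "efficiency")
  # strictly decreasing in delta-Cq at equal efficiencies
  d <- seq(-3, 3, by = 0.5)
  v <- relative_expression(20 + d, 20)
  expect_true(all(diff(v) < 0))
})

test_that("copies_from_curve inverts the curve", {
  sc <- fit_standard_curve(2:6, 38 - (1 / log10(2)) * (2:6))
  expect_equal(copies_from_curve(sc$intercept, sc), 1, tolerance = 1e-9)
  expect_equal(copies_from_curve(sc$intercept + sc$slope, sc), 10,
               tolerance = 1e-9)
  # round trip through simulated noise-free Cq
  for (copies in c(50, 1234, 1e6)) {
    cq <- sc$intercept + sc$slope * log10(copies)
    expect_equal(copies_from_curve(cq, sc), copies, tolerance = 1e-6)
  }
  bad <- fit_standard_curve(2:6, rep(25, 5))
  expect_error(copies_from_curve(30, bad), "invalid")
})

test_that("aggregate_cq means replicates and respects the detection limit", {
  m <- data.frame(sample_id = "s1", primer_pair = "E3",
                  replicate = 1:3, cq = c(24.0, 24.4, 41))
  a <- aggregate_cq(m)
  expect_equal(a$cq, 24.2)
  expect_equal(a$n_detected, 2L)
  m$cq <- rep(40, 3)
  expect_true(is.na(aggregate_cq(m)$cq))
})

test_that("mixture validation: single-species, constant total, recovery", {
  designs <- data.frame(mixture_id = c("m1", "m2", "m3", "m4"),
                        copies_wt = c(1000, 600, 0, 800),
                        copies_de4 = c(0, 400, 1000, 200))
  q <- simulate_qpcr(designs, noise_sd = 0, seed = 2)
  curves <- lapply(split(q$dilutions, q$dilutions$primer_pair), function(d)
    fit_standard_curve(d$log10_copies, d$cq, d$primer_pair[1]))
  rep <- validate_mixture(designs, q$measurements, curves)
  # single-species mixtures: absent isoform back as non-detected (0 copies)
  expect_equal(rep$est_de4[rep$mixture_id == "m1"], 0)
  expect_equal(rep$est_wt[rep$mixture_id == "m3"], 0)
  expect_equal(rep$recovery_wt[rep$mixture_id == "m1"], 1, tolerance = 1e-6)
  expect_equal(rep$recovery_total[rep$mixture_id == "m1"], 1,
               tolerance = 1e-6)
  # constant-total series: common-exon estimate steady across mixtures
  expect_equal(diff(range(rep$est_total)), 0, tolerance = 1e-6 * 1000)
  expect_true(all(rep$pass))
  # noise-free recovery is exact to float precision
  expect_equal(rep$est_wt[rep$mixture_id == "m2"], 600, tolerance = 1e-6)
  expect_equal(rep$est_de4[rep$mixture_id == "m2"], 400, tolerance = 1e-6)
})

test_that("missing primer coverage is reported with the gap named", {
  designs <- data.frame(mixture_id = "m1", copies_wt = 100, copies_de4 = 100)
  q <- simulate_qpcr(designs, noise_sd = 0)
  curves <- lapply(split(q$dilutions, q$dilutions$primer_pair), function(d)
    fit_standard_curve(d$log10_copies, d$cq, d$primer_pair[1]))
  meas <- q$measurements[q$measurements$primer_pair != "E3-E5", ]
  expect_error(validate_mixture(designs, meas, curves), "E3-E5")
})

test_that("mixture recovery error shrinks as Cq noise shrinks", {
  designs <- data.frame(mixture_id = paste0("m", 1:5),
                        copies_wt = c(900, 700, 500, 300, 100),
                        copies_de4 = c(100, 300, 500, 700, 900))
  mare <- vapply(c(0.3, 0.05, 0), function(sd) {
    q <- simulate_qpcr(designs, noise_sd = sd, seed = 17)
    curves <- lapply(split(q$dilutions, q$dilutions$primer_pair), function(d)
      fit_standard_curve(d$log10_copies, d$cq, d$primer_pair[1]))
    rep <- validate_mixture(designs, q$measurements, curves)
    mean(abs(c(rep$recovery_wt, rep$recovery_de4) - 1), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mare) <= 1e-12))
  expect_lt(mare[3], 1e-10)
})
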