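test_that("Kaplan-Meier product-limit estimator on worked examples", {
  # all censored: flat at 1
  km0 <- km_estimate(c(2, 4, 8), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # three events: 2/3, 1/3, 0
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$survival, c(2 / 3, 1 / 3, 0))
  # one event at 5 among two samples
  km2 <- km_estimate(c(5, 10), c(1, 0))
  expect_equal(km2$survival[km2$time == 5], 0.5)
  # invariants: starts <= 1, non-increasing
  set.seed(4)
  km3 <- km_estimate(rexp(50, 0.1), rbinom(50, 1, 0.7))
  expect_true(all(diff(km3$survival) <= 1e-12))
  expect_error(km_estimate(-1, 1), "negative")
  # with no censoring the estimator equals the empirical survival function
  tt <- c(3, 1, 4, 1, 5, 9, 2, 6)
  km4 <- km_estimate(tt, rep(1, 8))
  expect_equal(km4$survival,
               vapply(km4$time, function(t) mean(tt > t), numeric(1)))
})

test_that("log-rank: null cases and a hand-computed risk table", {
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # worked example: A events at 1,2; B censored at 3,4
  # t=1: n=4, nA=2, d=1 -> E_A += 1/2, V += (1*3)/(16*3)*4 = 1/4
  # t=2: n=3, nA=1, d=1 -> E_A += 1/3, V += (1*2)/(9*2)*2  = 2/9
  # chi2 = (2 - 5/6)^2 / (17/36) = 49/17
  lr1 <- logrank_test(c(1, 2, 3, 4), c(1, 1, 0, 0),
                      c("A", "A", "B", "B"))
  expect_equal(lr1$chi2, 49 / 17, tolerance = 1e-12)
  expect_equal(lr1$observed, c(2, 0))
  expect_equal(lr1$expected, c(5 / 6, 7 / 6), tolerance = 1e-12)
  # three identical groups: df = 2, chi2 = 0
  lr2 <- logrank_test(rep(t0, 3), rep(e0, 3), rep(c("a", "b", "c"), each = 4))
  expect_equal(lr2$df, 2L)
  expect_equal(lr2$chi2, 0, tolerance = 1e-12)
  # invariant to time-unit rescaling
  set.seed(12)
  tm <- rexp(60, 0.1); ev <- rbinom(60, 1, 0.6); g <- rep(c("a", "b"), 30)
  expect_equal(logrank_test(tm, ev, g)$chi2,
               logrank_test(tm * 12, ev, g)$chi2, tolerance = 1e-12)
})

test_that("log-rank agrees with survival::survdiff (independent route)", {
  skip_if_not_installed("survival")
  set.seed(21)
  for (k in 2:3) {
    n <- 40 * k
    tm <- rexp(n, 0.05 * exp(0.4 * (seq_len(n) %% k)))
    ev <- as.integer(tm < 30); tm <- pmin(tm, 30)
    g <- factor(seq_len(n) %% k)
    lr <- logrank_test(tm, ev, g)
    sd <- survival::survdiff(survival::Surv(tm, ev) ~ g)
    expect_equal(lr$chi2, sd$chisq, tolerance = 1e-9)
  }
})

test_that("Cox fit matches survival::coxph with Efron ties", {
  skip_if_not_installed("survival")
  set.seed(33)
  n <- 150
  x1 <- rbinom(n, 1, 0.5); x2 <- rnorm(n)
  tm <- round(rexp(n, 0.05 * exp(0.8 * x1 - 0.3 * x2)), 1)  # induces ties
  ev <- as.integer(tm < 30); tm <- pmin(tm, 30)
  f <- cox_fit(tm, ev, cbind(g = x1, z = x2))
  g <- survival::coxph(survival::Surv(tm, ev) ~ x1 + x2, ties = "efron")
  expect_equal(unname(f$coef), unname(coef(g)), tolerance = 1e-7)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-7)
  expect_equal(f$loglik[2], g$loglik[2], tolerance = 1e-7)
  expect_true(f$ci_low[1] <= f$hr[1] && f$hr[1] <= f$ci_high[1])
})

test_that("Cox null case and score test vs log-rank on tie-free data", {
  set.seed(44)
  n <- 400
  g <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.05)          # no group effect, continuous => tie-free
  ev <- as.integer(tm < 40); tm <- pmin(tm, 40)
  f <- cox_fit(tm, ev, matrix(g, ncol = 1))
  expect_lt(abs(f$coef), 0.3)
  expect_true(f$ci_low <= 1 && f$ci_high >= 1)
  lr <- logrank_test(tm, ev, g)
  expect_equal(f$score_chi2, lr$chi2, tolerance = 1e-6)
})

test_that("monotone likelihood yields N/A with a reason, not a crash", {
  set.seed(55)
  tm <- c(rexp(25, 0.2), rep(60, 25))
  ev <- c(rep(1, 25), rep(0, 25))
  g <- rep(c(1, 0), each = 25)   # all events in group 1, none in group 0
  f <- cox_fit(tm, ev, matrix(g, ncol = 1))
  expect_false(f$converged)
  expect_true(nzchar(f$na_reason))
  expect_true(is.na(f$hr))
  expect_error(cox_fit(tm, ev, matrix(1, nrow = 50)), "constant")
})

test_that("pearson_corr and kruskal_wallis match base R oracles", {
  set.seed(66)
  x <- rnorm(50); y <- 0.6 * x + rnorm(50)
  pc <- pearson_corr(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_error(pearson_corr(x, rep(1, 50)), "variance")

  v <- c(1:9); g <- rep(1:3, each = 3)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$H, 7.2)  # brute-force rank computation: see below
  # oracle: ranks are the values themselves; H = 12/(n(n+1)) sum Rj^2/nj - 3(n+1)
  Rj <- tapply(rank(v), g, sum)
  expect_equal(kw$H, 12 / 90 * sum(Rj^2 / 3) - 30, tolerance = 1e-12)
  vt <- c(1, 1, 2, 2, 3, 3, 4, 4, 5); # with ties: compare to base R
  kb <- kruskal.test(vt, g)
  kwt <- kruskal_wallis(vt, g)
  expect_equal(kwt$H, unname(kb$statistic), tolerance = 1e-12)
  expect_equal(kwt$p, kb$p.value, tolerance = 1e-12)
  # identical groups and permutation invariance
  expect_equal(kruskal_wallis(rep(1, 6), rep(1:2, 3))$H, 0)
  perm <- c(2, 1, 3, 6, 5, 4, 9, 7, 8)  # shuffle within groups
  expect_equal(kruskal_wallis(v[perm], g)$H, kw$H)
})

test_that("follow-up truncation never increases events", {
  set.seed(77)
  tm <- rexp(200, 0.01); ev <- rbinom(200, 1, 0.8)
  tr <- truncate_followup(tm, ev, 120)
  expect_lte(sum(tr$event), sum(ev))
  expect_true(all(tr$time <= 120))
  # events inside the horizon are untouched
  keep <- tm <= 120
  expect_equal(tr$event[keep], ev[keep])
})
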