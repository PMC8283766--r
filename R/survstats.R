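#' Kaplan-Meier product-limit estimator
#'
#' @param time Follow-up times (months, >= 0).
#' @param event Event indicator: 1 = relapse, 0 = censored.
#' @return data.frame with one row per distinct event-or-censoring time:
#'   \code{time}, \code{n_risk}, \code{n_event}, \code{n_censor},
#'   \code{survival}. Survival starts at 1 and is non-increasing.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("need >= 1 sample")
  if (any(time < 0)) stop("negative follow-up time")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, survival = surv)
}

#' Log-rank test for k survival curves
#'
#' Standard (unweighted) log-rank statistic: per-group observed minus
#' expected events accumulated over the pooled risk sets, with the usual
#' hypergeometric variance; chi-square reference with k - 1 degrees of
#' freedom.
#'
#' @param time,event As in \code{\link{km_estimate}}.
#' @param group Group labels (factor or character), k >= 2 levels.
#' @return List: \code{chi2}, \code{df}, \code{p}, \code{observed},
#'   \code{expected} (named per group), \code{n} (group sizes).
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 2L) stop("need >= 2 non-empty groups")
  if (any(table(group) == 0)) stop("empty group")
  if (sum(event) == 0) stop("need >= 1 event overall")
  ut <- sort(unique(time[event == 1]))
  O <- tapply(event, group, sum)
  E <- stats::setNames(numeric(k), levels(group))
  # variance-covariance of (O - E) for the first k-1 groups
  V <- matrix(0, k - 1, k - 1)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    nj <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    E <- E + d * nj / n
    if (n > 1) {
      f <- d * (n - d) / (n^2 * (n - 1))
      for (i in seq_len(k - 1)) for (j in seq_len(k - 1)) {
        V[i, j] <- V[i, j] +
          f * (if (i == j) nj[i] * (n - nj[i]) else -nj[i] * nj[j])
      }
    }
  }
  omE <- (O - E)[seq_len(k - 1)]
  chi2 <- tryCatch(
    drop(t(omE) %*% solve(V, omE)),
    error = function(e) if (all(abs(omE) < 1e-12)) 0 else stop(e))
  list(chi2 = chi2, df = k - 1L,
       p = stats::pchisq(chi2, k - 1L, lower.tail = FALSE),
       observed = as.numeric(O), expected = as.numeric(E),
       n = as.numeric(table(group)))
}

#' Cox proportional-hazards model by maximum partial likelihood
#'
#' Newton-Raphson maximisation of the Cox partial likelihood with the Efron
#' approximation for tied event times. Reports per-covariate hazard ratios
#' with Wald 95\% confidence intervals and p-values. Monotone likelihood
#' (complete separation, e.g. one group with no events) is detected by
#' coefficient divergence and reported as an N/A result with a reason rather
#' than an error.
#'
#' @param time,event As in \code{\link{km_estimate}}.
#' @param x Numeric covariate matrix (samples x covariates) or vector for a
#'   univariate model. Factors must be coded numerically by the caller
#'   (e.g. high = 1, low = 0).
#' @param max_iter Newton iterations (default 30).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @return Object of class \code{cox_fit}: list with \code{coef},
#'   \code{se}, \code{hr}, \code{ci_low}, \code{ci_high}, \code{p},
#'   \code{loglik} (initial, final), \code{score_chi2} (score test at beta =
#'   0), \code{iter}, \code{converged}, \code{na_reason} (empty string when
#'   the fit is usable).
#' @export
cox_fit <- function(time, event, x, max_iter = 30L, tol = 1e-9) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (sum(event) == 0) stop("need >= 1 event")
  if (any(apply(x, 2, function(v) length(unique(v)) == 1L))) {
    stop("covariate constant across all samples")
  }
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord, , drop = FALSE]

  lp_fun <- function(beta) .cox_loglik(time, event, x, beta)
  beta <- rep(0, p)
  l0 <- lp_fun(beta)
  score_chi2 <- tryCatch(
    drop(t(l0$U) %*% solve(l0$I, l0$U)), error = function(e) NA_real_)
  ll_old <- l0$ll
  na_reason <- ""
  converged <- FALSE
  iter <- 0L
  cur <- l0
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) NULL)
    if (is.null(step)) { na_reason <- "singular information matrix"; break }
    beta_new <- beta + step
    # step-halving to keep the likelihood increasing
    h <- 0
    repeat {
      nxt <- lp_fun(beta_new)
      if (is.finite(nxt$ll) && nxt$ll >= ll_old - 1e-12) break
      h <- h + 1
      if (h > 20) break
      beta_new <- beta + (beta_new - beta) / 2
    }
    beta <- beta_new
    cur <- nxt
    if (any(abs(beta) > 18)) {
      na_reason <- paste0(
        "monotone partial likelihood (complete separation): coefficient ",
        "diverges; typically all cases censored in one group")
      break
    }
    if (abs(cur$ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      ll_old <- cur$ll
      break
    }
    ll_old <- cur$ll
  }
  if (!converged && na_reason == "") {
    na_reason <- "no convergence after max_iter Newton iterations"
  }
  if (na_reason == "") {
    se <- sqrt(diag(solve(cur$I)))
    if (any(!is.finite(se)) || any(se > 1e3)) {
      na_reason <- "non-finite standard error (monotone likelihood)"
    }
  }
  if (na_reason != "") {
    est <- rep(NA_real_, p)
    out <- list(coef = est, se = est, hr = est, ci_low = est, ci_high = est,
                p = est, loglik = c(l0$ll, cur$ll), score_chi2 = score_chi2,
                iter = iter, converged = FALSE, na_reason = na_reason)
  } else {
    z <- beta / se
    out <- list(
      coef = stats::setNames(beta, colnames(x)),
      se = se,
      hr = exp(beta),
      ci_low = exp(beta - 1.959964 * se),
      ci_high = exp(beta + 1.959964 * se),
      p = 2 * stats::pnorm(-abs(z)),
      loglik = c(l0$ll, cur$ll),
      score_chi2 = score_chi2,
      iter = iter, converged = TRUE, na_reason = ""
    )
  }
  class(out) <- "cox_fit"
  out
}

# Efron partial log-likelihood, score and information at beta.
# Assumes records sorted by time.
.cox_loglik <- function(time, event, x, beta) {
  n <- nrow(x); p <- ncol(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  ut <- unique(time[event == 1])
  for (t in ut) {
    risk <- which(time >= t)
    dead <- which(time == t & event == 1)
    d <- length(dead)
    S0 <- sum(w[risk])
    S1 <- colSums(x[risk, , drop = FALSE] * w[risk])
    S2 <- crossprod(x[risk, , drop = FALSE] * sqrt(w[risk]))
    s0d <- sum(w[dead])
    s1d <- colSums(x[dead, , drop = FALSE] * w[dead])
    s2d <- crossprod(x[dead, , drop = FALSE] * sqrt(w[dead]))
    ll <- ll + sum(eta[dead])
    for (l in seq_len(d) - 1) {
      f <- l / d
      denom <- S0 - f * s0d
      num1 <- S1 - f * s1d
      num2 <- S2 - f * s2d
      ll <- ll - log(denom)
      U <- U - num1 / denom
      I <- I + num2 / denom - tcrossprod(num1 / denom)
    }
    U <- U + colSums(x[dead, , drop = FALSE])
  }
  list(ll = ll, U = U, I = I)
}

#' @export
print.cox_fit <- function(x, ...) {
  if (x$na_reason != "") {
    cat("cox_fit: N/A (", x$na_reason, ")\n", sep = "")
  } else {
    df <- data.frame(coef = x$coef, HR = x$hr, lower95 = x$ci_low,
                     upper95 = x$ci_high, p = x$p)
    print(df)
  }
  invisible(x)
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y Numeric vectors, n >= 3, finite.
#' @return List: \code{r}, \code{p} (two-sided, t with n - 2 df), \code{n}.
#' @export
pearson_corr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need >= 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Kruskal-Wallis rank-sum test with tie correction
#'
#' @param values Numeric response.
#' @param group Group labels, k >= 2 non-empty groups.
#' @return List: \code{H} (tie-corrected statistic), \code{df}, \code{p}.
#' @export
kruskal_wallis <- function(values, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 2L || any(table(group) == 0)) stop("need >= 2 non-empty groups")
  n <- length(values)
  r <- rank(values)
  Rj <- tapply(r, group, sum)
  nj <- tapply(r, group, length)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (C == 0) return(list(H = 0, df = k - 1L, p = 1))  # all values identical
  H <- H / C
  list(H = H, df = k - 1L,
       p = stats::pchisq(H, k - 1L, lower.tail = FALSE))
}
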