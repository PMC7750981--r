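#' Instrument-free exposure residuals
#'
#' Residuals from a linear regression of the exposure on the genetic score
#' (plus covariates). Stratifying on these residuals rather than the raw
#' exposure avoids the collider bias that stratifying on an
#' instrument-influenced variable would induce. By OLS orthogonality the
#' residuals are exactly uncorrelated with the score in-sample.
#'
#' @inheritParams fit_first_stage
#' @return Numeric residual vector, one entry per cohort row.
#' @export
iv_free_exposure <- function(cohort, score = "score", exposure = "exposure",
                             covariates = NULL) {
  s <- cohort[[score]]
  if (stats::sd(s) == 0) stop("instrument has no variance", call. = FALSE)
  xc <- covariate_matrix(cohort, covariates)
  stats::lm.fit(cbind(xc, score = s), cohort[[exposure]])$residuals
}

#' Assign individuals to quantile strata of a residual vector
#'
#' Cuts the sample into `k` near-equal groups by rank of the residuals
#' (ties broken by stable input order), so per-stratum counts differ by at
#' most 1. Reported stratum boundaries are the observed exposure quantiles
#' at the stratum edges, giving the natural-unit range labels attached to
#' each stratum.
#'
#' @param residuals Instrument-free exposure residuals.
#' @param k Number of strata (default 10, i.e. deciles).
#' @param exposure Optional observed exposure vector used for the reported
#'   boundary values (defaults to the residuals themselves).
#' @return List with `stratum` (integer labels 1..k) and `ranges`, a
#'   `data.frame` of `stratum`, `low`, `high`.
#' @export
assign_strata <- function(residuals, k = 10L, exposure = residuals) {
  n <- length(residuals)
  if (n < 10L * k) {
    stop("need at least 10 * k observations to form ", k, " strata",
         call. = FALSE)
  }
  o <- order(residuals)  # stable: ties keep input order
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stratum <- integer(n)
  stratum[o] <- rep(seq_len(k), times = sizes)
  edges <- stats::quantile(exposure, probs = seq(0, 1, length.out = k + 1),
                           names = FALSE)
  ranges <- data.frame(stratum = seq_len(k), low = edges[-(k + 1)],
                       high = edges[-1])
  list(stratum = stratum, ranges = ranges)
}

#' Localized average causal effect within one stratum
#'
#' The ratio of the stratum-specific score-outcome association (linear or
#' logistic, covariate-adjusted) to the score-exposure association, with a
#' delta-method standard error that treats the denominator as estimated:
#' `se^2 = se_num^2 / den^2 + num^2 * se_den^2 / den^4`. By default the
#' denominator is the full-sample first-stage coefficient (assumed
#' homogeneous across strata); pass a stratum-specific first stage for
#' sensitivity analyses.
#'
#' @inheritParams tsls_continuous
#' @param cohort_stratum Cohort rows belonging to the stratum.
#' @param first_stage A `first_stage` object (normally fit on the full
#'   sample) supplying the denominator and its SE.
#' @param family `"linear"` or `"logistic"` for the stratum association.
#' @return List with `lace`, `se`, `n`, and the numerator/denominator
#'   pieces.
#' @export
stratum_lace <- function(cohort_stratum, first_stage, outcome,
                         score = "score", covariates = c("age", "sex"),
                         family = c("linear", "logistic")) {
  family <- match.arg(family)
  dat <- drop_incomplete(cohort_stratum, c(outcome, score, covariates))
  n <- nrow(dat)
  xc <- covariate_matrix(dat, covariates)
  if (n <= ncol(xc) + 2L) stop("stratum too small", call. = FALSE)
  M <- cbind(xc, score = dat[[score]])
  if (family == "linear") {
    fit <- stats::lm.fit(M, dat[[outcome]])
    num <- fit$coefficients["score"]
    sigma2 <- sum(fit$residuals^2) / (n - ncol(M))
    se_num <- sqrt(sigma2 * solve(crossprod(M))["score", "score"])
  } else {
    fit <- stats::glm.fit(M, dat[[outcome]], family = stats::binomial())
    num <- fit$coefficients["score"]
    se_num <- sqrt(solve(crossprod(M * sqrt(fit$weights)))["score", "score"])
  }
  den <- first_stage$coef
  se_den <- first_stage$se
  if (abs(den / se_den) < 2) {
    warning("weak LACE denominator: |z| < 2", call. = FALSE)
  }
  lace <- unname(num / den)
  se <- sqrt(se_num^2 / den^2 + num^2 * se_den^2 / den^4)
  list(lace = lace, se = unname(se), n = n, num = unname(num),
       se_num = unname(se_num), den = den, se_den = se_den)
}

#' Piecewise-linear effect curve from stratum estimates
#'
#' Treats each stratum's LACE as the local slope of the exposure-outcome
#' relation on that stratum's exposure range and integrates across strata,
#' anchoring the curve to 0 at the reference knot. The curve is continuous
#' by construction; shifting the reference translates every knot by a
#' constant.
#'
#' @param strata `data.frame` with columns `low`, `high`, `lace` (one row
#'   per ordered stratum).
#' @param reference Exposure value at which the curve is anchored to zero
#'   (default: the lowest knot).
#' @return `data.frame` of `k + 1` knots: `exposure`, `effect`.
#' @export
piecewise_curve <- function(strata, reference = NULL) {
  stopifnot(!is.unsorted(strata$low))
  knots_x <- c(strata$low, strata$high[nrow(strata)])
  widths <- strata$high - strata$low
  effect <- c(0, cumsum(strata$lace * widths))
  if (is.null(reference)) reference <- knots_x[1]
  ref_val <- stats::approx(knots_x, effect, xout = reference, rule = 2)$y
  data.frame(exposure = knots_x, effect = effect - ref_val)
}

#' Tests of non-linearity across stratum estimates
#'
#' `p_quadratic` comes from an inverse-variance-weighted meta-regression of
#' the stratum LACEs on mean stratum exposure (two-sided normal test of
#' zero slope); `p_cochran_q` from the heterogeneity statistic
#' `Q = sum(w_i * (lace_i - lace_ivw)^2)` against chi-square(K - 1).
#'
#' @param strata `data.frame` with `lace`, `se`, `mean_exposure` (K >= 3
#'   rows).
#' @return List with `p_quadratic`, `p_cochran_q`, `q`, `meta_slope`,
#'   `meta_slope_se`.
#' @export
test_nonlinearity <- function(strata) {
  k <- nrow(strata)
  if (k < 3L) stop("need at least 3 strata", call. = FALSE)
  if (any(strata$se == 0)) stop("stratum SEs must be positive", call. = FALSE)
  w <- 1 / strata$se^2
  b <- strata$lace
  # Cochran Q around the IVW pooled effect
  pooled <- sum(w * b) / sum(w)
  q <- sum(w * (b - pooled)^2)
  p_q <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  # fixed-effect meta-regression on mean exposure
  x <- strata$mean_exposure
  xw <- sum(w * x) / sum(w)
  sxx <- sum(w * (x - xw)^2)
  slope <- sum(w * (x - xw) * b) / sxx
  se_slope <- sqrt(1 / sxx)
  p_quad <- 2 * stats::pnorm(-abs(slope / se_slope))
  list(p_quadratic = p_quad, p_cochran_q = p_q, q = q,
       meta_slope = slope, meta_slope_se = se_slope)
}

#' Non-linear MR over instrument-free exposure strata
#'
#' End-to-end driver: computes instrument-free residuals, cuts the sample
#' into `k` strata, estimates a localized causal effect in each (numerator:
#' stratum score-outcome association; denominator: full-sample first-stage
#' coefficient), reconstructs the piecewise-linear effect curve, and tests
#' non-linearity. With `k = 1` the single LACE is exactly the linear IV
#' (ratio) estimate.
#'
#' @inheritParams tsls_continuous
#' @param k Number of strata (default 10).
#' @param family `"linear"` or `"logistic"`.
#' @param per_stratum_denominator Use stratum-specific first stages for the
#'   LACE denominators (sensitivity option; default `FALSE`).
#' @param reference Exposure value anchoring the effect curve at zero
#'   (default: the lowest knot).
#' @return List of class `nonlinear_mr`: `strata` (a `data.frame` with
#'   ranges, mean exposure, `lace`, `se`, `n`), `curve`, `p_quadratic`,
#'   `p_cochran_q`.
#' @export
nonlinear_mr <- function(cohort, outcome, score = "score",
                         exposure = "exposure",
                         covariates = c("age", "sex"), k = 10L,
                         family = c("linear", "logistic"),
                         per_stratum_denominator = FALSE,
                         reference = NULL) {
  family <- match.arg(family)
  cohort <- drop_incomplete(cohort, c(outcome, score, exposure, covariates))
  res <- iv_free_exposure(cohort, score, exposure, covariates)
  st <- assign_strata(res, k = k, exposure = cohort[[exposure]])
  fs_full <- fit_first_stage(cohort, score, exposure, covariates)
  rows <- lapply(seq_len(k), function(i) {
    sub <- cohort[st$stratum == i, , drop = FALSE]
    fs <- if (per_stratum_denominator) {
      fit_first_stage(sub, score, exposure, covariates)
    } else fs_full
    l <- stratum_lace(sub, fs, outcome, score, covariates, family)
    data.frame(stratum = i, low = st$ranges$low[i],
               high = st$ranges$high[i],
               mean_exposure = mean(sub[[exposure]]),
               lace = l$lace, se = l$se, n = l$n)
  })
  strata <- do.call(rbind, rows)
  out <- list(strata = strata,
              curve = piecewise_curve(strata, reference = reference),
              first_stage = fs_full)
  if (k >= 3L) {
    nl <- test_nonlinearity(strata)
    out$p_quadratic <- nl$p_quadratic
    out$p_cochran_q <- nl$p_cochran_q
  }
  class(out) <- "nonlinear_mr"
  out
}
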