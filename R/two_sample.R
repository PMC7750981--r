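#' Per-variant summary statistics from individual-level data
#'
#' Regresses the exposure and an outcome on each variant's dosage in turn
#' (covariate-adjusted; logistic for binary outcomes), yielding the
#' variant-exposure and variant-outcome effect pairs consumed by the
#' summary-statistic estimators. When computed on the same sample as the
#' main analysis this carries the usual sample-overlap caveat.
#'
#' @param genotypes Individuals x variants dosage matrix (aligned).
#' @param cohort Cohort `data.frame` in the same row order.
#' @param outcome,exposure Column names.
#' @param covariates Covariate column names.
#' @param family `"linear"` or `"logistic"` for the outcome regressions.
#' @return `data.frame` with `variant_id`, `beta_gx`, `se_gx`, `beta_gy`,
#'   `se_gy`.
#' @export
variant_summary_stats <- function(genotypes, cohort, outcome,
                                  exposure = "exposure",
                                  covariates = c("age", "sex"),
                                  family = c("linear", "logistic")) {
  family <- match.arg(family)
  stopifnot(nrow(genotypes) == nrow(cohort))
  xc <- covariate_matrix(cohort, covariates)
  x <- cohort[[exposure]]
  y <- cohort[[outcome]]
  m <- ncol(genotypes)
  bx <- sx <- by <- sy <- numeric(m)
  n <- nrow(cohort)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    M <- cbind(xc, g = g)
    fx <- stats::lm.fit(M, x)
    xtx_inv <- solve(crossprod(M))["g", "g"]
    bx[j] <- fx$coefficients["g"]
    sx[j] <- sqrt(sum(fx$residuals^2) / (n - ncol(M)) * xtx_inv)
    if (family == "linear") {
      fy <- stats::lm.fit(M, y)
      by[j] <- fy$coefficients["g"]
      sy[j] <- sqrt(sum(fy$residuals^2) / (n - ncol(M)) * xtx_inv)
    } else {
      fy <- stats::glm.fit(M, y, family = stats::binomial())
      by[j] <- fy$coefficients["g"]
      w <- fy$weights
      vj <- solve(crossprod(M * sqrt(w)))["g", "g"]
      sy[j] <- sqrt(vj)
    }
  }
  data.frame(variant_id = colnames(genotypes), beta_gx = bx, se_gx = sx,
             beta_gy = by, se_gy = sy, stringsAsFactors = FALSE)
}

#' Harmonize summary statistics to the exposure-raising allele
#'
#' Negates both effect estimates of any variant whose variant-exposure
#' effect is negative, so every `beta_gx` is non-negative afterwards.
#' Standard errors are unchanged and per-variant Wald ratios are invariant.
#'
#' @param summary `data.frame` with `beta_gx`, `se_gx`, `beta_gy`, `se_gy`.
#' @return The harmonized `data.frame`.
#' @export
harmonize_summary <- function(summary) {
  flip <- summary$beta_gx < 0
  summary$beta_gx[flip] <- -summary$beta_gx[flip]
  summary$beta_gy[flip] <- -summary$beta_gy[flip]
  summary
}

check_summary <- function(summary, min_variants) {
  stopifnot(all(c("beta_gx", "se_gx", "beta_gy", "se_gy") %in%
                  names(summary)))
  if (any(summary$se_gx <= 0) || any(summary$se_gy <= 0)) {
    stop("all summary-statistic SEs must be positive", call. = FALSE)
  }
  if (nrow(summary) < min_variants) {
    stop("at least ", min_variants, " variants are required", call. = FALSE)
  }
  invisible(summary)
}

#' Wald ratio for a single variant
#'
#' `beta_gy / beta_gx`, with a first-order delta-method standard error
#' `se_gy / |beta_gx|`.
#'
#' @param beta_gx,se_gx Variant-exposure effect and SE.
#' @param beta_gy,se_gy Variant-outcome effect and SE.
#' @return List with `beta` and `se`.
#' @export
wald_ratio <- function(beta_gx, se_gx, beta_gy, se_gy) {
  if (beta_gx == 0) stop("beta_gx is zero; ratio undefined", call. = FALSE)
  list(beta = beta_gy / beta_gx, se = se_gy / abs(beta_gx))
}

#' Inverse-variance weighted estimator
#'
#' Slope of the variant-outcome effects on the variant-exposure effects
#' through the origin, weighted by `1 / se_gy^2`. The default standard
#' error is fixed-effect, `1 / sqrt(sum(w * beta_gx^2))`; with
#' `random_effects = TRUE` it is inflated by the multiplicative
#' overdispersion factor `max(1, sqrt(Q / (m - 1)))`.
#'
#' @param summary Harmonized summary statistics (>= 2 variants).
#' @param random_effects Use the multiplicative random-effects SE.
#' @param outcome Label for the result row.
#' @return An [estimate_record()] with method `"ivw"`.
#' @export
mr_ivw <- function(summary, random_effects = FALSE, outcome = "outcome") {
  check_summary(summary, 2L)
  w <- 1 / summary$se_gy^2
  bx <- summary$beta_gx
  by <- summary$beta_gy
  sxx <- sum(w * bx^2)
  slope <- sum(w * bx * by) / sxx
  se <- sqrt(1 / sxx)
  if (random_effects) {
    q <- sum(w * (by - slope * bx)^2)
    se <- se * max(1, sqrt(q / (nrow(summary) - 1)))
  }
  estimate_record(outcome, "ivw", beta = slope, se = se, n = nrow(summary))
}

#' MR-Egger regression
#'
#' Weighted regression of variant-outcome on variant-exposure effects with a
#' free intercept (weights `1 / se_gy^2`). A non-zero intercept indicates
#' directional pleiotropy; the slope is the pleiotropy-adjusted causal
#' effect. Standard errors use the multiplicative overdispersion convention
#' (residual sigma floored at 1) with t(m - 2) p-values.
#'
#' @param summary Harmonized summary statistics (>= 3 variants).
#' @param outcome Label for the result rows.
#' @return List with `slope` and `intercept`, both [estimate_record()]s
#'   (methods `"egger_slope"`, `"egger_intercept"`).
#' @export
mr_egger <- function(summary, outcome = "outcome") {
  check_summary(summary, 3L)
  if (stats::sd(summary$beta_gx) == 0) {
    stop("no spread in beta_gx; Egger regression undefined", call. = FALSE)
  }
  m <- nrow(summary)
  w <- 1 / summary$se_gy^2
  fit <- stats::lm(beta_gy ~ beta_gx, data = summary, weights = w)
  sm <- summary(fit)
  sigma <- max(1, sm$sigma)
  cf <- sm$coefficients
  se_int <- cf[1, 2] / sm$sigma * sigma
  se_slo <- cf[2, 2] / sm$sigma * sigma
  mk <- function(b, s, meth) {
    r <- estimate_record(outcome, meth, beta = b, se = s, n = m)
    r$p <- 2 * stats::pt(-abs(b / s), df = m - 2)  # t-based, Egger convention
    r
  }
  list(slope = mk(cf[2, 1], se_slo, "egger_slope"),
       intercept = mk(cf[1, 1], se_int, "egger_intercept"))
}

# Weighted median of x with weights w (Bowden interpolation form).
weighted_median_value <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  i <- max(which(cw < 0.5))
  x[i] + (x[i + 1] - x[i]) * (0.5 - cw[i]) / (cw[i + 1] - cw[i])
}

#' Weighted-median estimator
#'
#' Weighted median of the per-variant Wald ratios, with inverse-variance
#' weights from the delta-method ratio variance; consistent when at least
#' half the weight comes from valid instruments. The standard error is a
#' parametric bootstrap (normal perturbation of both effect vectors) with a
#' fixed seed.
#'
#' @param summary Harmonized summary statistics (>= 3 variants).
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Bootstrap seed.
#' @param outcome Label for the result row.
#' @return An [estimate_record()] with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(summary, n_boot = 1000L, seed = 1L,
                               outcome = "outcome") {
  check_summary(summary, 3L)
  drop0 <- summary$beta_gx == 0
  if (any(drop0)) {
    warning(sum(drop0), " variant(s) with beta_gx = 0 dropped",
            call. = FALSE)
    summary <- summary[!drop0, , drop = FALSE]
    check_summary(summary, 3L)
  }
  ratio <- summary$beta_gy / summary$beta_gx
  var_ratio <- summary$se_gy^2 / summary$beta_gx^2 +
    summary$beta_gy^2 * summary$se_gx^2 / summary$beta_gx^4
  w <- 1 / var_ratio
  est <- weighted_median_value(ratio, w)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  m <- nrow(summary)
  boot <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(m, summary$beta_gx, summary$se_gx)
    by <- stats::rnorm(m, summary$beta_gy, summary$se_gy)
    keep <- bx != 0
    r <- by[keep] / bx[keep]
    v <- summary$se_gy[keep]^2 / bx[keep]^2 +
      by[keep]^2 * summary$se_gx[keep]^2 / bx[keep]^4
    weighted_median_value(r, 1 / v)
  }, numeric(1))
  se <- stats::sd(boot)
  if (se == 0) se = .Machine$double.eps
  estimate_record(outcome, "weighted_median", beta = est, se = se, n = m)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
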