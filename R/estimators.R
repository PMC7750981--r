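#' Construct a tidy effect-estimate record
#'
#' The universal result currency of the package: one row per estimate, with
#' Wald 95% confidence limits (`beta +/- 1.96 * se`) and a two-sided normal
#' p-value.
#'
#' @param outcome,method,subgroup,scale Character labels.
#' @param beta,se Point estimate and standard error (`se > 0`).
#' @param n Analysis sample size.
#' @return One-row `data.frame` of class `estimate_record`.
#' @export
estimate_record <- function(outcome, method, beta, se, n,
                            scale = "per-SD beta", subgroup = "all") {
  beta <- unname(beta)
  se <- unname(se)
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  z <- beta / se
  rec <- data.frame(
    outcome = outcome, method = method, subgroup = subgroup, scale = scale,
    beta = beta, se = se,
    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
    p = 2 * stats::pnorm(-abs(z)), n = as.integer(n),
    stringsAsFactors = FALSE
  )
  class(rec) <- c("estimate_record", "data.frame")
  rec
}

# Covariates that are constant in the analysis sample (e.g. sex inside a
# sex-stratified subgroup) are absorbed by the intercept and dropped.
usable_covariates <- function(cohort, covariates) {
  if (is.null(covariates) || length(covariates) == 0L) return(NULL)
  covariates[vapply(covariates, function(v) {
    length(unique(cohort[[v]][!is.na(cohort[[v]])])) > 1L
  }, logical(1))]
}

# Model matrix for a covariate name set (intercept included).
covariate_matrix <- function(cohort, covariates) {
  covariates <- usable_covariates(cohort, covariates)
  if (is.null(covariates) || length(covariates) == 0L) {
    return(matrix(1, nrow(cohort), 1, dimnames = list(NULL, "(Intercept)")))
  }
  mm <- stats::model.matrix(stats::reformulate(covariates),
                            data = cohort[, covariates, drop = FALSE])
  if (nrow(mm) != nrow(cohort)) {
    stop("missing values in covariates; filter the cohort first",
         call. = FALSE)
  }
  mm
}

drop_incomplete <- function(cohort, cols) {
  cohort[stats::complete.cases(cohort[, cols, drop = FALSE]), , drop = FALSE]
}

#' Observational regression of an outcome on the exposure
#'
#' Linear (continuous outcome) or logistic (binary outcome) regression of
#' the outcome on the exposure plus covariates; the reported coefficient is
#' the per-unit (conventionally per-SD) exposure effect, on the log-odds
#' scale for logistic fits.
#'
#' @param cohort Cohort `data.frame`.
#' @param outcome,exposure Column names.
#' @param covariates Character vector of covariate column names (default
#'   age and sex).
#' @param family `"linear"` or `"logistic"`.
#' @param subgroup Label recorded in the result.
#' @return An [estimate_record()].
#' @export
fit_observational <- function(cohort, outcome, exposure = "exposure",
                              covariates = c("age", "sex"),
                              family = c("linear", "logistic"),
                              subgroup = "all") {
  family <- match.arg(family)
  cohort <- drop_incomplete(cohort, c(outcome, exposure, covariates))
  y <- cohort[[outcome]]
  if (family == "logistic" && !all(y %in% c(0, 1))) {
    stop("logistic family requires a 0/1 outcome", call. = FALSE)
  }
  covariates <- usable_covariates(cohort, covariates)
  fml <- stats::reformulate(c(exposure, covariates), response = outcome)
  if (family == "linear") {
    fit <- stats::lm(fml, data = cohort)
  } else {
    if (length(unique(y)) < 2L) {
      stop("degenerate binary outcome (single level)", call. = FALSE)
    }
    fit <- stats::glm(fml, data = cohort, family = stats::binomial())
    if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  if (!(exposure %in% rownames(sm))) {
    stop("rank-deficient model: exposure coefficient not estimable",
         call. = FALSE)
  }
  estimate_record(
    outcome = outcome, method = "observational",
    beta = sm[exposure, 1], se = sm[exposure, 2], n = nrow(cohort),
    scale = if (family == "linear") "per-SD beta" else "per-SD log-OR",
    subgroup = subgroup
  )
}

#' First-stage regression of the exposure on the instrument
#'
#' Linear regression of the exposure on the genetic score plus covariates,
#' giving the genotype-predicted exposure used by the two-stage estimators
#' and the partial F of the score term.
#'
#' @inheritParams fit_observational
#' @param score Column name of the instrument (genetic risk score).
#' @return A list of class `first_stage`: `fitted` values, `coef` of the
#'   score, `se`, `f` (partial F), `n`, and the residuals.
#' @export
fit_first_stage <- function(cohort, score = "score", exposure = "exposure",
                            covariates = c("age", "sex")) {
  cohort <- drop_incomplete(cohort, c(score, exposure, covariates))
  s <- cohort[[score]]
  if (stats::sd(s) == 0) stop("instrument has no variance", call. = FALSE)
  n <- nrow(cohort)
  xc <- covariate_matrix(cohort, covariates)
  if (n <= ncol(xc) + 1L) stop("too few observations", call. = FALSE)
  M <- cbind(xc, score = s)
  fit <- stats::lm.fit(M, cohort[[exposure]])
  cf <- fit$coefficients["score"]
  res <- fit$residuals
  sigma2 <- sum(res^2) / (n - ncol(M))
  xtx_inv <- solve(crossprod(M))
  se <- sqrt(sigma2 * xtx_inv["score", "score"])
  out <- list(fitted = cohort[[exposure]] - res, coef = unname(cf),
              se = unname(se), f = unname((cf / se)^2), n = n,
              residuals = res)
  class(out) <- "first_stage"
  out
}

# Just-identified IV fit: y on [x_endog, exog] instrumented by
# [z, exog]; robust (HC1) or cluster-robust sandwich SEs computed from
# residuals using the OBSERVED endogenous regressor.
iv_fit <- function(y, x_endog, z, exog, cluster = NULL) {
  n <- length(y)
  X <- cbind(endog = x_endog, exog)
  Z <- cbind(z = z, exog)
  k <- ncol(X)
  ztx <- crossprod(Z, X)
  beta <- solve(ztx, crossprod(Z, y))
  e <- drop(y - X %*% beta)
  bread <- solve(ztx)
  ze <- Z * e
  if (is.null(cluster)) {
    meat <- crossprod(ze) * n / (n - k)
  } else {
    zs <- rowsum(ze, cluster)
    g <- nrow(zs)
    meat <- crossprod(zs) * (g / (g - 1)) * ((n - 1) / (n - k))
  }
  V <- bread %*% meat %*% t(bread)
  list(beta = drop(beta), vcov = V, se = sqrt(diag(V)), n = n,
       residuals = e)
}

#' Two-stage least squares for a continuous outcome
#'
#' Instrumental-variable estimate of the causal effect of the exposure on a
#' continuous outcome, using the genetic score as the single instrument and
#' adjusting for covariates in both stages. Standard errors are the proper
#' 2SLS sandwich: residuals are computed with the observed (not fitted)
#' exposure, and the default is heteroskedasticity-robust HC1 (or
#' cluster-robust when `cluster` is given).
#'
#' @inheritParams fit_first_stage
#' @param outcome Continuous outcome column name.
#' @param f_floor First-stage partial F below which a weak-instrument
#'   warning (not an error) is raised (default 10).
#' @param cluster Optional clustering column name for the sandwich SE.
#' @param subgroup Label recorded in the result.
#' @return An [estimate_record()] with method `"tsls"`.
#' @export
tsls_continuous <- function(cohort, outcome, score = "score",
                            exposure = "exposure",
                            covariates = c("age", "sex"),
                            f_floor = 10, cluster = NULL, subgroup = "all") {
  cohort <- drop_incomplete(cohort, c(outcome, score, exposure, covariates))
  fs <- fit_first_stage(cohort, score, exposure, covariates)
  if (fs$f < f_floor) {
    warning(sprintf("weak instrument: first-stage F = %.2f < %.0f",
                    fs$f, f_floor), call. = FALSE)
  }
  exog <- covariate_matrix(cohort, covariates)
  fit <- iv_fit(cohort[[outcome]], cohort[[exposure]], cohort[[score]],
                exog,
                cluster = if (is.null(cluster)) NULL else cohort[[cluster]])
  estimate_record(outcome, "tsls", beta = fit$beta["endog"],
                  se = fit$se["endog"], n = fit$n, subgroup = subgroup)
}

#' Two-stage estimator for a binary outcome ("2SPS")
#'
#' Logistic regression of the binary outcome on the genotype-predicted
#' exposure (the first-stage fitted values) plus covariates, with robust
#' sandwich standard errors; the reported effect is the log-odds ratio per
#' unit (per SD) of exposure.
#'
#' @inheritParams tsls_continuous
#' @param outcome Binary 0/1 outcome column name.
#' @return An [estimate_record()] with method `"two_stage_logistic"` on the
#'   log-OR scale.
#' @export
two_stage_logistic <- function(cohort, outcome, score = "score",
                               exposure = "exposure",
                               covariates = c("age", "sex"),
                               f_floor = 10, cluster = NULL,
                               subgroup = "all") {
  cohort <- drop_incomplete(cohort, c(outcome, score, exposure, covariates))
  y <- cohort[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("degenerate binary outcome (single level)", call. = FALSE)
  }
  fs <- fit_first_stage(cohort, score, exposure, covariates)
  if (fs$f < f_floor) {
    warning(sprintf("weak instrument: first-stage F = %.2f < %.0f",
                    fs$f, f_floor), call. = FALSE)
  }
  dat <- cohort
  dat$.xhat <- fs$fitted
  fml <- stats::reformulate(c(".xhat", usable_covariates(dat, covariates)),
                            response = outcome)
  fit <- stats::glm(fml, data = dat, family = stats::binomial())
  if (!fit$converged) {
    stop("second-stage logistic fit did not converge (separation?)",
         call. = FALSE)
  }
  V <- if (is.null(cluster)) {
    sandwich::vcovHC(fit, type = "HC1")
  } else {
    sandwich::vcovCL(fit, cluster = cohort[[cluster]])
  }
  estimate_record(outcome, "two_stage_logistic",
                  beta = stats::coef(fit)[".xhat"],
                  se = sqrt(V[".xhat", ".xhat"]), n = nrow(cohort),
                  scale = "per-SD log-OR", subgroup = subgroup)
}

#' Fisher z test for a male-female difference in effect
#'
#' `z = (beta_male - beta_female) / sqrt(se_male^2 + se_female^2)` with a
#' two-sided standard-normal p-value. Both estimates must be on the same
#' scale (e.g. both log-ORs).
#'
#' @param est_male,est_female [estimate_record()]s (or any one-row frames
#'   with `beta`, `se`, `scale`).
#' @return List with `z` and `p`.
#' @export
sex_difference_z <- function(est_male, est_female) {
  if (!identical(est_male$scale, est_female$scale)) {
    stop("estimates are on different scales: ", est_male$scale, " vs ",
         est_female$scale, call. = FALSE)
  }
  z <- (est_male$beta - est_female$beta) /
    sqrt(est_male$se^2 + est_female$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Standard subgroup index sets
#'
#' Builds named logical filters over a cohort: `all`, `men`/`women` (from
#' `sex`), and `age_lt_med` / `age_ge_med` split at the median age.
#'
#' @param cohort Cohort `data.frame`.
#' @param by Character subset of `c("sex", "age_median")`.
#' @return Named list of logical vectors.
#' @export
standard_subgroups <- function(cohort, by = c("sex", "age_median")) {
  out <- list(all = rep(TRUE, nrow(cohort)))
  if ("sex" %in% by) {
    out$men <- cohort$sex == "male"
    out$women <- cohort$sex == "female"
  }
  if ("age_median" %in% by) {
    med <- stats::median(cohort$age)
    out$age_lt_med <- cohort$age < med
    out$age_ge_med <- cohort$age >= med
  }
  out
}

#' Run estimators over an outcome x method x subgroup grid
#'
#' Every requested cell yields either an estimate row or a flagged row
#' (NA estimate plus a `note`); a failing cell never aborts the run.
#'
#' @inheritParams tsls_continuous
#' @param outcomes Named character vector or list mapping outcome column ->
#'   family (`"linear"` or `"logistic"`).
#' @param methods Subset of `c("observational", "mr")`.
#' @param subgroups Named list of logical vectors (see
#'   [standard_subgroups()]).
#' @return Tidy `data.frame` of estimate rows with a `note` column.
#' @export
run_subgroups <- function(cohort, outcomes, score = "score",
                          exposure = "exposure",
                          covariates = c("age", "sex"),
                          methods = c("observational", "mr"),
                          subgroups = list(all = rep(TRUE, nrow(cohort)))) {
  rows <- list()
  flag_row <- function(outcome, method, subgroup, msg) {
    data.frame(outcome = outcome, method = method, subgroup = subgroup,
               scale = NA_character_, beta = NA_real_, se = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
               n = NA_integer_, note = msg, stringsAsFactors = FALSE)
  }
  for (oc in names(outcomes)) {
    fam <- outcomes[[oc]]
    for (meth in methods) {
      for (sg in names(subgroups)) {
        sub <- cohort[subgroups[[sg]], , drop = FALSE]
        method_label <- if (meth == "observational") "observational"
          else if (fam == "linear") "tsls" else "two_stage_logistic"
        rec <- tryCatch({
          if (nrow(sub) == 0L) stop("empty subgroup")
          r <- if (meth == "observational") {
            fit_observational(sub, oc, exposure, covariates,
                              family = fam, subgroup = sg)
          } else if (fam == "linear") {
            tsls_continuous(sub, oc, score, exposure, covariates,
                            subgroup = sg)
          } else {
            two_stage_logistic(sub, oc, score, exposure, covariates,
                               subgroup = sg)
          }
          r$note <- ""
          as.data.frame(r)
        }, error = function(e) {
          flag_row(oc, method_label, sg, conditionMessage(e))
        })
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
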