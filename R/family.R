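#' Build a sibship index
#'
#' Groups cohort rows by `family_id`, optionally restricts membership to
#' one sex first, and drops families with fewer than `min_sibs` retained
#' members.
#'
#' @param cohort Cohort `data.frame` with `individual_id` and `family_id`.
#' @param min_sibs Minimum retained members per family (default 2).
#' @param sex_filter Optional `"male"` or `"female"`: keep only members of
#'   that sex before applying the size filter.
#' @return List of class `sibship_index`: `members` (named list family ->
#'   individual ids), `rows` (named list family -> cohort row indices),
#'   `n_families`, `n_individuals`.
#' @export
build_sibships <- function(cohort, min_sibs = 2L, sex_filter = NULL) {
  if (!"family_id" %in% names(cohort)) {
    stop("cohort has no family_id column", call. = FALSE)
  }
  keep <- !is.na(cohort$family_id)
  if (!is.null(sex_filter)) keep <- keep & cohort$sex == sex_filter
  idx <- which(keep)
  rows_by_fam <- split(idx, cohort$family_id[idx])
  rows_by_fam <- rows_by_fam[lengths(rows_by_fam) >= min_sibs]
  if (length(rows_by_fam) == 0L) {
    stop("no families with at least ", min_sibs, " qualifying members",
         call. = FALSE)
  }
  out <- list(
    members = lapply(rows_by_fam, function(i) cohort$individual_id[i]),
    rows = rows_by_fam,
    n_families = length(rows_by_fam),
    n_individuals = sum(lengths(rows_by_fam))
  )
  class(out) <- "sibship_index"
  out
}

index_rows <- function(index) unlist(index$rows, use.names = FALSE)

index_family <- function(index) {
  rep(names(index$rows), lengths(index$rows))
}

#' Centre a variable within families
#'
#' Subtracts the family mean from each member's value; the family mean is
#' returned alongside. Families with any missing member value are dropped
#' with a warning. Within every retained family the centred values sum to
#' zero, so centred variables are exactly uncorrelated with any
#' family-constant quantity.
#'
#' @param values Numeric vector aligned with the cohort rows the index was
#'   built from (i.e. `values[i]` is the value of cohort row `i`).
#' @param index A [build_sibships()] index.
#' @return List with `centered` and `family_mean`, both aligned with
#'   `unlist(index$rows)`, plus `rows` (the cohort row indices) and
#'   `family` labels.
#' @export
center_within_family <- function(values, index) {
  rows <- index$rows
  has_na <- vapply(rows, function(i) anyNA(values[i]), logical(1))
  if (any(has_na)) {
    warning(sum(has_na), " family(ies) dropped due to missing values",
            call. = FALSE)
    rows <- rows[!has_na]
    if (length(rows) == 0L) stop("no complete families", call. = FALSE)
  }
  fam <- rep(names(rows), lengths(rows))
  ridx <- unlist(rows, use.names = FALSE)
  v <- values[ridx]
  mu <- stats::ave(v, fam)
  list(centered = v - mu, family_mean = mu, rows = ridx, family = fam)
}

#' Within-sibling non-genetic association
#'
#' Regression of the outcome on the family-centred exposure plus the family
#' mean exposure plus covariates, restricted to sibships. The reported
#' effect is the centred (within-family) coefficient, which is free of
#' confounding by any family-constant factor; standard errors are
#' cluster-robust by family. For balanced sibships the within coefficient
#' equals the family fixed-effects estimate.
#'
#' @inheritParams fit_observational
#' @param index A [build_sibships()] index on the same cohort.
#' @return An [estimate_record()] with method `"sib_nongenetic"`.
#' @export
sib_nongenetic <- function(cohort, index, outcome, exposure = "exposure",
                           covariates = c("age", "sex"),
                           family = c("linear", "logistic"),
                           subgroup = "all") {
  family <- match.arg(family)
  cw <- center_within_family(cohort[[exposure]], index)
  dat <- cohort[cw$rows, , drop = FALSE]
  dat$.x_within <- cw$centered
  dat$.x_mean <- cw$family_mean
  if (stats::sd(dat$.x_within) == 0) {
    stop("exposure is constant within every family; within effect ",
         "inestimable", call. = FALSE)
  }
  fml <- stats::reformulate(c(".x_within", ".x_mean",
                              usable_covariates(dat, covariates)),
                            response = outcome)
  if (family == "linear") {
    fit <- stats::lm(fml, data = dat)
  } else {
    fit <- stats::glm(fml, data = dat, family = stats::binomial())
    if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
  }
  V <- sandwich::vcovCL(fit, cluster = cw$family)
  b <- stats::coef(fit)[".x_within"]
  if (is.na(b)) stop("within coefficient not estimable", call. = FALSE)
  estimate_record(outcome, "sib_nongenetic", beta = b,
                  se = sqrt(V[".x_within", ".x_within"]), n = nrow(dat),
                  scale = if (family == "linear") "per-SD beta"
                          else "per-SD log-OR",
                  subgroup = subgroup)
}

#' Within-sibling Mendelian randomization
#'
#' Two-stage estimator whose instrument is the family-centred genetic
#' score, isolating the Mendelian (within-family) variation that dynastic
#' effects and assortative mating cannot reach. The family-mean score is
#' included as a covariate in both stages. Continuous outcomes use
#' two-stage least squares; binary outcomes use the two-stage logistic
#' plug-in. Standard errors are cluster-robust by family. For two-sib
#' families the continuous estimator coincides exactly with the sib-pair
#' difference (difference-in-score) IV estimator.
#'
#' @inheritParams tsls_continuous
#' @param index A [build_sibships()] index on the same cohort.
#' @param family `"linear"` or `"logistic"`.
#' @return An [estimate_record()] with method `"sib_mr"`.
#' @export
sib_mr <- function(cohort, index, outcome, score = "score",
                   exposure = "exposure", covariates = c("age", "sex"),
                   family = c("linear", "logistic"), f_floor = 10,
                   subgroup = "all") {
  family <- match.arg(family)
  cw <- center_within_family(cohort[[score]], index)
  dat <- cohort[cw$rows, , drop = FALSE]
  dat$.g_within <- cw$centered
  dat$.g_mean <- cw$family_mean
  if (stats::sd(dat$.g_within) == 0) {
    stop("score is constant within every family", call. = FALSE)
  }
  exog <- cbind(covariate_matrix(dat, covariates), g_mean = dat$.g_mean)
  # within-family first stage (for the weak-instrument check and 2SPS)
  M1 <- cbind(exog, g_within = dat$.g_within)
  fs <- stats::lm.fit(M1, dat[[exposure]])
  cf <- fs$coefficients["g_within"]
  sigma2 <- sum(fs$residuals^2) / (nrow(dat) - ncol(M1))
  se_cf <- sqrt(sigma2 * solve(crossprod(M1))["g_within", "g_within"])
  f_within <- (cf / se_cf)^2
  if (f_within < f_floor) {
    warning(sprintf("weak within-family instrument: F = %.2f < %.0f",
                    f_within, f_floor), call. = FALSE)
  }
  if (family == "linear") {
    fit <- iv_fit(dat[[outcome]], dat[[exposure]], dat$.g_within, exog,
                  cluster = cw$family)
    rec <- estimate_record(outcome, "sib_mr", beta = fit$beta["endog"],
                           se = fit$se["endog"], n = nrow(dat),
                           subgroup = subgroup)
  } else {
    y <- dat[[outcome]]
    if (!all(y %in% c(0, 1))) stop("outcome must be 0/1", call. = FALSE)
    dat$.xhat <- dat[[exposure]] - fs$residuals
    fml <- stats::reformulate(c(".xhat", ".g_mean",
                                usable_covariates(dat, covariates)),
                              response = outcome)
    fit <- stats::glm(fml, data = dat, family = stats::binomial())
    if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
    V <- sandwich::vcovCL(fit, cluster = cw$family)
    rec <- estimate_record(outcome, "sib_mr",
                           beta = stats::coef(fit)[".xhat"],
                           se = sqrt(V[".xhat", ".xhat"]), n = nrow(dat),
                           scale = "per-SD log-OR", subgroup = subgroup)
  }
  attr(rec, "first_stage_f") <- unname(f_within)
  rec
}
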