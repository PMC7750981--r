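#' Declare an analysis plan
#'
#' An analysis plan names the outcomes (with their regression family and
#' whether they are inverse-normal transformed first), the covariate set,
#' the subgroup splits, and the methods to run, so a whole analysis matrix
#' is reviewable as one object.
#'
#' @param outcomes `data.frame` with columns `name` (cohort column),
#'   `family` (`"linear"` / `"logistic"`) and optional logical `transform`
#'   (inverse-normal transform before analysis; continuous outcomes only).
#' @param covariates Covariate column names (default age, sex, centre and
#'   five ancestry principal components).
#' @param subgroup_by Subset of `c("sex", "age_median")` passed to
#'   [standard_subgroups()].
#' @param methods Subset of `c("observational", "mr")`.
#' @param k Strata count if non-linear MR is requested downstream.
#' @param seed Seed recorded in the plan (used for e.g. bootstrap SEs).
#' @return List of class `analysis_plan`.
#' @export
analysis_plan <- function(outcomes,
                          covariates = c("age", "sex", "centre",
                                         paste0("pc", 1:5)),
                          subgroup_by = "sex",
                          methods = c("observational", "mr"),
                          k = 10L, seed = 1L) {
  stopifnot(is.data.frame(outcomes),
            all(c("name", "family") %in% names(outcomes)),
            all(outcomes$family %in% c("linear", "logistic")),
            all(methods %in% c("observational", "mr")))
  if (is.null(outcomes$transform)) outcomes$transform <- FALSE
  plan <- list(outcomes = outcomes, covariates = covariates,
               subgroup_by = subgroup_by, methods = methods,
               k = as.integer(k), seed = as.integer(seed))
  class(plan) <- "analysis_plan"
  plan
}

validate_plan <- function(plan, cohort) {
  problems <- character(0)
  miss_oc <- setdiff(plan$outcomes$name, names(cohort))
  if (length(miss_oc)) {
    problems <- c(problems,
                  paste("missing outcome column(s):",
                        paste(miss_oc, collapse = ", ")))
  }
  miss_cv <- setdiff(plan$covariates, names(cohort))
  if (length(miss_cv)) {
    problems <- c(problems,
                  paste("missing covariate column(s):",
                        paste(miss_cv, collapse = ", ")))
  }
  bad_tr <- plan$outcomes$name[plan$outcomes$transform &
                                 plan$outcomes$family != "linear"]
  if (length(bad_tr)) {
    problems <- c(problems,
                  paste("transform requested for non-continuous outcome(s):",
                        paste(bad_tr, collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid analysis plan:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Run a full analysis plan
#'
#' Computes the genetic risk score, applies the inverse-normal
#' transformation (and standardizes the exposure) as declared, then fills
#' every outcome x method x subgroup cell via [run_subgroups()]. Failures
#' in a cell are flagged in the `note` column rather than aborting. The
#' returned log records per-outcome missing-data exclusions, and the run is
#' deterministic given the plan seed.
#'
#' @param plan An [analysis_plan()].
#' @param cohort Cohort `data.frame` (must contain `exposure`).
#' @param genotypes Dosage matrix aligned with the cohort rows.
#' @param weights Variant weights table.
#' @return List with `results` (tidy `data.frame`), `transforms` (one
#'   record per transformed variable, including the exposure), and `log`
#'   (character lines; includes per-outcome exclusion counts).
#' @export
run_plan <- function(plan, cohort, genotypes, weights) {
  stopifnot(inherits(plan, "analysis_plan"))
  validate_plan(plan, cohort)
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))
  say("n cohort rows: ", nrow(cohort))

  scores <- compute_grs(genotypes, weights)
  cohort$score <- scores$rescaled[match(cohort$individual_id,
                                        scores$individual_id)]
  say("scored ", sum(!is.na(cohort$score)), " individuals on ",
      nrow(weights), " variants")

  tr_exp <- inverse_normal_transform(cohort$exposure, "exposure")
  cohort$exposure <- tr_exp$transformed
  transforms <- tr_exp$record
  for (i in seq_len(nrow(plan$outcomes))) {
    if (plan$outcomes$transform[i]) {
      nm <- plan$outcomes$name[i]
      tr <- inverse_normal_transform(cohort[[nm]], nm)
      cohort[[nm]] <- tr$transformed
      transforms <- rbind(transforms, tr$record)
      say("inverse-normal transformed ", nm, " (n = ", tr$record$n_nonmissing,
          ", natural SD = ", signif(tr$record$natural_sd, 4), ")")
    }
  }
  for (nm in plan$outcomes$name) {
    say("outcome ", nm, ": excluded ", sum(is.na(cohort[[nm]])),
        " rows for missingness")
  }

  outcomes <- stats::setNames(as.list(plan$outcomes$family),
                              plan$outcomes$name)
  subgroups <- standard_subgroups(cohort, by = plan$subgroup_by)
  results <- run_subgroups(cohort, outcomes, score = "score",
                           exposure = "exposure",
                           covariates = plan$covariates,
                           methods = plan$methods, subgroups = subgroups)
  say("result rows: ", nrow(results), " (",
      sum(results$note != ""), " flagged)")
  list(results = results, transforms = transforms, log = log)
}

#' Convert SD-scale results to natural units
#'
#' For every SD-scale linear result row with a matching transform record,
#' appends the effect and confidence limits multiplied by the outcome's
#' natural SD. Rows without a matching record keep `NA` natural-unit
#' columns and are flagged.
#'
#' @param results Tidy results `data.frame` from [run_plan()].
#' @param transform_records `data.frame` of transform records.
#' @return `results` with `beta_natural`, `ci_low_natural`,
#'   `ci_high_natural`, `natural_sd` columns added.
#' @export
report_natural_units <- function(results, transform_records) {
  idx <- match(results$outcome, transform_records$variable_name)
  sds <- transform_records$natural_sd[idx]
  applies <- !is.na(sds) & !is.na(results$beta) &
    results$scale %in% "per-SD beta"
  results$natural_sd <- NA_real_
  results$beta_natural <- NA_real_
  results$ci_low_natural <- NA_real_
  results$ci_high_natural <- NA_real_
  if (any(applies)) {
    s <- sds[applies]
    results$natural_sd[applies] <- s
    results$beta_natural[applies] <- sd_to_natural(results$beta[applies], s)
    results$ci_low_natural[applies] <-
      sd_to_natural(results$ci_low[applies], s)
    results$ci_high_natural[applies] <-
      sd_to_natural(results$ci_high[applies], s)
  }
  results
}
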