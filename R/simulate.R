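#' Simulation configuration for synthetic MR cohorts
#'
#' Bundles every parameter of the synthetic data-generating process into a
#' validated list. The generator emulates the statistical structure that
#' one-sample MR of an anthropometric exposure assumes: a panel of
#' independent biallelic variants in Hardy-Weinberg proportions whose
#' weighted score explains a small configurable fraction of exposure
#' variance, an individual-level confounder acting on both exposure and
#' outcomes, sibships created by Mendelian transmission from simulated
#' parents, dynastic (parental score to offspring outcome) effects, and
#' assortative mating between parental scores.
#'
#' @param n_individuals Number of unrelated individuals drawn by
#'   [simulate_unrelated()].
#' @param n_families Number of sibships drawn by [simulate_sibships()].
#' @param sibs_per_family Siblings per family (at least 2).
#' @param n_variants Number of independent biallelic variants in the score
#'   panel (default 73, the size of the main instrument).
#' @param allele_freq_range Range from which effect-allele frequencies are
#'   drawn uniformly; must lie inside (0.05, 0.95).
#' @param target_r2 Fraction of exposure variance explained by the
#'   (rescaled) genetic risk score; default 0.017, i.e. 1.7%.
#' @param confounder_effect_on_exposure Effect of the standard-normal
#'   confounder U on the exposure, in exposure-SD units per SD of U.
#' @param confounder_effect_on_outcome Effect of U on every outcome linear
#'   predictor, in outcome-SD (or log-odds) units.
#' @param confounder_family_frac Fraction of the variance of U shared by all
#'   members of a family in sibship draws (0 = purely individual).
#' @param dynastic_effect Effect of the standardized mid-parental score on
#'   each offspring outcome linear predictor (sibships only).
#' @param assortative_mating_corr Correlation imposed between the two
#'   parental scores of each family, in [0, 1).
#' @param causal_shape One of "linear", "quadratic", "piecewise": shape of
#'   the causal effect of the (standardized) exposure on outcomes.
#' @param causal_params Named list of shape coefficients. For "linear":
#'   `list(beta = ...)`; for "quadratic": `list(beta = ..., center = ...)`
#'   giving `beta * (x - center)^2`; for "piecewise":
#'   `list(breaks = ..., slopes = ...)` with `length(slopes) ==
#'   length(breaks) + 1`, the continuous piecewise-linear function anchored
#'   at f(0) = 0. Sex-specific effects are given as
#'   `list(male = <params>, female = <params>)`.
#' @param binary_baseline_logodds Intercept of the logistic model generating
#'   binary outcomes. The default 1.01 gives a baseline prevalence of about
#'   73%, the cohabitation rate of the motivating cohort.
#' @param exposure_mean,exposure_sd Location and scale used to express the
#'   standardized exposure in natural units (defaults 27.4 and 4.8 kg/m^2,
#'   the observed BMI distribution of the motivating cohort).
#' @param seed Integer seed; identical configurations (including seed)
#'   produce bit-identical tables.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_individuals = 500, seed = 7)
#' cfg$target_r2
#' @export
sim_config <- function(n_individuals = 10000L,
                       n_families = 5000L,
                       sibs_per_family = 2L,
                       n_variants = 73L,
                       allele_freq_range = c(0.05, 0.95),
                       target_r2 = 0.017,
                       confounder_effect_on_exposure = 0.3,
                       confounder_effect_on_outcome = 0.3,
                       confounder_family_frac = 0,
                       dynastic_effect = 0,
                       assortative_mating_corr = 0,
                       causal_shape = c("linear", "quadratic", "piecewise"),
                       causal_params = list(beta = 0.1),
                       binary_baseline_logodds = 1.01,
                       exposure_mean = 27.4,
                       exposure_sd = 4.8,
                       seed = 1L) {
  causal_shape <- match.arg(causal_shape)
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_families = as.integer(n_families),
    sibs_per_family = as.integer(sibs_per_family),
    n_variants = as.integer(n_variants),
    allele_freq_range = as.numeric(allele_freq_range),
    target_r2 = target_r2,
    confounder_effect_on_exposure = confounder_effect_on_exposure,
    confounder_effect_on_outcome = confounder_effect_on_outcome,
    confounder_family_frac = confounder_family_frac,
    dynastic_effect = dynastic_effect,
    assortative_mating_corr = assortative_mating_corr,
    causal_shape = causal_shape,
    causal_params = causal_params,
    binary_baseline_logodds = binary_baseline_logodds,
    exposure_mean = exposure_mean,
    exposure_sd = exposure_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_variants < 1L) stop("n_variants must be >= 1", call. = FALSE)
  if (cfg$sibs_per_family < 2L) {
    stop("sibs_per_family must be >= 2", call. = FALSE)
  }
  if (!(cfg$target_r2 > 0 && cfg$target_r2 < 1)) {
    stop("target_r2 must lie strictly in (0, 1)", call. = FALSE)
  }
  fr <- cfg$allele_freq_range
  if (length(fr) != 2L || fr[1] >= fr[2] || fr[1] < 0.05 || fr[2] > 0.95) {
    stop("allele_freq_range must be an increasing pair inside [0.05, 0.95]",
         call. = FALSE)
  }
  if (cfg$assortative_mating_corr < 0 || cfg$assortative_mating_corr >= 1) {
    stop("assortative_mating_corr must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$confounder_family_frac < 0 || cfg$confounder_family_frac >= 1) {
    stop("confounder_family_frac must lie in [0, 1)", call. = FALSE)
  }
  noise_var <- 1 - cfg$target_r2 - cfg$confounder_effect_on_exposure^2
  if (noise_var <= 0) {
    stop("target_r2 + confounder_effect_on_exposure^2 must be < 1 so the ",
         "exposure noise variance is positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a variant-weights panel
#'
#' Draws effect-allele frequencies uniformly within the configured range and
#' per-allele weights from a half-normal truncated below (selected GWAS
#' panels carry no near-zero effects), then rescales the weights so that
#' the population variance of the weighted score under Hardy-Weinberg
#' equilibrium, `sum(2 * p * (1 - p) * beta^2)`, equals `target_r2`. Because
#' the exposure is generated with unit variance, this makes the population
#' R-squared of the (weighted or rescaled) score on the exposure equal to
#' `target_r2` exactly; the allele-count rescaling is linear and leaves the
#' R-squared unchanged.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `freq`.
#' @examples
#' w <- simulate_variant_panel(sim_config(n_variants = 10, seed = 2))
#' sum(2 * w$freq * (1 - w$freq) * w$beta^2)  # = target_r2
#' @export
simulate_variant_panel <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  m <- config$n_variants
  freq <- stats::runif(m, config$allele_freq_range[1],
                       config$allele_freq_range[2])
  # half-normal truncated below: a GWAS-selected panel carries no
  # near-zero effects (discovery significance bounds |beta| away from 0)
  beta_raw <- stats::qnorm(stats::runif(m, stats::pnorm(0.6), 1))
  # rescale so Var(score) = sum 2p(1-p) beta^2 = target_r2 under HWE
  v_raw <- sum(2 * freq * (1 - freq) * beta_raw^2)
  beta <- beta_raw * sqrt(config$target_r2 / v_raw)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, m, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
  data.frame(
    variant_id = sprintf("rs%06d", seq_len(m)),
    effect_allele = ea,
    other_allele = unname(oa),
    beta = beta,
    freq = freq,
    stringsAsFactors = FALSE
  )
}

# Causal effect of the standardized exposure on an outcome linear predictor.
# params may carry $male / $female sub-lists for sex-specific shapes.
causal_effect <- function(x, sex, shape, params) {
  if (!is.null(params$male) || !is.null(params$female)) {
    out <- numeric(length(x))
    m <- sex == "male"
    out[m] <- causal_effect(x[m], NULL, shape, params$male)
    out[!m] <- causal_effect(x[!m], NULL, shape, params$female)
    return(out)
  }
  switch(shape,
    linear = params$beta * x,
    quadratic = {
      ctr <- if (is.null(params$center)) 0 else params$center
      params$beta * (x - ctr)^2
    },
    piecewise = piecewise_linear(x, params$breaks, params$slopes),
    stop("unknown causal shape: ", shape, call. = FALSE)
  )
}

# Continuous piecewise-linear function with f(0) = 0: the integral of the
# step function taking slopes[i] on (breaks[i-1], breaks[i]].
piecewise_linear <- function(x, breaks, slopes) {
  stopifnot(length(slopes) == length(breaks) + 1L, !is.unsorted(breaks))
  edges <- c(-Inf, breaks, Inf)
  f_at <- function(v) {
    lo <- min(0, v)
    hi <- max(0, v)
    len <- pmax(0, pmin(edges[-1], hi) - pmax(edges[-length(edges)], lo))
    sign(v) * sum(slopes * len)
  }
  vapply(x, f_at, numeric(1))
}

# Shared covariate draws (age, sex, centre, ancestry PCs).
draw_covariates <- function(n) {
  age <- pmin(pmax(round(stats::rnorm(n, 57.2, 8)), 37), 73)
  sex <- ifelse(stats::runif(n) < 0.461, "male", "female")
  centre <- sample(sprintf("centre%02d", 1:10), n, replace = TRUE)
  pcs <- matrix(stats::rnorm(n * 5L), n, 5L,
                dimnames = list(NULL, paste0("pc", 1:5)))
  cbind(data.frame(age = age, sex = sex, centre = centre,
                   stringsAsFactors = FALSE),
        as.data.frame(pcs))
}

# Outcome block from a standardized exposure, confounder and family shock.
draw_outcomes <- function(x_std, sex, u, fam_shock, cfg) {
  b <- cfg$confounder_effect_on_outcome
  f <- causal_effect(x_std, sex, cfg$causal_shape, cfg$causal_params)
  n <- length(x_std)
  noise_sd <- sqrt(max(0.1, 1 - b^2))
  lp <- f + b * u + fam_shock
  tdi <- lp + stats::rnorm(n, 0, noise_sd)
  income <- -lp + stats::rnorm(n, 0, noise_sd)
  p_cohab <- stats::plogis(cfg$binary_baseline_logodds + lp)
  p_degree <- stats::plogis(-0.1 - lp)
  data.frame(
    tdi = tdi,
    income = income,
    cohabit = stats::rbinom(n, 1L, p_cohab),
    degree = stats::rbinom(n, 1L, p_degree),
    exposure_true_effect = f
  )
}

genotype_matrix <- function(dos, ids, variant_ids) {
  dimnames(dos) <- list(ids, variant_ids)
  dos
}

#' Simulate a cohort of unrelated individuals
#'
#' Genotype dosages are drawn `Binomial(2, freq)` per variant
#' (Hardy-Weinberg). The standardized exposure is the centred weighted score
#' plus `confounder_effect_on_exposure * U` plus Gaussian noise sized so the
#' population variance is 1. Continuous outcomes (`tdi`, `income`) and
#' binary outcomes (`cohabit`, `degree`) share a linear predictor built from
#' the configured causal shape, the confounder, and (for binary outcomes) a
#' logit link; `income` and `degree` receive the predictor with opposite
#' sign so the table carries effects in both directions.
#'
#' @param config A [sim_config()].
#' @param weights Variant panel from [simulate_variant_panel()].
#' @return A list with elements `genotypes` (an individuals x variants
#'   dosage matrix) and `cohort` (a `data.frame` holding ids, covariates,
#'   `exposure` in SD units, `exposure_raw` in natural units, the outcome
#'   columns, and the simulation-truth columns `confounder_true` and
#'   `exposure_true_effect`).
#' @examples
#' cfg <- sim_config(n_individuals = 200, n_variants = 5, seed = 3)
#' sim <- simulate_unrelated(cfg, simulate_variant_panel(cfg))
#' dim(sim$genotypes); names(sim$cohort)
#' @export
simulate_unrelated <- function(config, weights) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_individuals
  m <- nrow(weights)
  dos <- matrix(stats::rbinom(n * m, 2L, rep(weights$freq, each = n)), n, m)
  score <- drop(dos %*% weights$beta)
  score_c <- score - 2 * sum(weights$freq * weights$beta)
  u <- stats::rnorm(n)
  a <- config$confounder_effect_on_exposure
  noise_sd <- sqrt(1 - config$target_r2 - a^2)
  x <- score_c + a * u + stats::rnorm(n, 0, noise_sd)
  cov_df <- draw_covariates(n)
  out <- draw_outcomes(x, cov_df$sex, u, 0, config)
  ids <- sprintf("id%07d", seq_len(n))
  cohort <- cbind(
    data.frame(individual_id = ids, family_id = NA_character_,
               stringsAsFactors = FALSE),
    cov_df,
    data.frame(exposure = x,
               exposure_raw = config$exposure_mean + config$exposure_sd * x,
               confounder_true = u),
    out
  )
  list(genotypes = genotype_matrix(dos, ids, weights$variant_id),
       cohort = cohort)
}

#' Simulate sibships with Mendelian transmission
#'
#' Two parents per family are drawn under Hardy-Weinberg; assortative mating
#' couples the parental weighted scores at the configured correlation via a
#' Gaussian-copula rank coupling (fathers and mothers are re-paired so the
#' ranks of their scores follow a bivariate normal with that correlation,
#' leaving both marginals untouched). Each sibling then receives, per
#' variant, one allele from each parent by independent Mendelian
#' transmission. Offspring outcomes additionally include `dynastic_effect`
#' times the standardized mid-parental score, and the confounder U may carry
#' a family-shared component (`confounder_family_frac`).
#'
#' @inheritParams simulate_unrelated
#' @return As [simulate_unrelated()]; the cohort additionally has non-missing
#'   `family_id` and a `midparent_score_z` truth column.
#' @examples
#' cfg <- sim_config(n_families = 50, sibs_per_family = 2, n_variants = 5,
#'                   seed = 4)
#' sim <- simulate_sibships(cfg, simulate_variant_panel(cfg))
#' table(table(sim$cohort$family_id))
#' @export
simulate_sibships <- function(config, weights) {
  validate_sim_config(config)
  if (config$n_families < 1L) stop("n_families must be >= 1", call. = FALSE)
  set.seed(config$seed + 2L)
  nf <- config$n_families
  k <- config$sibs_per_family
  m <- nrow(weights)
  p <- weights$freq

  # parental allele pairs (two haplotypes each), HWE
  pat_h1 <- matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  pat_h2 <- matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  mat_h1 <- matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  mat_h2 <- matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)

  r <- config$assortative_mating_corr
  if (r > 0) {
    # Gaussian-copula rank coupling of parental scores
    s_f <- drop((pat_h1 + pat_h2) %*% weights$beta)
    s_m <- drop((mat_h1 + mat_h2) %*% weights$beta)
    z1 <- stats::rnorm(nf)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(nf)
    ord_f <- order(s_f)[rank(z1, ties.method = "first")]
    ord_m <- order(s_m)[rank(z2, ties.method = "first")]
    pat_h1 <- pat_h1[ord_f, , drop = FALSE]
    pat_h2 <- pat_h2[ord_f, , drop = FALSE]
    mat_h1 <- mat_h1[ord_m, , drop = FALSE]
    mat_h2 <- mat_h2[ord_m, , drop = FALSE]
  }

  n <- nf * k
  fam_of <- rep(seq_len(nf), each = k)
  # one allele from each parent, independent per sib and per variant
  pick <- function(h1, h2) {
    sel <- matrix(stats::runif(n * m) < 0.5, n, m)
    ifelse(sel, h1[fam_of, , drop = FALSE], h2[fam_of, , drop = FALSE])
  }
  dos <- pick(pat_h1, pat_h2) + pick(mat_h1, mat_h2)

  score <- drop(dos %*% weights$beta)
  score_c <- score - 2 * sum(weights$freq * weights$beta)
  mid <- drop((pat_h1 + pat_h2 + mat_h1 + mat_h2) %*% weights$beta) / 2
  mid_z <- as.numeric(scale(mid))

  fr <- config$confounder_family_frac
  u_fam <- stats::rnorm(nf)
  u <- sqrt(1 - fr) * stats::rnorm(n) + sqrt(fr) * u_fam[fam_of]
  a <- config$confounder_effect_on_exposure
  noise_sd <- sqrt(1 - config$target_r2 - a^2)
  x <- score_c + a * u + stats::rnorm(n, 0, noise_sd)

  cov_df <- draw_covariates(n)
  out <- draw_outcomes(x, cov_df$sex, u,
                       config$dynastic_effect * mid_z[fam_of], config)
  ids <- sprintf("id%07d", seq_len(n))
  cohort <- cbind(
    data.frame(individual_id = ids,
               family_id = sprintf("fam%06d", fam_of),
               stringsAsFactors = FALSE),
    cov_df,
    data.frame(exposure = x,
               exposure_raw = config$exposure_mean + config$exposure_sd * x,
               confounder_true = u,
               midparent_score_z = mid_z[fam_of]),
    out
  )
  list(genotypes = genotype_matrix(dos, ids, weights$variant_id),
       cohort = cohort)
}
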