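make_family_fixture <- function() {
  data.frame(
    individual_id = sprintf("i%d", 1:6),
    family_id = c("f1", "f2", "f2", "f3", "f3", "f3"),
    sex = c("male", "male", "female", "male", "male", "female"),
    stringsAsFactors = FALSE
  )
}

test_that("sibship index keeps only qualifying families", {
  ch <- make_family_fixture()
  idx <- build_sibships(ch)
  expect_equal(idx$n_families, 2L)  # f1 has a single member
  expect_equal(idx$n_individuals, 5L)
  # sex filter applied before the size filter: f2 has one male only
  idxm <- build_sibships(ch, sex_filter = "male")
  expect_error(build_sibships(ch[1, , drop = FALSE]), "no families")
  expect_false("f2" %in% names(idxm$members))
  expect_equal(names(idxm$members), "f3")
  expect_equal(idxm$n_individuals, 2L)
  # one female per family at most: the female-only index is empty
  expect_error(build_sibships(ch, sex_filter = "female"), "no families")
})

test_that("family centring is exact arithmetic with zero family sums", {
  ch <- make_family_fixture()
  idx <- build_sibships(ch)
  vals <- c(99, 25, 27, 10, 20, 30)
  cw <- center_within_family(vals, idx)
  expect_equal(cw$centered[cw$family == "f2"], c(-1, 1))
  expect_equal(unique(cw$family_mean[cw$family == "f2"]), 26)
  sums <- tapply(cw$centered, cw$family, sum)
  expect_true(all(abs(sums) < 1e-12))
  # identical sibs centre to zero
  cw2 <- center_within_family(rep(5, 6), idx)
  expect_true(all(cw2$centered == 0))
  # a family with a missing member is dropped with a warning
  vals[2] <- NA
  expect_warning(cw3 <- center_within_family(vals, idx), "dropped")
  expect_false("f2" %in% cw3$family)
})

test_that("centred scores are orthogonal to family-constant variables", {
  cfg <- sim_config(n_families = 2000, n_variants = 15, seed = 110)
  sc <- make_scored_sibs(cfg)
  idx <- build_sibships(sc$cohort)
  cw <- center_within_family(sc$cohort$score, idx)
  fam_const <- cw$family_mean
  expect_lt(abs(cor(cw$centered, fam_const)), 1e-10)
  mid <- sc$cohort$midparent_score_z[cw$rows]
  expect_lt(abs(cor(cw$centered, mid)), 0.05)
})

test_that("two-sib sib MR equals the sib-pair difference estimator", {
  cfg <- sim_config(n_families = 1500, n_variants = 12, seed = 111,
                    dynastic_effect = 0.1)
  sc <- make_scored_sibs(cfg)
  ch <- sc$cohort
  idx <- build_sibships(ch)
  est <- sib_mr(ch, idx, "tdi", covariates = NULL)
  o <- seq(1, nrow(ch), by = 2)
  dg <- ch$score[o] - ch$score[o + 1]
  dx <- ch$exposure[o] - ch$exposure[o + 1]
  dy <- ch$tdi[o] - ch$tdi[o + 1]
  beta_diff <- sum(dg * dy) / sum(dg * dx)
  expect_equal(est$beta, beta_diff, tolerance = 1e-8)
})

test_that("within coefficient matches family fixed effects for two sibs", {
  cfg <- sim_config(n_families = 300, n_variants = 10, seed = 112)
  sc <- make_scored_sibs(cfg)
  ch <- sc$cohort
  idx <- build_sibships(ch)
  est <- sib_nongenetic(ch, idx, "tdi", covariates = NULL)
  fe <- lm(tdi ~ exposure + factor(family_id), data = ch)
  expect_equal(est$beta, unname(coef(fe)["exposure"]), tolerance = 1e-8)
  # constant exposure within every family is inestimable
  ch2 <- ch
  ch2$exposure <- ave(ch2$exposure, ch2$family_id)
  expect_error(sib_nongenetic(ch2, idx, "tdi", covariates = NULL),
               "inestimable|constant")
})

test_that("family-level confounding biases the population but not the within fit", {
  reps <- 15
  pop_bias <- within_bias <- within_se <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_families = 3000, n_variants = 15,
                      confounder_family_frac = 0.8,
                      confounder_effect_on_exposure = 0.4,
                      confounder_effect_on_outcome = 0.4, seed = 200 + r)
    sc <- make_scored_sibs(cfg)
    idx <- build_sibships(sc$cohort)
    pop <- fit_observational(sc$cohort, "tdi", covariates = NULL)
    win <- sib_nongenetic(sc$cohort, idx, "tdi", covariates = NULL)
    pop_bias[r] <- pop$beta - 0.1
    within_bias[r] <- win$beta - 0.1
    within_se[r] <- win$se
  }
  # population regression absorbs most of the confounding ...
  expect_gt(mean(pop_bias), 0.1)
  # ... the within fit only the individual-level share
  expect_lt(mean(within_bias), 0.5 * mean(pop_bias))
})

test_that("dynastic effects bias population MR but not sib MR", {
  cfg <- sim_config(n_families = 8000, n_variants = 30, seed = 120,
                    dynastic_effect = 0.1, assortative_mating_corr = 0.4)
  sc <- make_scored_sibs(cfg)
  ch <- sc$cohort
  idx <- build_sibships(ch)
  pop <- tsls_continuous(ch, "tdi")
  sib <- sib_mr(ch, idx, "tdi")
  expect_gt(abs(pop$beta - 0.1), abs(sib$beta - 0.1))
  # efficiency ordering: the within estimator discards information
  expect_gt(sib$se, pop$se)
})
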