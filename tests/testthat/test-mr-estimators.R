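test_that("single-instrument 2SLS equals the Wald ratio", {
  set.seed(1)
  n <- 1000
  g <- rbinom(n, 2, 0.4)
  x <- 0.2 * g + rnorm(n)
  y <- 0.5 * x + rnorm(n)
  ch <- data.frame(score = g, exposure = x, yy = y)
  est <- tsls_continuous(ch, "yy", covariates = NULL)
  expect_equal(est$beta, cov(g, y) / cov(g, x), tolerance = 1e-8)
  # invariance to linear rescaling of the instrument
  ch2 <- ch
  ch2$score <- 7.3 * ch$score + 2
  est2 <- tsls_continuous(ch2, "yy", covariates = NULL)
  expect_equal(est$beta, est2$beta, tolerance = 1e-8)
  expect_equal(est$se, est2$se, tolerance = 1e-8)
})

test_that("estimate records satisfy the Wald CI identity", {
  r <- estimate_record("y", "tsls", beta = 0.2, se = 0.05, n = 100)
  expect_equal(r$ci_low, 0.2 - 1.96 * 0.05, tolerance = 1e-9)
  expect_equal(r$ci_high, 0.2 + 1.96 * 0.05, tolerance = 1e-9)
  expect_true(r$p > 0 && r$p <= 1)
  expect_error(estimate_record("y", "tsls", beta = 0.2, se = 0, n = 10))
})

test_that("observational fit returns the identity and confounded slopes", {
  set.seed(2)
  n <- 2000
  ch <- data.frame(exposure = rnorm(n), age = rnorm(n),
                   sex = sample(c("male", "female"), n, TRUE))
  ch$same <- ch$exposure + rnorm(n, 0, 1e-6)
  est <- fit_observational(ch, "same")
  expect_equal(est$beta, 1, tolerance = 1e-6)
  expect_lt(est$p, 1e-100)
  # logistic family requires 0/1
  ch$bad <- ch$exposure
  expect_error(fit_observational(ch, "bad", family = "logistic"), "0/1")
  ch$flat <- 1
  expect_error(fit_observational(ch, "flat", family = "logistic"))
})

test_that("first stage recovers its coefficient and flags weak instruments", {
  set.seed(3)
  n <- 4000
  ch <- data.frame(score = rnorm(n))
  ch$exposure <- 2 * ch$score + rnorm(n)
  fs <- fit_first_stage(ch, covariates = NULL)
  expect_equal(fs$coef, 2, tolerance = 0.05)
  expect_gt(fs$f, 1000)
  # orthogonal score: F ~ 1, and downstream 2SLS warns
  ch$yy <- rnorm(n)
  ch$exposure <- rnorm(n)
  expect_warning(tsls_continuous(ch, "yy", covariates = NULL),
                 "weak instrument")
  ch$score <- 1
  expect_error(fit_first_stage(ch, covariates = NULL), "variance")
})

test_that("IV nulls out confounding for continuous and binary outcomes", {
  cfg <- sim_config(n_individuals = 30000, causal_params = list(beta = 0),
                    seed = 50)
  sc <- make_scored_cohort(cfg)
  est <- tsls_continuous(sc$cohort, "tdi")
  expect_lt(abs(est$beta), 2 * est$se)
  estb <- two_stage_logistic(sc$cohort, "cohabit")
  expect_lt(abs(estb$beta), 2 * estb$se)
  expect_identical(estb$scale, "per-SD log-OR")
})

test_that("adjusting for the true confounder aligns observational and IV fits", {
  cfg <- sim_config(n_individuals = 20000, seed = 65)
  sc <- make_scored_cohort(cfg)
  obs <- fit_observational(sc$cohort, "tdi",
                           covariates = c("age", "sex", "confounder_true"))
  iv <- tsls_continuous(sc$cohort, "tdi")
  expect_lt(abs(obs$beta - iv$beta), 2 * iv$se)
  # and the confounder-adjusted observational slope is the causal 0.1
  expect_lt(abs(obs$beta - 0.1), 3 * obs$se)
})

test_that("robust and conventional 2SLS SEs agree under homoskedasticity", {
  cfg <- sim_config(n_individuals = 50000, seed = 60)
  sc <- make_scored_cohort(cfg)
  ch <- sc$cohort
  est <- tsls_continuous(ch, "tdi", covariates = NULL)
  # classical (homoskedastic) 2SLS covariance as the oracle
  Z <- cbind(z = ch$score, 1)
  X <- cbind(endog = ch$exposure, 1)
  bz <- solve(crossprod(Z, X), crossprod(Z, ch$tdi))
  e <- drop(ch$tdi - X %*% bz)
  A <- solve(crossprod(Z, X))
  Vc <- A %*% (crossprod(Z) * sum(e^2) / (nrow(ch) - 2)) %*% t(A)
  expect_equal(est$se, sqrt(Vc[1, 1]), tolerance = 0.05)
})

test_that("two-stage logistic recovers sex-specific odds ratios", {
  # causal log-ORs log(1.07) in men, log(0.83) in women on cohabitation
  ors_w <- ors_m <- numeric(8)
  for (r in 1:8) {
    cfg <- sim_config(
      n_individuals = 100000,
      causal_params = list(male = list(beta = log(1.07)),
                           female = list(beta = log(0.83))),
      seed = 1000 + r
    )
    sc <- make_scored_cohort(cfg)
    women <- sc$cohort[sc$cohort$sex == "female", ]
    men <- sc$cohort[sc$cohort$sex == "male", ]
    ors_w[r] <- exp(two_stage_logistic(women, "cohabit",
                                       subgroup = "women")$beta)
    ors_m[r] <- exp(two_stage_logistic(men, "cohabit",
                                       subgroup = "men")$beta)
  }
  mc_w <- sd(log(ors_w)) / sqrt(length(ors_w))
  mc_m <- sd(log(ors_m)) / sqrt(length(ors_m))
  expect_lt(abs(mean(log(ors_w)) - log(0.83)), 2.5 * mc_w)
  expect_lt(abs(mean(log(ors_m)) - log(1.07)), 2.5 * mc_m)
  # and the protective female effect is clearly below the male OR
  expect_lt(mean(ors_w), mean(ors_m))
})

test_that("Fisher z test is symmetric, antisymmetric and matches hand math", {
  a <- estimate_record("y", "tsls", beta = 0.1, se = 0.05, n = 10,
                       scale = "per-SD log-OR")
  expect_equal(sex_difference_z(a, a)$z, 0)
  expect_equal(sex_difference_z(a, a)$p, 1)
  b <- estimate_record("y", "tsls", beta = -0.1, se = 0.04, n = 10,
                       scale = "per-SD log-OR")
  expect_equal(sex_difference_z(a, b)$z, -sex_difference_z(b, a)$z)
  expect_equal(sex_difference_z(a, b)$p, sex_difference_z(b, a)$p)
  # from printed ORs 1.07 (0.97, 1.17) vs 0.83 (0.76, 0.92): z ~= 3.7
  m <- estimate_record("cohabit", "two_stage_logistic", beta = log(1.07),
                       se = (log(1.17) - log(0.97)) / 3.92, n = 1,
                       scale = "per-SD log-OR")
  f <- estimate_record("cohabit", "two_stage_logistic", beta = log(0.83),
                       se = (log(0.92) - log(0.76)) / 3.92, n = 1,
                       scale = "per-SD log-OR")
  expect_equal(sex_difference_z(m, f)$z, 3.7, tolerance = 0.02)
  # mismatched scales are not comparable
  c_ <- estimate_record("y", "tsls", beta = 0.1, se = 0.05, n = 10)
  expect_error(sex_difference_z(a, c_), "scales")
})

test_that("subgroup runs partition the sample and flag failures", {
  cfg <- sim_config(n_individuals = 3000, n_variants = 10, seed = 80)
  sc <- make_scored_cohort(cfg)
  ch <- sc$cohort
  sgs <- standard_subgroups(ch, by = c("sex", "age_median"))
  expect_equal(sum(sgs$men) + sum(sgs$women), nrow(ch))
  expect_equal(sum(sgs$age_lt_med) + sum(sgs$age_ge_med), nrow(ch))
  res <- run_subgroups(ch, list(tdi = "linear", cohabit = "logistic"),
                       subgroups = sgs["all"])
  expect_equal(nrow(res), 4L)  # 2 outcomes x 2 methods x 1 subgroup
  expect_true(all(res$note == ""))
  # an empty subgroup yields a flagged row, not an error
  res2 <- run_subgroups(ch, list(tdi = "linear"),
                        subgroups = list(none = rep(FALSE, nrow(ch))))
  expect_true(all(is.na(res2$beta)))
  expect_true(all(res2$note != ""))
})
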