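test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(target_r2 = 0), "target_r2")
  expect_error(sim_config(target_r2 = 1), "target_r2")
  expect_error(sim_config(assortative_mating_corr = 1), "assortative")
  expect_error(sim_config(sibs_per_family = 1), "sibs_per_family")
  expect_error(sim_config(target_r2 = 0.5,
                          confounder_effect_on_exposure = 0.9),
               "noise variance")
})

test_that("variant panel hits the configured score variance analytically", {
  cfg <- sim_config(n_variants = 73, target_r2 = 0.017, seed = 42)
  w <- simulate_variant_panel(cfg)
  expect_equal(sum(2 * w$freq * (1 - w$freq) * w$beta^2), 0.017,
               tolerance = 1e-12)
  expect_true(all(w$freq >= 0.05 & w$freq <= 0.95))
  expect_true(all(w$effect_allele != w$other_allele))
  expect_false(anyDuplicated(w$variant_id) > 0)
  # single variant at freq p, weight b has HWE score variance 2p(1-p)b^2
  cfg1 <- sim_config(n_variants = 1, target_r2 = 0.01, seed = 3)
  w1 <- simulate_variant_panel(cfg1)
  expect_equal(2 * w1$freq * (1 - w1$freq) * w1$beta^2, 0.01,
               tolerance = 1e-12)
})

test_that("identical configs give bit-identical tables", {
  cfg <- sim_config(n_individuals = 500, n_variants = 10, seed = 7)
  a <- simulate_unrelated(cfg, simulate_variant_panel(cfg))
  b <- simulate_unrelated(cfg, simulate_variant_panel(cfg))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$cohort, b$cohort)
  cfgf <- sim_config(n_families = 100, n_variants = 10, seed = 7)
  sa <- simulate_sibships(cfgf, simulate_variant_panel(cfgf))
  sb <- simulate_sibships(cfgf, simulate_variant_panel(cfgf))
  expect_identical(sa$cohort, sb$cohort)
})

test_that("unrelated draws respect HWE and dosage expectations", {
  cfg <- sim_config(n_individuals = 50000, n_variants = 20, seed = 12)
  w <- simulate_variant_panel(cfg)
  sim <- simulate_unrelated(cfg, w)
  d <- sim$genotypes
  expect_true(all(d >= 0 & d <= 2))
  # E[dosage] = 2p within 3 binomial SEs
  se <- sqrt(2 * w$freq * (1 - w$freq) / nrow(d))
  expect_true(all(abs(colMeans(d) - 2 * w$freq) < 3.5 * se))
  # genotype frequencies consistent with p^2, 2pq, q^2
  pvals <- vapply(seq_len(ncol(d)), function(j) {
    obs <- tabulate(d[, j] + 1L, 3L)
    p <- w$freq[j]
    exp_ <- nrow(d) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stats::pchisq(sum((obs - exp_)^2 / exp_), df = 2, lower.tail = FALSE)
  }, numeric(1))
  expect_gte(mean(pvals > 0.001), 0.95)
  expect_equal(sd(sim$cohort$exposure), 1, tolerance = 0.03)
})

test_that("confounding produces the closed-form omitted-variable bias", {
  # x = S + 0.3 U + e (unit variance), y = 0.1 x + 0.3 U + eps
  # => naive slope = 0.1 + 0.09 / var(x) ~= 0.19
  reps <- 20
  slopes <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(n_individuals = 10000, n_variants = 20, seed = 100 + r)
    sc <- make_scored_cohort(cfg)
    unname(coef(lm(tdi ~ exposure, data = sc$cohort))["exposure"])
  }, numeric(1))
  expect_equal(mean(slopes), 0.19, tolerance = 0.01)
})

test_that("sibling dosages correlate near 0.5 under random mating", {
  cfg <- sim_config(n_families = 10000, n_variants = 15, seed = 21,
                    dynastic_effect = 0, assortative_mating_corr = 0)
  sim <- simulate_sibships(cfg, simulate_variant_panel(cfg))
  d <- sim$genotypes
  o <- seq(1, nrow(d), by = 2)
  cors <- vapply(seq_len(ncol(d)), function(j) cor(d[o, j], d[o + 1, j]),
                 numeric(1))
  expect_true(mean(cors) > 0.45 && mean(cors) < 0.55)
  # bookkeeping: n_families * sibs_per_family rows, every family complete
  expect_equal(nrow(sim$cohort), 20000L)
  expect_true(all(table(sim$cohort$family_id) == 2L))
})

test_that("assortative mating induces the configured parental-score coupling", {
  cfg <- sim_config(n_families = 8000, n_variants = 30, seed = 31,
                    assortative_mating_corr = 0.4)
  sim <- simulate_sibships(cfg, simulate_variant_panel(cfg))
  # sibs share more than half their score variation under AM
  s <- compute_grs(sim$genotypes,
                   simulate_variant_panel(cfg))$weighted
  o <- seq(1, length(s), by = 2)
  expect_gt(cor(s[o], s[o + 1]), 0.55)
})

test_that("null-effect, null-confounding draws align naive and IV estimands", {
  diffs <- ses <- numeric(30)
  for (r in seq_len(30)) {
    cfg <- sim_config(n_individuals = 8000, n_variants = 20,
                      confounder_effect_on_exposure = 0,
                      confounder_effect_on_outcome = 0,
                      causal_params = list(beta = 0.1), seed = 300 + r)
    sc <- make_scored_cohort(cfg)
    naive <- fit_observational(sc$cohort, "tdi")
    iv <- tsls_continuous(sc$cohort, "tdi")
    diffs[r] <- naive$beta - iv$beta
    ses[r] <- iv$se
  }
  expect_lt(abs(mean(diffs)), 2 * mean(ses))
})

test_that("piecewise causal shapes integrate correctly", {
  f <- mrcohort:::piecewise_linear(c(-2, -1, 0, 1, 2), breaks = 0,
                                   slopes = c(-1, 1))
  expect_equal(f, c(2, 1, 0, 1, 2))
  g <- mrcohort:::piecewise_linear(c(0.5, 1.5), breaks = 1,
                                   slopes = c(2, 0))
  expect_equal(g, c(1, 2))
})
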