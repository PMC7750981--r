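# Build a scored cohort of unrelated individuals from a config.
make_scored_cohort <- function(cfg) {
  w <- simulate_variant_panel(cfg)
  sim <- simulate_unrelated(cfg, w)
  sim$cohort$score <- compute_grs(sim$genotypes, w)$rescaled
  list(cohort = sim$cohort, genotypes = sim$genotypes, weights = w)
}

# Build a scored sibship cohort from a config.
make_scored_sibs <- function(cfg) {
  w <- simulate_variant_panel(cfg)
  sim <- simulate_sibships(cfg, w)
  sim$cohort$score <- compute_grs(sim$genotypes, w)$rescaled
  list(cohort = sim$cohort, genotypes = sim$genotypes, weights = w)
}

# Two-variant weights fixture with explicit alleles.
tiny_weights <- function(beta = c(0.1, 0.2),
                         ea = c("A", "C"), oa = c("G", "T"),
                         freq = c(0.3, 0.5)) {
  data.frame(variant_id = c("rs1", "rs2"), effect_allele = ea,
             other_allele = oa, beta = beta, freq = freq,
             stringsAsFactors = FALSE)
}

tiny_dosages <- function(d, ids = sprintf("i%d", seq_len(nrow(d)))) {
  m <- as.matrix(d)
  dimnames(m) <- list(ids, c("rs1", "rs2")[seq_len(ncol(m))])
  m
}
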