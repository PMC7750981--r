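#' Align a dosage matrix to a variant-weights table
#'
#' Reorders the genotype columns to the order of the weights table and
#' orients every dosage to the weights' effect allele. A variant whose
#' stored effect/other alleles are the reverse of the weights' pair has its
#' dosage flipped to `2 - dosage`. Strand-ambiguous palindromic pairs (A/T
#' or C/G) cannot be flipped safely and raise an error instead.
#'
#' @param genotypes Individuals x variants dosage matrix with variant ids as
#'   column names.
#' @param weights Weights `data.frame` (`variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, ...).
#' @param genotype_alleles Optional `data.frame` (`variant_id`,
#'   `effect_allele`, `other_allele`) describing the allele the stored
#'   dosages count. If omitted, dosages are assumed to already count the
#'   weights' effect allele and only column reordering is performed.
#' @return The aligned dosage matrix.
#' @export
align_dosages <- function(genotypes, weights, genotype_alleles = NULL) {
  missing_v <- setdiff(weights$variant_id, colnames(genotypes))
  if (length(missing_v)) {
    stop("variants absent from genotype matrix: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  g <- genotypes[, weights$variant_id, drop = FALSE]
  if (is.null(genotype_alleles)) return(g)
  idx <- match(weights$variant_id, genotype_alleles$variant_id)
  if (anyNA(idx)) {
    stop("genotype_alleles is missing variants: ",
         paste(weights$variant_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  ga <- genotype_alleles[idx, , drop = FALSE]
  same <- ga$effect_allele == weights$effect_allele &
    ga$other_allele == weights$other_allele
  swapped <- ga$effect_allele == weights$other_allele &
    ga$other_allele == weights$effect_allele
  ambiguous <- paste0(weights$effect_allele, weights$other_allele) %in%
    c("AT", "TA", "CG", "GC")
  if (any(swapped & ambiguous)) {
    stop("strand-ambiguous allele mismatch (A/T or C/G) at: ",
         paste(weights$variant_id[swapped & ambiguous], collapse = ", "),
         call. = FALSE)
  }
  if (any(!same & !swapped)) {
    stop("irreconcilable alleles at: ",
         paste(weights$variant_id[!same & !swapped], collapse = ", "),
         call. = FALSE)
  }
  flip <- which(swapped)
  if (length(flip)) g[, flip] <- 2 - g[, flip, drop = FALSE]
  g
}

#' Weighted genetic risk score
#'
#' The per-individual dot product of aligned allele dosages with per-allele
#' weights: `sum_i beta_i * dosage_i`.
#'
#' @inheritParams align_dosages
#' @param impute_missing If `TRUE`, missing dosages are replaced by the
#'   per-variant mean dosage before scoring. The default is a hard error:
#'   silent imputation corrupts the score.
#' @return Named numeric vector of weighted scores.
#' @export
weighted_score <- function(genotypes, weights, impute_missing = FALSE) {
  g <- genotypes[, weights$variant_id, drop = FALSE]
  if (anyNA(g)) {
    if (!impute_missing) {
      stop("missing dosages present; set impute_missing = TRUE to use ",
           "per-variant mean imputation", call. = FALSE)
    }
    mu <- colMeans(g, na.rm = TRUE)
    for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  }
  drop(g %*% weights$beta)
}

#' Rescale a weighted score to the allele-count scale
#'
#' `rescaled_i = weighted_i * n_variants / sum(beta)`, so an individual
#' carrying one effect allele at every variant scores exactly `n_variants`,
#' and scores range over `[0, 2 * n_variants]` when all weights are
#' positive. The rescaling is linear, so every downstream IV estimate is
#' invariant to it.
#'
#' @param weighted Numeric vector of weighted scores.
#' @param weights Weights `data.frame`.
#' @return Rescaled score vector.
#' @export
rescale_score <- function(weighted, weights) {
  s <- sum(weights$beta)
  if (s == 0) {
    stop("sum of weights is zero; rescaled score undefined", call. = FALSE)
  }
  weighted * nrow(weights) / s
}

#' Drop variants from a weights table
#'
#' Removes the given variant ids (e.g. variants with known pleiotropic
#' effects on other traits) and reports the count retained. Unknown ids
#' trigger a warning, not an error.
#'
#' @param weights Weights `data.frame`.
#' @param exclusion_ids Character vector of variant ids to drop.
#' @return The filtered weights table.
#' @examples
#' w <- data.frame(variant_id = c("rs1", "rs2"), effect_allele = "A",
#'                 other_allele = "G", beta = c(0.1, 0.2))
#' exclude_variants(w, "rs2")
#' @export
exclude_variants <- function(weights, exclusion_ids) {
  unknown <- setdiff(exclusion_ids, weights$variant_id)
  if (length(unknown)) {
    warning("exclusion ids not in weights table: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- weights[!(weights$variant_id %in% exclusion_ids), , drop = FALSE]
  if (nrow(out) == 0L) warning("all variants excluded", call. = FALSE)
  message(nrow(out), " of ", nrow(weights), " variants retained")
  rownames(out) <- NULL
  out
}

#' Convenience: aligned, weighted and rescaled score per individual
#'
#' @inheritParams align_dosages
#' @inheritParams weighted_score
#' @return `data.frame` with `individual_id`, `weighted`, `rescaled`.
#' @export
compute_grs <- function(genotypes, weights, genotype_alleles = NULL,
                        impute_missing = FALSE) {
  g <- align_dosages(genotypes, weights, genotype_alleles)
  w <- weighted_score(g, weights, impute_missing)
  data.frame(
    individual_id = rownames(genotypes),
    weighted = unname(w),
    rescaled = unname(rescale_score(w, weights)),
    stringsAsFactors = FALSE
  )
}

#' Instrument strength: incremental R-squared and partial F
#'
#' Compares the regression of the exposure on covariates with and without
#' the score term, returning the incremental R-squared attributable to the
#' score and its partial F statistic.
#'
#' @param score Numeric instrument vector.
#' @param exposure Numeric exposure vector.
#' @param covariates Optional `data.frame` of covariates.
#' @return A list with `r2` (incremental), `f` (partial F), `df1`, `df2`
#'   and `p`.
#' @export
instrument_strength <- function(score, exposure, covariates = NULL) {
  keep <- stats::complete.cases(score, exposure,
                                if (is.null(covariates)) rep(0, length(score))
                                else covariates)
  score <- score[keep]
  exposure <- exposure[keep]
  n <- length(score)
  if (is.null(covariates)) {
    x0 <- matrix(1, n, 1)
  } else {
    covariates <- covariates[keep, , drop = FALSE]
    x0 <- stats::model.matrix(~ ., data = covariates)
  }
  if (qr(x0)$rank < ncol(x0)) {
    stop("covariates are rank deficient", call. = FALSE)
  }
  if (n <= ncol(x0) + 2L) stop("too few observations", call. = FALSE)
  fit0 <- stats::lm.fit(x0, exposure)
  fit1 <- stats::lm.fit(cbind(x0, score = score), exposure)
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  tss <- sum((exposure - mean(exposure))^2)
  df2 <- n - ncol(x0) - 1L
  f <- (rss0 - rss1) / (rss1 / df2)
  list(r2 = (rss0 - rss1) / tss, f = f, df1 = 1L, df2 = df2,
       p = stats::pf(f, 1, df2, lower.tail = FALSE))
}
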