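#' Read / write the standard file formats
#'
#' Variant weights travel as 5-column TSV (`variant_id`, `effect_allele`,
#' `other_allele`, `beta`, `freq`), cohort tables as CSV (header row,
#' UTF-8, '.' decimal), genotype dosages as TSV with individuals in rows
#' and an `individual_id` first column, and results as tidy CSV. A minimal
#' VCF 4.2 writer/reader with a per-sample `DS` (dosage) FORMAT field is
#' provided for interoperability; reading requires the vcfR package.
#'
#' @param weights,cohort,results `data.frame`s to write.
#' @param genotypes Individuals x variants dosage matrix.
#' @param path File path.
#' @name mrcohort-io
NULL

#' @rdname mrcohort-io
#' @export
write_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname mrcohort-io
#' @export
read_weights <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "beta")
  if (!all(need %in% names(w))) {
    stop("weights file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(w$variant_id)) {
    stop("duplicate variant ids in weights file", call. = FALSE)
  }
  if (any(w$effect_allele == w$other_allele)) {
    stop("effect and other allele identical for some variants",
         call. = FALSE)
  }
  w
}

#' @rdname mrcohort-io
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname mrcohort-io
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' @rdname mrcohort-io
#' @export
write_dosages <- function(genotypes, path) {
  df <- data.frame(individual_id = rownames(genotypes),
                   genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname mrcohort-io
#' @export
read_dosages <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0 | m > 2, na.rm = TRUE)) {
    stop("dosages outside [0, 2]", call. = FALSE)
  }
  m
}

#' @rdname mrcohort-io
#' @param weights Weights table supplying alleles for the VCF records.
#' @export
write_dosage_vcf <- function(genotypes, weights, path) {
  stopifnot(all(colnames(genotypes) == weights$variant_id))
  ids <- rownames(genotypes)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the alternate (effect) allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(genotypes))) {
    writeLines(paste(c("1", j, weights$variant_id[j],
                       weights$other_allele[j], weights$effect_allele[j],
                       ".", "PASS", ".", "DS",
                       format(genotypes[, j], trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname mrcohort-io
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  m <- t(ds)  # individuals in rows
  colnames(m) <- vcfR::getID(v)
  m
}

#' @rdname mrcohort-io
#' @export
write_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
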