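#' Rank-based inverse-normal transformation
#'
#' Replaces each non-missing value by the standard-normal quantile of its
#' Blom rank fraction, `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks
#' for ties so that equal inputs map to equal outputs. Missing values are
#' preserved in place. The transform is rank-preserving and invariant to any
#' strictly monotone re-labelling of the input.
#'
#' @param values Numeric vector, possibly with `NA`s.
#' @param variable_name Label stored in the returned transform record.
#' @return A list with `transformed` (same length as `values`) and `record`,
#'   a one-row `data.frame` (`variable_name`, `n_nonmissing`, `natural_sd`
#'   -- the SD of the raw non-missing values, used later to convert SD-scale
#'   effects back to natural units -- and `tie_policy`).
#' @examples
#' inverse_normal_transform(c(1, 2, 3))$transformed  # -0.8694 0 0.8694
#' @export
inverse_normal_transform <- function(values, variable_name = "value") {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2L) {
    stop("inverse_normal_transform needs at least 2 non-missing values",
         call. = FALSE)
  }
  v <- values[ok]
  if (max(v) == min(v)) {
    stop("inverse_normal_transform: all non-missing values are equal",
         call. = FALSE)
  }
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  record <- data.frame(
    variable_name = variable_name,
    n_nonmissing = n,
    natural_sd = stats::sd(v),
    tie_policy = "average-rank/Blom",
    stringsAsFactors = FALSE
  )
  list(transformed = out, record = record)
}

#' Convert an SD-scale effect to natural units
#'
#' Multiplies an effect expressed per SD of a transformed outcome by the SD
#' of that outcome in its original units. For example, with a deprivation
#' index whose natural SD is 2.99, an effect of 0.05 SD corresponds to
#' `0.05 * 2.99 = 0.150` index units.
#'
#' @param beta_sd Effect size on the SD scale.
#' @param natural_sd SD of the outcome in natural units; must be positive.
#' @param digits Decimal places for the reported value (default 3, matching
#'   conventional reporting); use `NULL` to skip rounding.
#' @return The effect in natural units.
#' @examples
#' sd_to_natural(0.05, 2.99)  # 0.150
#' @export
sd_to_natural <- function(beta_sd, natural_sd, digits = 3) {
  if (!is.numeric(natural_sd) || any(natural_sd <= 0)) {
    stop("natural_sd must be positive", call. = FALSE)
  }
  out <- beta_sd * natural_sd
  if (!is.null(digits)) out <- round(out, digits)
  out
}
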