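#' Allele-orientation harmonization
#'
#' Two canonical orientations are supported for plotting effect size against
#' allele frequency:
#'
#' * **minor_allele_signed** (the default, and the recommended convention):
#'   every record reports the minor allele, so frequencies lie in (0, 0.5] and
#'   effects keep their sign (risk-increasing or protective relative to the
#'   minor allele). A record with `eaf > 0.5` has its alleles swapped,
#'   `eaf := 1 - eaf`, `beta := -beta`.
#' * **positive_effect**: every record reports the trait-increasing allele, so
#'   effects are non-negative and frequencies span (0, 1). A record with
#'   `beta < 0` has its alleles swapped, `beta := -beta`, `eaf := 1 - eaf`.
#'
#' Both transforms are idempotent, leave `se`, `pvalue` and `n` untouched, and
#' preserve the per-variant variance contribution `2 f (1 - f) beta^2`, so
#' statistical power is orientation-invariant. Ties are deterministic:
#' `eaf == 0.5` is never flipped under the minor-allele convention, and
#' `beta == 0` is never flipped under the positive-effect convention (its sign
#' is undefined).
#'
#' The minor allele is defined from the study's own effect-allele frequency,
#' not a reference panel.
#'
#' @param x a [sumstats] table, or any data frame carrying the columns
#'   `eaf`, `beta`, `effect_allele`, `other_allele`.
#' @return An object of the same shape with records re-oriented.
#' @examples
#' df <- data.frame(variant_id = "rs1", chrom = "1", pos_bp = 1L,
#'                  effect_allele = "A", other_allele = "G",
#'                  eaf = 0.7, beta = 0.2, se = 0.01, pvalue = 1e-8)
#' ss <- sumstats(df, study_n = 1000)
#' to_minor_allele(ss)$eaf   # 0.3, beta flipped to -0.2
#' @export
to_minor_allele <- function(x) {
  flip_records(x, x$eaf > 0.5)
}

#' @rdname to_minor_allele
#' @export
to_positive_effect <- function(x) {
  flip_records(x, x$beta < 0)
}

flip_records <- function(x, flip) {
  flip <- !is.na(flip) & flip
  if (any(flip)) {
    ea <- x$effect_allele[flip]
    x$effect_allele[flip] <- x$other_allele[flip]
    x$other_allele[flip] <- ea
    x$eaf[flip] <- 1 - x$eaf[flip]
    x$beta[flip] <- -x$beta[flip]
  }
  x
}

#' Harmonize a whole table to one orientation
#'
#' @param table a [sumstats] table.
#' @param mode `"minor_allele_signed"` (default) or `"positive_effect"`.
#' @return The harmonized table; record order and table metadata are
#'   preserved.
#' @seealso [to_minor_allele()], [to_positive_effect()]
#' @export
harmonize_table <- function(table, mode = c("minor_allele_signed", "positive_effect")) {
  mode <- match.arg(mode)
  out <- switch(mode,
                minor_allele_signed = to_minor_allele(table),
                positive_effect = to_positive_effect(table))
  if (inherits(table, "sumstats")) out <- set_records(table, as.data.frame(out))
  attr(out, "orientation") <- mode
  out
}
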