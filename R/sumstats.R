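# canonical column order of a summary-statistics table
SUMSTATS_COLS <- c("variant_id", "chrom", "pos_bp", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n", "gene", "trait", "source")
SUMSTATS_MANDATORY <- c("variant_id", "chrom", "pos_bp", "effect_allele",
                        "other_allele", "eaf", "beta", "se", "pvalue")

# column-name synonyms recognised by dialect = "auto" (all lower-cased)
AUTO_DIALECT <- list(
  variant_id    = c("variant_id", "snp", "rsid", "id", "variant", "markername", "marker"),
  chrom         = c("chrom", "chr", "chromosome", "#chrom", "#chr"),
  pos_bp        = c("pos_bp", "pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "a1", "allele1", "ea", "alt", "effect_allele_1"),
  other_allele  = c("other_allele", "a2", "allele2", "oa", "nea", "ref", "non_effect_allele"),
  eaf           = c("eaf", "af", "freq", "frq", "a1freq", "effect_allele_frequency"),
  beta          = c("beta", "b", "effect", "es", "effect_size"),
  se            = c("se", "stderr", "standard_error", "sebeta"),
  pvalue        = c("pvalue", "p", "pval", "p_value", "pval"),
  n             = c("n", "nsample", "n_total", "samplesize"),
  gene          = c("gene", "gene_name", "nearest_gene"),
  trait         = c("trait", "phenotype", "trait_name"),
  source        = c("source", "study_type", "platform")
)

#' Construct a summary-statistics table
#'
#' A `sumstats` object is a data frame of per-variant association records
#' (one row per variant) carrying study metadata as attributes. Effects are on
#' the beta scale: per-allele regression coefficients for quantitative traits,
#' log odds ratios for binary traits. Odds ratios must be log-transformed
#' before they enter this container.
#'
#' Rows violating the record invariants (frequency strictly inside (0,1),
#' positive standard error, p-value in (0,1], positive position, distinct
#' alleles, unique variant id) are dropped and reported via the
#' `"rejected"` attribute, so that loaded + rejected rows always account for
#' every input row. A p-value of exactly 0 is clamped to the smallest positive
#' double with a warning rather than rejected, so that -log10(p) stays finite.
#'
#' @param records data frame with at least the mandatory columns
#'   `variant_id, chrom, pos_bp, effect_allele, other_allele, eaf, beta, se,
#'   pvalue`; optional `n`, `gene`, `trait`, `source`.
#' @param trait_name study trait label.
#' @param study_n study sample size (total); records without a per-variant `n`
#'   fall back to this value.
#' @param trait_model `"quantitative"` or `"binary"`.
#' @param n_cases,n_controls case/control counts, required downstream for
#'   binary-trait power.
#' @param sort sort records by (chrom, pos_bp)? Default `TRUE`.
#' @return A `sumstats` data frame, sorted by (chrom, pos_bp), with attributes
#'   `trait_name`, `study_n`, `trait_model`, `n_cases`, `n_controls` and
#'   `rejected` (a data frame with a `reason` column; zero rows if all input
#'   rows were valid).
#' @examples
#' df <- data.frame(variant_id = c("rs1", "rs2"), chrom = "1",
#'                  pos_bp = c(100L, 200L), effect_allele = c("A", "C"),
#'                  other_allele = c("G", "T"), eaf = c(0.3, 0.7),
#'                  beta = c(0.1, -0.2), se = 0.02, pvalue = c(1e-9, 1e-12))
#' ss <- sumstats(df, trait_name = "height", study_n = 10000)
#' nrow(ss)
#' @export
sumstats <- function(records, trait_name = "trait", study_n,
                     trait_model = c("quantitative", "binary"),
                     n_cases = NULL, n_controls = NULL, sort = TRUE) {
  trait_model <- match.arg(trait_model)
  if (!is_scalar_number(study_n) || study_n < 1) stop2("`study_n` must be a positive number")
  if (trait_model == "binary") {
    if (is.null(n_cases) || is.null(n_controls)) {
      stop2("binary trait model requires `n_cases` and `n_controls`")
    }
    if (abs(n_cases + n_controls - study_n) > 0.5) {
      stop2("`n_cases` + `n_controls` must equal `study_n`")
    }
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SUMSTATS_MANDATORY, names(records))
  if (length(missing_cols)) {
    stop2("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("n", "gene", "trait", "source")) {
    if (!opt %in% names(records)) {
      records[[opt]] <- if (opt == "n") NA_integer_ else NA_character_
    }
  }
  records <- records[SUMSTATS_COLS]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$pos_bp <- as.integer(records$pos_bp)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (num in c("eaf", "beta", "se", "pvalue")) records[[num]] <- as.numeric(records[[num]])
  records$n <- as.integer(records$n)
  for (chr in c("gene", "trait", "source")) {
    v <- as.character(records[[chr]])
    v[!is.na(v) & v == ""] <- NA_character_
    records[[chr]] <- v
  }
  records$source[is.na(records$source)] <- "gwas"

  clamp <- !is.na(records$pvalue) & records$pvalue == 0
  if (any(clamp)) {
    warning(sum(clamp), " p-value(s) of 0 clamped to the smallest positive double",
            call. = FALSE)
    records$pvalue[clamp] <- .Machine$double.xmin
  }

  chk <- validate_sumstats_records(records)
  records <- chk$valid
  if (!nrow(records)) stop2("no valid records remain after validation")
  if (nrow(chk$rejected)) {
    message(nrow(chk$rejected), " record(s) rejected during validation (see attr(x, \"rejected\"))")
  }
  if (sort) {
    records <- records[order(records$chrom, records$pos_bp, records$variant_id), , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(records,
            trait_name = trait_name,
            study_n = as.integer(round(study_n)),
            trait_model = trait_model,
            n_cases = if (is.null(n_cases)) NA_integer_ else as.integer(n_cases),
            n_controls = if (is.null(n_controls)) NA_integer_ else as.integer(n_controls),
            rejected = chk$rejected,
            class = c("sumstats", "data.frame"))
}

# row-level invariant checks; returns list(valid = , rejected = ) and guarantees
# nrow(valid) + nrow(rejected) == nrow(input)
validate_sumstats_records <- function(records) {
  reason <- character(nrow(records))
  flag <- function(bad, why) {
    bad <- !is.na(bad) & bad
    reason[bad & reason == ""] <<- why
  }
  flag(is.na(records$variant_id) | records$variant_id == "", "missing variant_id")
  flag(is.na(records$pos_bp) | records$pos_bp < 1, "pos_bp < 1 or missing")
  flag(is.na(records$eaf) | records$eaf <= 0 | records$eaf >= 1, "eaf outside (0,1)")
  flag(is.na(records$se) | records$se <= 0, "se <= 0 or missing")
  flag(is.na(records$pvalue) | records$pvalue <= 0 | records$pvalue > 1, "pvalue outside (0,1]")
  flag(is.na(records$beta), "missing beta")
  flag(is.na(records$effect_allele) | is.na(records$other_allele) |
         records$effect_allele == records$other_allele, "effect_allele == other_allele")
  flag(!is.na(records$n) & records$n < 1, "n < 1")
  dup <- duplicated(records$variant_id)
  flag(dup, "duplicate variant_id")
  ok <- reason == ""
  rejected <- records[!ok, , drop = FALSE]
  rejected$reason <- reason[!ok]
  rownames(rejected) <- NULL
  list(valid = records[ok, , drop = FALSE], rejected = rejected)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %d variants | trait '%s' | %s | N = %d\n",
              nrow(x), attr(x, "trait_name"), attr(x, "trait_model"),
              attr(x, "study_n")))
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej)) cat(sprintf("  (%d rejected rows, see attr(x, \"rejected\"))\n", nrow(rej)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

resolve_dialect <- function(header, dialect) {
  lower <- tolower(header)
  map <- character(0)
  if (identical(dialect, "auto")) {
    for (canon in names(AUTO_DIALECT)) {
      hit <- which(lower %in% AUTO_DIALECT[[canon]])
      if (length(hit)) map[[canon]] <- header[hit[1L]]
    }
  } else {
    if (is.null(names(dialect)) || any(names(dialect) == "")) {
      stop2("`dialect` must be a named character vector: canonical_name = file_column")
    }
    bad <- setdiff(names(dialect), SUMSTATS_COLS)
    if (length(bad)) stop2("unknown canonical column(s) in dialect: ", paste(bad, collapse = ", "))
    absent <- setdiff(unname(dialect), header)
    if (length(absent)) stop2("dialect refers to column(s) not in the file: ", paste(absent, collapse = ", "))
    map <- dialect
  }
  unresolved <- setdiff(SUMSTATS_MANDATORY, names(map))
  if (length(unresolved)) {
    stop2("could not resolve mandatory column(s): ", paste(unresolved, collapse = ", "))
  }
  map
}

#' Read a summary-statistics table from delimited text
#'
#' Reads a tab- or comma-delimited file with a header row, resolves column
#' names to the canonical schema, validates every row, and returns a
#' [sumstats] table. The `"auto"` dialect recognises the common column-name
#' synonyms used across GWAS sumstats dialects (SNP/rsid/variant_id,
#' A1/effect_allele, AF/EAF/freq, BETA/b/effect, SE, P/pval, ...); an explicit
#' dialect is a named character vector, e.g.
#' `c(variant_id = "MarkerName", eaf = "Freq1")`, merged over auto-resolution
#' of the remaining columns.
#'
#' @param path file path (TSV canonical; CSV accepted).
#' @param dialect `"auto"` or a named character vector mapping canonical
#'   column names to file column names.
#' @inheritParams sumstats
#' @return A validated [sumstats] table sorted by (chrom, pos_bp); rejected
#'   rows are reported in `attr(x, "rejected")`.
#' @export
read_sumstats <- function(path, dialect = "auto", trait_name = "trait",
                          study_n, trait_model = c("quantitative", "binary"),
                          n_cases = NULL, n_controls = NULL) {
  if (!file.exists(path)) stop2("file not found: ", path)
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           na.strings = c("", "NA"))
  if (!nrow(raw)) stop2("empty table: ", path)
  if (!identical(dialect, "auto")) {
    # user mapping wins; auto fills the rest
    auto <- tryCatch(resolve_dialect(names(raw), "auto"), error = function(e) character(0))
    dialect <- c(dialect, auto[setdiff(names(auto), names(dialect))])
  }
  map <- resolve_dialect(names(raw), dialect)
  out <- raw[unname(map)]
  names(out) <- names(map)
  sumstats(out, trait_name = trait_name, study_n = study_n,
           trait_model = trait_model, n_cases = n_cases, n_controls = n_controls)
}

#' Write a summary-statistics table to canonical TSV
#'
#' Canonical tab-delimited output with the full column schema; absent optional
#' fields are written as empty cells and read back as absent, so
#' `read_sumstats(write_sumstats(x))` is the identity on all canonical fields.
#'
#' @param table a [sumstats] object with at least one record.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  if (!inherits(table, "sumstats")) stop2("`table` must be a sumstats object")
  if (!nrow(table)) stop2("refusing to write an empty sumstats table")
  df <- as.data.frame(table)[SUMSTATS_COLS]
  for (num in c("eaf", "beta", "se", "pvalue")) df[[num]] <- fmt_num(df[[num]], 17)
  ok <- tryCatch({
    data.table::fwrite(df, path, sep = "\t", na = "", quote = FALSE)
    TRUE
  }, error = function(e) stop2("cannot write to '", path, "': ", conditionMessage(e)))
  invisible(path)
}

# study metadata accessors --------------------------------------------------

#' Study metadata of a sumstats table
#' @param x a [sumstats] object.
#' @return `study_n()`: the study sample size; `trait_model()`: model string.
#' @export
study_n <- function(x) attr(x, "study_n")

#' @rdname study_n
#' @export
trait_model <- function(x) attr(x, "trait_model")

# replace the records of a sumstats table, keeping metadata (internal)
set_records <- function(table, records, sort = FALSE) {
  at <- attributes(table)
  if (sort) {
    records <- records[order(records$chrom, records$pos_bp, records$variant_id), , drop = FALSE]
  }
  rownames(records) <- NULL
  attributes(records) <- c(attributes(records)[c("names", "row.names")],
                           at[c("trait_name", "study_n", "trait_model",
                                "n_cases", "n_controls", "rejected")],
                           list(class = c("sumstats", "data.frame")))
  records
}
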