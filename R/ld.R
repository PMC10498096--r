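#' LD reference panel
#'
#' A symmetric matrix of pairwise allelic correlations `r` between variants,
#' keyed by variant id and annotated with genomic position. Correlations are
#' signed and assumed oriented to the same effect alleles as the
#' summary-statistics table they will be used with (this is automatic when the
#' matrix is computed from effect-allele dosages with [ld_from_genotypes()]);
#' re-orienting a variant's alleles flips the sign of its row and column,
#' which matters for stepwise selection but not for `r^2`-based clumping.
#'
#' @param R square symmetric correlation matrix (base matrix or sparse
#'   `Matrix`), unit diagonal, entries in `[-1, 1]`.
#' @param variant_ids unique variant ids, one per row of `R`; taken from
#'   `rownames(R)` when omitted.
#' @param pos_bp per-variant base-pair positions.
#' @param chrom per-variant chromosome labels (recycled; default `"1"`).
#' @return An `ld_reference` object.
#' @export
ld_reference <- function(R, variant_ids = rownames(R), pos_bp, chrom = "1") {
  if (is.null(variant_ids)) stop2("`variant_ids` required when R has no rownames")
  m <- length(variant_ids)
  if (nrow(R) != m || ncol(R) != m) stop2("R must be ", m, " x ", m)
  if (anyDuplicated(variant_ids)) stop2("variant ids in the LD reference must be unique")
  if (length(pos_bp) != m) stop2("`pos_bp` must have one position per variant")
  dg <- Matrix::diag(R)
  if (any(abs(dg - 1) > 1e-8)) stop2("LD matrix must have unit diagonal")
  if (max(abs(R - Matrix::t(R))) > 1e-8) stop2("LD matrix must be symmetric")
  if (max(abs(R)) > 1 + 1e-8) stop2("correlations must lie in [-1, 1]")
  dimnames(R) <- list(variant_ids, variant_ids)
  structure(list(R = R, variant_ids = as.character(variant_ids),
                 pos_bp = as.integer(pos_bp),
                 chrom = rep_len(as.character(chrom), m)),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d variants, %d chromosome(s)\n",
              length(x$variant_ids), length(unique(x$chrom))))
  invisible(x)
}

#' Compute an LD reference from a genotype matrix
#'
#' Pearson correlation of dosage columns (individuals in rows, variants in
#' columns, dosages 0/1/2 of the effect allele).
#'
#' @param G numeric genotype matrix with column names as variant ids.
#' @param pos_bp per-variant positions; defaults to the column index.
#' @param chrom per-variant chromosome labels.
#' @return An [ld_reference].
#' @export
ld_from_genotypes <- function(G, pos_bp = seq_len(ncol(G)), chrom = "1") {
  G <- as.matrix(G)
  if (nrow(G) < 2) stop2("need at least 2 individuals")
  if (is.null(colnames(G))) colnames(G) <- paste0("v", seq_len(ncol(G)))
  sds <- apply(G, 2, function(col) stats::sd(col))
  if (any(sds == 0)) {
    stop2("monomorphic variant(s): ", paste(colnames(G)[sds == 0], collapse = ", "))
  }
  ld_reference(cor(G), colnames(G), pos_bp = pos_bp, chrom = chrom)
}

#' Read an LD matrix or genotype matrix from TSV
#'
#' Accepts either a square correlation matrix with a variant-id header (and
#' the same ids as a first column or as rownames), or an individuals-by-
#' variants genotype dosage table, distinguished by `kind`.
#'
#' @param path TSV path.
#' @param kind `"matrix"` (correlations) or `"genotypes"`.
#' @param pos_bp,chrom per-variant annotations (see [ld_reference()]).
#' @return An [ld_reference].
#' @export
read_ld <- function(path, kind = c("matrix", "genotypes"), pos_bp = NULL, chrom = "1") {
  kind <- match.arg(kind)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (kind == "matrix" && !is.numeric(df[[1]])) {
    rownames(df) <- df[[1]]
    df <- df[-1]
  }
  M <- as.matrix(df)
  if (kind == "genotypes") {
    return(ld_from_genotypes(M, pos_bp = pos_bp %||% seq_len(ncol(M)), chrom = chrom))
  }
  ld_reference(M, colnames(M), pos_bp = pos_bp %||% seq_len(ncol(M)), chrom = chrom)
}

# extract the dense correlation submatrix for a set of ids
ld_submatrix <- function(ld, ids) {
  idx <- match(ids, ld$variant_ids)
  as.matrix(ld$R[idx, idx, drop = FALSE])
}

ld_lookup <- function(ld, ids_a, ids_b) {
  as.matrix(ld$R[match(ids_a, ld$variant_ids), match(ids_b, ld$variant_ids), drop = FALSE])
}
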