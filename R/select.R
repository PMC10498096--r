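#' Identify independent significant variants
#'
#' Correlated variants near a causal site all show significant associations
#' through linkage disequilibrium alone, so trumpet plots are most readable
#' when restricted to variants that represent distinct association signals.
#' Two selection methods are provided:
#'
#' * [clump()] — greedy LD clumping: pick the most significant unassigned
#'   variant as a lead, absorb every unassigned variant on the same chromosome
#'   within `window_bp` of the lead **and** in LD at `r^2 >= r2_threshold`,
#'   repeat until all significant variants are assigned.
#' * [stepwise_select()] — approximate conditional/joint analysis from
#'   summary statistics plus the LD reference: forward stepwise selection in
#'   which each candidate is evaluated conditional on the variants already in
#'   the model, and joint effect estimates are reported for the final set.
#'
#' @name ld_select
NULL

# common candidate filter; errors if candidates are missing from the LD panel
selection_candidates <- function(table, ld, p_threshold, maf_min = 0) {
  maf <- pmin(table$eaf, 1 - table$eaf)
  keep <- table$pvalue < p_threshold & maf > maf_min
  cand <- as.data.frame(table)[keep, , drop = FALSE]
  if (nrow(cand)) {
    missing <- setdiff(cand$variant_id, ld$variant_ids)
    if (length(missing)) {
      stop2("candidate variant(s) absent from the LD reference: ",
            paste(utils::head(missing, 20), collapse = ", "),
            if (length(missing) > 20) sprintf(" ... (%d total)", length(missing)) else "")
    }
  }
  cand
}

new_selection_result <- function(leads, membership, method) {
  structure(list(lead_ids = leads$variant_id, leads = leads,
                 membership = membership, method = method),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method = %s, %d lead variant(s)\n",
              x$method, length(x$lead_ids)))
  print.data.frame(utils::head(x$leads, 10), ...)
  invisible(x)
}

#' Greedy LD clumping
#'
#' Restricts to variants with minor allele frequency above `maf_min` and
#' association p-value below `p_threshold`, then repeatedly takes the
#' unassigned variant with the smallest p-value as a lead and absorbs all
#' unassigned variants on the same chromosome with position within
#' `window_bp` of the lead and squared correlation at least `r2_threshold`.
#' The window is measured lead-to-candidate (not chained), and absorption
#' requires the window and `r^2` conditions jointly, so a distant variant in
#' high LD stays un-absorbed. P-value ties are broken by distance to the
#' current lead, then lexicographic id, making the output independent of the
#' input row order.
#'
#' The result is a partition: every significant variant is exactly one lead
#' or absorbed by exactly one lead, and no two leads jointly satisfy the
#' (window and `r^2`) condition.
#'
#' @param table a [sumstats] table.
#' @param ld an [ld_reference] covering every candidate.
#' @param p_threshold significance threshold, default genome-wide `5e-8`.
#' @param r2_threshold minimum squared correlation for absorption, default
#'   0.1.
#' @param window_bp half-window around the lead in base pairs, default
#'   100,000 (a 100-kb window).
#' @param maf_min minor-allele-frequency filter, default 0.01.
#' @return A `selection_result` with `method = "clump"`: `lead_ids` in
#'   selection order, a `leads` data frame (id, chrom, pos, marginal effect,
#'   se, p, `n_absorbed`), and `membership` mapping each lead to its absorbed
#'   ids. An empty candidate set yields an empty result, not an error.
#' @export
clump <- function(table, ld, p_threshold = 5e-8, r2_threshold = 0.1,
                  window_bp = 100000L, maf_min = 0.01) {
  check_prob(p_threshold, "p_threshold")
  check_prob(r2_threshold, "r2_threshold", open_left = FALSE, open_right = FALSE)
  cand <- selection_candidates(table, ld, p_threshold, maf_min)
  leads <- cand[0, , drop = FALSE]
  membership <- list()
  if (!nrow(cand)) {
    leads$n_absorbed <- integer(0)
    return(new_selection_result(leads, membership, "clump"))
  }
  cand <- cand[order(cand$pvalue, cand$variant_id), , drop = FALSE]
  assigned <- rep(FALSE, nrow(cand))
  lead_rows <- integer(0)
  while (!all(assigned)) {
    open <- which(!assigned)
    # smallest P among unassigned; order above makes ties lexicographic in id
    li <- open[1L]
    lead <- cand[li, ]
    assigned[li] <- TRUE
    open <- setdiff(open, li)
    absorbed <- character(0)
    if (length(open)) {
      same_chr <- cand$chrom[open] == lead$chrom
      in_window <- abs(cand$pos_bp[open] - lead$pos_bp) <= window_bp
      hits <- open[same_chr & in_window]
      if (length(hits)) {
        r <- drop(ld_lookup(ld, cand$variant_id[hits], lead$variant_id))
        hits <- hits[r^2 >= r2_threshold]
        if (length(hits)) {
          assigned[hits] <- TRUE
          absorbed <- cand$variant_id[hits]
        }
      }
    }
    lead_rows <- c(lead_rows, li)
    membership[[lead$variant_id]] <- absorbed
  }
  leads <- cand[lead_rows, , drop = FALSE]
  leads$n_absorbed <- lengths(membership[leads$variant_id])
  rownames(leads) <- NULL
  new_selection_result(leads, membership, "clump")
}

#' Forward stepwise conditional/joint selection from summary statistics
#'
#' Approximates a conditional and joint multi-variant analysis using only
#' marginal summary statistics and an LD reference. Marginal effects are
#' standardized to the correlation scale, `b = z / sqrt(n)` with
#' `z = beta / se`; for a selected set S with LD submatrix `R_S`, the joint
#' standardized effects are `R_S^{-1} b_S`, and a candidate c is evaluated by
#' its conditional z-score
#' `(z_c - R_{c,S} R_S^{-1} z_S) / sqrt(1 - R_{c,S} R_S^{-1} R_{S,c})`.
#' Selection starts from the smallest marginal p-value, adds at each step the
#' candidate with the smallest conditional p-value if it is below
#' `p_threshold`, and stops when none qualifies. Joint estimates are
#' back-transformed to the input beta scale.
#'
#' The procedure runs per chromosome, and correlations between variants more
#' than `window_bp` apart are treated as zero (a banded approximation
#' appropriate to the local range of LD). Candidates whose maximum `r^2` with
#' the selected set exceeds `collinearity_r2_cap` are skipped, as is any
#' candidate that would make the selected-set LD matrix numerically singular
#' (condition number above 1e8; a warning names the variant).
#'
#' With an identity LD matrix the procedure reduces exactly to marginal
#' thresholding with joint estimates equal to the marginal ones.
#'
#' @inheritParams clump
#' @param collinearity_r2_cap maximum `r^2` to the selected set, default 0.9.
#' @return A `selection_result` with `method = "stepwise"`; `leads` carries
#'   both marginal (`beta`, `se`, `pvalue`) and joint (`joint_beta`,
#'   `joint_se`, `joint_p`) estimates.
#' @export
stepwise_select <- function(table, ld, p_threshold = 5e-8, window_bp = 100000L,
                            collinearity_r2_cap = 0.9) {
  check_prob(p_threshold, "p_threshold")
  cand <- selection_candidates(table, ld, p_threshold, maf_min = 0)
  if (!nrow(cand)) {
    leads <- cand
    leads$joint_beta <- leads$joint_se <- leads$joint_p <- numeric(0)
    return(new_selection_result(leads, list(), "stepwise"))
  }
  nvec <- ifelse(is.na(cand$n), study_n(table), cand$n)
  if (any(is.na(nvec))) stop2("per-variant n unavailable and study_n missing")
  cand$.n <- nvec
  cand$.z <- cand$beta / cand$se

  pieces <- lapply(split(cand, cand$chrom), stepwise_one_chrom,
                   ld = ld, p_threshold = p_threshold,
                   window_bp = window_bp, cap = collinearity_r2_cap)
  leads <- do.call(rbind, pieces)
  leads <- leads[order(leads$pvalue, leads$variant_id), , drop = FALSE]
  leads$.n <- leads$.z <- NULL
  rownames(leads) <- NULL
  new_selection_result(leads, setNames(rep(list(character(0)), nrow(leads)),
                                       leads$variant_id), "stepwise")
}

stepwise_one_chrom <- function(cand, ld, p_threshold, window_bp, cap) {
  m <- nrow(cand)
  R <- ld_submatrix(ld, cand$variant_id)
  # banded approximation: LD beyond the window is treated as absent
  dist <- abs(outer(cand$pos_bp, cand$pos_bp, "-"))
  R[dist > window_bp] <- 0
  diag(R) <- 1
  z <- cand$.z
  sel <- integer(0)
  avail <- order(cand$pvalue, cand$variant_id)   # deterministic candidate order
  repeat {
    rem <- setdiff(avail, sel)
    if (!length(rem)) break
    if (!length(sel)) {
      best <- rem[1L]
      if (cand$pvalue[best] >= p_threshold) break
      sel <- best
      next
    }
    Rs <- R[sel, sel, drop = FALSE]
    Rinv <- solve(Rs)
    zs <- z[sel]
    cond_z <- rep(NA_real_, length(rem))
    for (k in seq_along(rem)) {
      c_i <- rem[k]
      r_cs <- R[c_i, sel]
      if (max(r_cs^2) > cap) next
      v <- 1 - drop(r_cs %*% Rinv %*% r_cs)
      if (v < 1e-8) next
      if (kappa(R[c(sel, c_i), c(sel, c_i)]) > 1e8) {
        warning("skipping near-singular candidate ", cand$variant_id[c_i], call. = FALSE)
        next
      }
      cond_z[k] <- (z[c_i] - drop(r_cs %*% Rinv %*% zs)) / sqrt(v)
    }
    cond_p <- 2 * pnorm(-abs(cond_z))
    if (all(is.na(cond_p)) || min(cond_p, na.rm = TRUE) >= p_threshold) break
    sel <- c(sel, rem[which.min(cond_p)])
  }
  leads <- cand[sel, , drop = FALSE]
  if (nrow(leads)) {
    Rs <- R[sel, sel, drop = FALSE]
    Rinv <- solve(Rs)
    b_std <- z[sel] / sqrt(cand$.n[sel])
    b_joint_std <- drop(Rinv %*% b_std)
    scale <- leads$se * sqrt(leads$.n)           # beta = b_std * se * sqrt(n)
    leads$joint_beta <- b_joint_std * scale
    leads$joint_se <- sqrt(diag(Rinv)) * leads$se
    leads$joint_p <- 2 * pnorm(-abs(leads$joint_beta / leads$joint_se))
  } else {
    leads$joint_beta <- leads$joint_se <- leads$joint_p <- numeric(0)
  }
  leads
}

#' Write a selection result as TSV
#'
#' @param result a `selection_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  df <- result$leads
  num <- intersect(c("eaf", "beta", "se", "pvalue", "joint_beta", "joint_se", "joint_p"),
                   names(df))
  for (cn in num) df[[cn]] <- fmt_num(df[[cn]], 10)
  data.table::fwrite(df, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}
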