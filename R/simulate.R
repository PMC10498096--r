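#' Simulation configuration
#'
#' Parameters of the synthetic mixed common+rare architecture used for
#' fixtures and oracle tests. Common, array-like variants get minor allele
#' frequencies log10-uniform on `[-2, -0.3]` and sit in LD blocks; rare,
#' exome-like variants get frequencies log10-uniform on `[-5, -2]`, are
#' emitted LD-free (singleton-like), tagged `source = "exome"` and given gene
#' labels. Causal effects follow the standard frequency-dependent
#' architecture family
#' \deqn{\beta \mid \mathrm{causal} \sim N\!\big(0,\ \tau^2 / (2f(1-f))^{\gamma}\big)}
#' so that `gamma = 0` gives frequency-independent effects, `gamma = 1` gives
#' equal expected per-variant variance explained across the spectrum, and the
#' default `gamma = 0.5` produces the characteristic trumpet: many common
#' variants of small effect and a rare tail of large effects. Within an LD
#' block all variants share one frequency (LD partners have similar
#' frequencies, and it makes the copula correlation target exactly
#' attainable); the number of causal variants is exactly
#' `round(causal_fraction * m)` for reproducible architecture.
#'
#' @param seed integer RNG seed; every simulation op is deterministic given
#'   the config.
#' @param n_gwas study sample size behind the emitted statistics; default
#'   351,550 (a typical large-biobank GWAS sample size).
#' @param m_common,m_rare numbers of common and rare variants.
#' @param causal_fraction fraction of variants that are causal, default 0.3.
#' @param tau architecture scale parameter (per-variant standard deviation of
#'   the variance-explained contribution at `gamma = 1`), default 0.02 on the
#'   standardized-phenotype scale.
#' @param gamma architecture exponent in `[0, 1]`, default 0.5.
#' @param ld_blocks data frame with columns `size` and `rho` describing
#'   common-variant LD blocks, recycled across the common variants; default
#'   blocks of 5 variants at genotype correlation 0.7.
#' @param n_individuals cohort size for [simulate_cohort()], default 2000.
#' @param trait_name trait label on emitted tables.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_gwas = 351550L, m_common = 1000L, m_rare = 250L,
                       causal_fraction = 0.3, tau = 0.02, gamma = 0.5,
                       ld_blocks = data.frame(size = 5L, rho = 0.7),
                       n_individuals = 2000L, trait_name = "simulated_trait") {
  if (m_common < 0 || m_rare < 0) stop2("variant counts must be >= 0")
  if (m_common + m_rare < 1) stop2("need at least one variant")
  if (gamma < 0 || gamma > 1) stop2("`gamma` must lie in [0, 1]")
  check_prob(causal_fraction, "causal_fraction", open_left = FALSE, open_right = FALSE)
  if (tau <= 0) stop2("`tau` must be positive")
  ld_blocks <- as.data.frame(ld_blocks)
  if (!all(c("size", "rho") %in% names(ld_blocks))) stop2("`ld_blocks` needs `size` and `rho` columns")
  if (any(ld_blocks$rho < 0 | ld_blocks$rho >= 1)) stop2("block `rho` must lie in [0, 1)")
  if (any(ld_blocks$size < 1)) stop2("block sizes must be >= 1")
  structure(list(seed = as.integer(seed), n_gwas = as.integer(n_gwas),
                 m_common = as.integer(m_common), m_rare = as.integer(m_rare),
                 causal_fraction = causal_fraction, tau = tau, gamma = gamma,
                 ld_blocks = ld_blocks, n_individuals = as.integer(n_individuals),
                 trait_name = trait_name),
            class = "sim_config")
}

# draw the variant architecture (positions, frequencies, LD blocks, true
# effects, emitted orientation); consumes RNG state
draw_architecture <- function(config) {
  m_c <- config$m_common; m_r <- config$m_rare
  # common variants: cyclic LD blocks, one shared frequency per block
  block_sizes <- integer(0); block_rhos <- numeric(0)
  i <- 1L
  while (sum(block_sizes) < m_c) {
    row <- ((i - 1L) %% nrow(config$ld_blocks)) + 1L
    block_sizes <- c(block_sizes, config$ld_blocks$size[row])
    block_rhos <- c(block_rhos, config$ld_blocks$rho[row])
    i <- i + 1L
  }
  if (length(block_sizes)) {
    over <- sum(block_sizes) - m_c
    block_sizes[length(block_sizes)] <- block_sizes[length(block_sizes)] - over
    keep <- block_sizes > 0
    block_sizes <- block_sizes[keep]; block_rhos <- block_rhos[keep]
  }
  n_blocks <- length(block_sizes)
  block_f <- 10^runif(n_blocks, -2, -0.3)
  block_id <- rep(seq_len(n_blocks), block_sizes)
  f_common <- block_f[block_id]
  rho_common <- block_rhos[block_id]
  within <- unlist(lapply(block_sizes, seq_len), use.names = FALSE)
  # blocks round-robin over 20 autosome-like chromosomes, 300-kb apart within
  # a chromosome so distinct blocks never share a clumping window
  chrom_common <- sprintf("%02d", ((block_id - 1L) %% 20L) + 1L)
  chrom_rank <- (block_id - 1L) %/% 20L
  pos_common <- chrom_rank * 300000L + 1L + (within - 1L) * 10000L

  f_rare <- 10^runif(m_r, -5, -2)
  m <- m_c + m_r
  arch <- data.frame(
    variant_id = sprintf("v%06d", seq_len(m)),
    chrom = c(chrom_common, rep("22", m_r)),
    pos_bp = c(pos_common, seq_len(m_r) * 50000L),
    block = c(block_id, if (m_r) max(c(block_id, 0L)) + seq_len(m_r) else integer(0)),
    rho = c(rho_common, rep(0, m_r)),
    maf = c(f_common, f_rare),
    source = rep(c("gwas", "exome"), c(m_c, m_r)),
    gene = c(rep(NA_character_, m_c), if (m_r) sprintf("GENE%04d", seq_len(m_r)) else character(0)),
    stringsAsFactors = FALSE)

  n_causal <- round(config$causal_fraction * m)
  causal <- rep(FALSE, m)
  if (n_causal > 0) causal[sample.int(m, n_causal)] <- TRUE
  sd_beta <- config$tau / (2 * arch$maf * (1 - arch$maf))^(config$gamma / 2)
  arch$beta_true <- ifelse(causal, rnorm(m, 0, sd_beta), 0)
  arch$causal <- causal
  # emitted allele orientation: common variants report either allele
  arch$flip <- c(runif(m_c) < 0.5, rep(FALSE, m_r))
  allele_pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4, m, replace = TRUE)
  arch$effect_allele <- allele_pairs[pick, 1]
  arch$other_allele <- allele_pairs[pick, 2]
  arch
}

#' Simulate a GWAS/exome summary-statistics table
#'
#' Draws an architecture per the config, then emits marginal statistics:
#' `se = 1 / sqrt(n_gwas * 2 f (1-f))` (standardized phenotype),
#' `beta = beta_true + Normal(0, se^2)`, and a two-sided Wald p-value from
#' `z = beta / se`, so that (beta, se, p) are mutually consistent by
#' construction. Roughly half the common records are emitted on the
#' major-allele orientation (frequency above 0.5, flipped effect sign) so the
#' harmonization step is exercised. Deterministic given the config seed.
#'
#' @param config a [sim_config].
#' @return A list: `sumstats` (the emitted [sumstats] table), `truth` (per
#'   variant: minor-allele frequency, true effect on the emitted orientation,
#'   causal flag, LD block), and `ld` (the block-diagonal true-LD
#'   [ld_reference] in table order, sparse for large m).
#' @export
simulate_sumstats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  arch <- draw_architecture(config)
  f <- arch$maf
  se <- 1 / sqrt(config$n_gwas * 2 * f * (1 - f))
  beta_hat <- arch$beta_true + rnorm(nrow(arch), 0, se)
  eaf <- ifelse(arch$flip, 1 - f, f)
  beta_emit <- ifelse(arch$flip, -beta_hat, beta_hat)
  ea <- ifelse(arch$flip, arch$other_allele, arch$effect_allele)
  oa <- ifelse(arch$flip, arch$effect_allele, arch$other_allele)
  z <- beta_hat / se
  pvalue <- 2 * pnorm(-abs(z))
  pvalue[pvalue == 0] <- .Machine$double.xmin
  records <- data.frame(
    variant_id = arch$variant_id, chrom = arch$chrom, pos_bp = arch$pos_bp,
    effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta_emit,
    se = se, pvalue = pvalue, n = config$n_gwas, gene = arch$gene,
    trait = config$trait_name, source = arch$source, stringsAsFactors = FALSE)
  ss <- sumstats(records, trait_name = config$trait_name, study_n = config$n_gwas)
  truth <- data.frame(variant_id = arch$variant_id, maf = f,
                      beta_true = ifelse(arch$flip, -arch$beta_true, arch$beta_true),
                      causal = arch$causal, block = arch$block,
                      stringsAsFactors = FALSE)
  list(sumstats = ss, truth = truth, ld = architecture_ld(arch))
}

# true block-diagonal LD of an architecture, ordered like the sorted table
architecture_ld <- function(arch) {
  ord <- order(arch$chrom, arch$pos_bp, arch$variant_id)
  arch <- arch[ord, , drop = FALSE]
  blocks <- split(seq_len(nrow(arch)), arch$block)[as.character(unique(arch$block))]
  mats <- lapply(blocks, function(idx) {
    k <- length(idx)
    M <- matrix(arch$rho[idx[1]], k, k); diag(M) <- 1
    M
  })
  R <- if (nrow(arch) > 2000) Matrix::bdiag(mats) else as.matrix(Matrix::bdiag(mats))
  ld_reference(R, arch$variant_id, pos_bp = arch$pos_bp, chrom = arch$chrom)
}

# latent (tetrachoric-style) correlation needed so that thresholded Gaussian
# haplotypes at frequency f reach allele correlation r
latent_rho <- function(r, f) {
  if (r <= 0) return(r)
  t <- qnorm(f)
  p11 <- function(rho) {
    integrate(function(z) dnorm(z) * pnorm((t - rho * z) / sqrt(1 - rho^2)),
              -Inf, t, rel.tol = 1e-10)$value
  }
  target <- f^2 + r * f * (1 - f)
  uniroot(function(rho) p11(rho) - target, c(1e-9, 1 - 1e-9), tol = 1e-9)$root
}

# achieved allele correlation for a latent correlation (used to report back)
achieved_allele_r <- function(rho, f) {
  t <- qnorm(f)
  p11 <- integrate(function(z) dnorm(z) * pnorm((t - rho * z) / sqrt(1 - rho^2)),
                   -Inf, t, rel.tol = 1e-10)$value
  (p11 - f^2) / (f * (1 - f))
}

#' Simulate an individual-level cohort matching the architecture
#'
#' Generates genotypes for the config's common variants (rare variants are
#' essentially monomorphic at cohort scale and are excluded) and a
#' quantitative phenotype. Within each LD block, haplotypes come from a
#' Gaussian copula: exchangeable latent normals with the latent correlation
#' calibrated (by numerically inverting the threshold-bivariate-normal
#' relation) so that allele dosages achieve the block's target genotype
#' correlation `rho`; two haplotypes sum to a Binomial(2, f)-margin genotype.
#' The phenotype is `G beta_true` plus Gaussian noise scaled so the total
#' variance is approximately 1. The same config seed yields an architecture
#' identical to [simulate_sumstats()], so cohort-derived marginal statistics
#' (see [cohort_sumstats()]) estimate the same true effects.
#'
#' @param config a [sim_config] with `n_individuals >= 100`.
#' @return A list: `G` (individuals x variants dosage matrix with variant-id
#'   column names), `y` (phenotype vector), `truth`, `pos_bp`, `chrom`, and
#'   `ld` (the true block LD of the simulated variants).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_individuals < 100) stop2("`n_individuals` must be >= 100")
  if (config$m_common < 1) stop2("cohort simulation needs at least one common variant")
  set.seed(config$seed)
  arch <- draw_architecture(config)
  arch <- arch[arch$source == "gwas", , drop = FALSE]
  n <- config$n_individuals
  m <- nrow(arch)
  G <- matrix(0L, n, m, dimnames = list(NULL, arch$variant_id))
  for (b in unique(arch$block)) {
    idx <- which(arch$block == b)
    k <- length(idx)
    f <- arch$maf[idx[1]]
    rho <- arch$rho[idx[1]]
    rl <- if (k > 1 && rho > 0) latent_rho(rho, f) else 0
    if (k > 1 && rho > 0) {
      ach <- achieved_allele_r(rl, f)
      if (abs(ach - rho) > 0.02) {
        warning(sprintf("block %s: requested r = %.3f, achieved %.3f at f = %.2g",
                        b, rho, ach, f), call. = FALSE)
      }
    }
    t <- qnorm(f)
    hap <- function() {
      W <- rnorm(n)
      Z <- sqrt(rl) * matrix(W, n, k) + sqrt(1 - rl) * matrix(rnorm(n * k), n, k)
      (Z < t) + 0L
    }
    G[, idx] <- hap() + hap()
  }
  gvar <- drop(G %*% arch$beta_true)
  vg <- stats::var(gvar)
  noise_sd <- sqrt(max(1 - vg, 0.05))
  y <- gvar + rnorm(n, 0, noise_sd)
  list(G = G, y = y,
       truth = data.frame(variant_id = arch$variant_id, maf = arch$maf,
                          beta_true = arch$beta_true, causal = arch$causal,
                          block = arch$block, stringsAsFactors = FALSE),
       pos_bp = arch$pos_bp, chrom = arch$chrom,
       ld = architecture_ld(arch))
}

#' Marginal summary statistics from an individual-level cohort
#'
#' Per-variant simple linear regression of the phenotype on dosage: the
#' standard marginal GWAS scan, used as the individual-level oracle for the
#' summary-statistics methods.
#'
#' @param G dosage matrix (individuals x variants, column names = ids).
#' @param y phenotype vector.
#' @param pos_bp,chrom per-variant annotations.
#' @param trait_name trait label.
#' @return A [sumstats] table with `study_n = nrow(G)`.
#' @export
cohort_sumstats <- function(G, y, pos_bp = seq_len(ncol(G)), chrom = "1",
                            trait_name = "cohort_trait") {
  n <- nrow(G)
  gbar <- colMeans(G); ybar <- mean(y)
  sxx <- colSums(G^2) - n * gbar^2
  if (any(sxx == 0)) stop2("monomorphic variant(s) in the cohort: ",
                           paste(colnames(G)[sxx == 0], collapse = ", "))
  sxy <- drop(crossprod(G, y)) - n * gbar * ybar
  syy <- sum(y^2) - n * ybar^2
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  se <- sqrt(rss / (n - 2) / sxx)
  p <- 2 * stats::pt(-abs(beta / se), df = n - 2)
  p[p == 0] <- .Machine$double.xmin
  records <- data.frame(
    variant_id = colnames(G), chrom = rep_len(chrom, ncol(G)), pos_bp = pos_bp,
    effect_allele = "A", other_allele = "G", eaf = gbar / 2, beta = beta,
    se = se, pvalue = p, n = n, stringsAsFactors = FALSE)
  sumstats(records, trait_name = trait_name, study_n = n)
}

#' Write simulation outputs as TSV
#'
#' @param sim a [simulate_sumstats()] result.
#' @param sumstats_path,truth_path output paths (truth optional).
#' @return `sumstats_path`, invisibly.
#' @export
write_simulation <- function(sim, sumstats_path, truth_path = NULL) {
  write_sumstats(sim$sumstats, sumstats_path)
  if (!is.null(truth_path)) {
    tr <- sim$truth
    tr$maf <- fmt_num(tr$maf, 10); tr$beta_true <- fmt_num(tr$beta_true, 10)
    data.table::fwrite(tr, truth_path, sep = "\t", quote = FALSE)
  }
  invisible(sumstats_path)
}
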