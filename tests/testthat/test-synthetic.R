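test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(seed = 101, m_common = 200, m_rare = 40)
  a <- simulate_sumstats(cfg)
  b <- simulate_sumstats(cfg)
  expect_identical(as.data.frame(a$sumstats), as.data.frame(b$sumstats))
  expect_identical(a$truth, b$truth)
  c <- simulate_sumstats(sim_config(seed = 102, m_common = 200, m_rare = 40))
  expect_false(identical(a$sumstats$beta, c$sumstats$beta))
})

test_that("emitted beta, se, and p are mutually consistent", {
  sim <- simulate_sumstats(sim_config(seed = 7, m_common = 400, m_rare = 100))
  ss <- sim$sumstats
  p_expected <- 2 * pnorm(-abs(ss$beta / ss$se))
  p_expected[p_expected == 0] <- .Machine$double.xmin
  expect_equal(log(ss$pvalue), log(p_expected), tolerance = 1e-10)
  expect_equal(ss$se, 1 / sqrt(study_n(ss) * 2 * pmin(ss$eaf, 1 - ss$eaf) *
                                 (1 - pmin(ss$eaf, 1 - ss$eaf))), tolerance = 1e-12)
})

test_that("gamma = 1 equalizes expected variance explained across the spectrum", {
  cfg <- sim_config(seed = 5, m_common = 15000, m_rare = 5000,
                    causal_fraction = 1, gamma = 1, tau = 0.02,
                    ld_blocks = data.frame(size = 1, rho = 0))
  sim <- simulate_sumstats(cfg)
  tr <- sim$truth
  ve <- 2 * tr$maf * (1 - tr$maf) * tr$beta_true^2
  # E[ve] = tau^2 exactly; sample mean of tau^2 * chi2(1) draws,
  # relative sd sqrt(2/m) = 0.01 at m = 20000
  expect_equal(mean(ve), cfg$tau^2, tolerance = 0.05)
  # and it is frequency-independent: compare rare vs common halves
  rare <- tr$maf < 0.01
  expect_equal(mean(ve[rare]) / mean(ve[!rare]), 1, tolerance = 0.1)
})

test_that("a null architecture is calibrated at the nominal type-I rate", {
  cfg <- sim_config(seed = 13, m_common = 4000, m_rare = 1000, causal_fraction = 0)
  sim <- simulate_sumstats(cfg)
  frac <- mean(sim$sumstats$pvalue < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(sim$sumstats)))
})

test_that("discovery rates track analytic power across power bins", {
  cfg <- sim_config(seed = 23, m_common = 10000, m_rare = 2000, causal_fraction = 1)
  sim <- simulate_sumstats(cfg)
  spec <- power_spec(n = cfg$n_gwas, alpha = 5e-8)
  tr <- sim$truth
  pw <- analytic_power(tr$maf, abs(tr$beta_true), spec)
  sig <- sim$sumstats$pvalue[match(tr$variant_id, sim$sumstats$variant_id)] < 5e-8
  for (bin in list(c(0.2, 0.4), c(0.4, 0.6), c(0.6, 0.8), c(0.8, 0.95))) {
    in_bin <- pw >= bin[1] & pw < bin[2]
    if (sum(in_bin) < 50) next
    expected <- mean(pw[in_bin])
    observed <- mean(sig[in_bin])
    expect_lt(abs(observed - expected),
              3 * sqrt(expected * (1 - expected) / sum(in_bin)) + 0.01)
  }
})

test_that("rare variants are exome-tagged singleton-like records", {
  sim <- simulate_sumstats(sim_config(seed = 3, m_common = 100, m_rare = 50))
  ss <- sim$sumstats
  rare <- ss$source == "exome"
  expect_equal(sum(rare), 50)
  expect_true(all(pmin(ss$eaf, 1 - ss$eaf)[rare] < 0.01))
  expect_true(all(!is.na(ss$gene[rare])))
  expect_true(all(is.na(ss$gene[!rare])))
})

test_that("cohort genotypes honour margins and block correlation targets", {
  cfg <- sim_config(seed = 41, m_common = 12, m_rare = 0,
                    ld_blocks = data.frame(size = c(4, 4, 4), rho = c(0, 0.7, 0.4)),
                    n_individuals = 4000)
  cohort <- simulate_cohort(cfg)
  expect_equal(dim(cohort$G), c(4000L, 12L))
  expect_true(all(cohort$G %in% 0:2))
  # margins: empirical frequency close to the architecture frequency
  fhat <- colMeans(cohort$G) / 2
  expect_lt(max(abs(fhat - cohort$truth$maf)), 4 * sqrt(0.25 / (2 * 4000)) + 0.01)
  C <- cor(cohort$G)
  blocks <- split(seq_len(12), cohort$truth$block)
  rho_target <- c(0, 0.7, 0.4)
  for (k in seq_along(blocks)) {
    idx <- blocks[[k]]
    off <- C[idx, idx][upper.tri(diag(length(idx)))]
    expect_lt(max(abs(off - rho_target[k])), 0.08)
  }
  # across blocks: independent
  expect_lt(max(abs(C[blocks[[1]], blocks[[2]]])), 0.08)
})

test_that("marginal cohort statistics recover a lone causal effect", {
  cfg <- sim_config(seed = 57, m_common = 5, m_rare = 0, causal_fraction = 0.2,
                    tau = 0.3, ld_blocks = data.frame(size = 1, rho = 0),
                    n_individuals = 4000)
  cohort <- simulate_cohort(cfg)
  expect_equal(sum(cohort$truth$causal), 1)
  tab <- cohort_sumstats(cohort$G, cohort$y, pos_bp = cohort$pos_bp)
  i <- match(cohort$truth$variant_id[cohort$truth$causal], tab$variant_id)
  expect_lt(abs(tab$beta[i] - cohort$truth$beta_true[cohort$truth$causal]),
            3 * tab$se[i])
  # oracle: per-variant lm on the raw cohort
  j <- match(tab$variant_id[1], colnames(cohort$G))
  fit <- summary(lm(cohort$y ~ cohort$G[, j]))$coefficients
  expect_equal(tab$beta[1], fit[2, 1], tolerance = 1e-10)
  expect_equal(tab$se[1], fit[2, 2], tolerance = 1e-10)
})

test_that("significant simulated variants form a trumpet across frequency deciles", {
  sim <- simulate_sumstats(sim_config(seed = 71, m_common = 8000, m_rare = 2000))
  ss <- harmonize_table(sim$sumstats, "minor_allele_signed")
  sig <- as.data.frame(ss)[ss$pvalue < 5e-8, ]
  expect_gt(nrow(sig), 200)
  # ten equal-width bins on the log10 frequency axis (the axis the plot
  # uses); the strict comparison is made over bins dense enough for a stable
  # median
  br <- seq(log10(min(sig$eaf)), log10(0.5), length.out = 11)
  bin <- cut(log10(sig$eaf), br, labels = FALSE, include.lowest = TRUE)
  med <- tapply(abs(sig$beta), bin, median)
  dense <- tapply(sig$eaf, bin, length) >= 20
  expect_gte(sum(dense), 5)
  expect_true(all(diff(med[dense]) < 0))
})
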