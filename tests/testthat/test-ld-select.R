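test_that("ld_from_genotypes computes dosage correlations with guards", {
  set.seed(1)
  G <- matrix(rbinom(5000 * 4, 2, 0.5), ncol = 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  G <- cbind(G, v5 = G[, 1])                      # perfect LD with v1
  ld <- ld_from_genotypes(G, pos_bp = 1:5)
  expect_equal(ld$R["v1", "v5"], 1)
  R4 <- ld$R[1:4, 1:4]                            # the independent columns
  expect_lt(max(abs(R4[upper.tri(R4)])), 0.05)    # |r| ~ 1/sqrt(n)
  # single variant: 1x1 unit matrix
  ld1 <- ld_from_genotypes(G[, 1, drop = FALSE], pos_bp = 1)
  expect_equal(dim(ld1$R), c(1L, 1L))
  expect_equal(unname(ld1$R[1, 1]), 1)
  G[, 2] <- 1L
  expect_error(ld_from_genotypes(G, pos_bp = 1:5), "monomorphic.*v2")
})

test_that("ld_reference validates symmetry, diagonal, and bounds", {
  M <- diag(3); M[1, 2] <- 0.5
  expect_error(ld_reference(M, c("a", "b", "c"), 1:3), "symmetric")
  M[2, 1] <- 0.5
  expect_silent(ld_reference(M, c("a", "b", "c"), 1:3))
  M2 <- M; diag(M2) <- 2
  expect_error(ld_reference(M2, c("a", "b", "c"), 1:3), "diagonal")
  expect_error(ld_reference(M, c("a", "a", "c"), 1:3), "unique")
})

test_that("clumping with no LD keeps every significant variant as a lead", {
  tab <- random_table(40, seed = 5)
  ld <- identity_ld(tab)
  res <- clump(tab, ld, p_threshold = 1e-4, maf_min = 0)
  sig <- tab$variant_id[tab$pvalue < 1e-4]
  expect_setequal(res$lead_ids, sig)
  expect_true(all(lengths(res$membership) == 0))
})

test_that("a high-LD nearby pair collapses to the stronger lead", {
  df <- random_records(2)
  df$pos_bp <- c(100000L, 110000L)
  df$pvalue <- c(1e-9, 1e-10); df$eaf <- c(0.3, 0.3)
  tab <- sumstats(df, study_n = 1000)
  R <- matrix(c(1, sqrt(0.95), sqrt(0.95), 1), 2)
  ld <- ld_reference(R, tab$variant_id, tab$pos_bp)
  res <- clump(tab, ld)
  expect_equal(res$lead_ids, tab$variant_id[tab$pvalue == 1e-10])
  expect_equal(res$membership[[res$lead_ids]], tab$variant_id[tab$pvalue == 1e-9])
})

test_that("the six-variant fixture clumps exactly as the hand-executed greedy steps", {
  p <- toy6_paths()
  tab <- read_sumstats(p$sumstats, study_n = 100000)
  ld <- read_ld(p$ld)
  res <- clump(tab, ld)
  # greedy by P: s6 (absorbs s5: 10 kb, r2 = 0.36), s1 (absorbs s2, s3), s4
  expect_equal(res$lead_ids, c("s6", "s1", "s4"))
  expect_setequal(res$membership[["s1"]], c("s2", "s3"))
  expect_equal(res$membership[["s6"]], "s5")
  expect_equal(res$membership[["s4"]], character(0))
  expect_equal(res$leads$n_absorbed, c(1L, 2L, 0L))
  # partition postcondition, checked exhaustively
  assigned <- c(res$lead_ids, unlist(res$membership))
  expect_setequal(assigned, tab$variant_id)
  expect_equal(anyDuplicated(assigned), 0L)
  for (a in res$lead_ids) for (b in setdiff(res$lead_ids, a)) {
    ia <- match(a, tab$variant_id); ib <- match(b, tab$variant_id)
    joint <- abs(tab$pos_bp[ia] - tab$pos_bp[ib]) <= 100000 &&
      as.matrix(ld$R)[a, b]^2 >= 0.1
    expect_false(joint)
  }
})

test_that("clumping is invariant to input row order and monotone in r2", {
  p <- toy6_paths()
  tab <- read_sumstats(p$sumstats, study_n = 100000)
  ld <- read_ld(p$ld)
  base <- clump(tab, ld)
  set.seed(9)
  shuffled <- sumstats(as.data.frame(tab)[sample(nrow(tab)), ], study_n = 100000)
  expect_equal(clump(shuffled, ld)$lead_ids, base$lead_ids)
  # relaxing r2 (lower threshold -> more absorption) cannot increase lead count
  n_leads <- vapply(c(0.01, 0.1, 0.5, 0.99),
                    function(r2) length(clump(tab, ld, r2_threshold = r2)$lead_ids),
                    numeric(1))
  expect_true(all(diff(n_leads) >= 0))
})

test_that("candidates missing from the LD panel are reported by id", {
  tab <- random_table(5, seed = 2)
  ld <- identity_ld(tab[1:3, ])
  expect_error(clump(tab, ld, p_threshold = 0.999, maf_min = 0), "r0000[45]")
})

test_that("stepwise with identity LD reduces to marginal thresholding", {
  tab <- random_table(30, seed = 8)
  ld <- identity_ld(tab)
  res <- stepwise_select(tab, ld, p_threshold = 1e-4)
  sig <- tab$variant_id[tab$pvalue < 1e-4]
  expect_setequal(res$lead_ids, sig)
  idx <- match(res$leads$variant_id, tab$variant_id)
  expect_equal(res$leads$joint_beta, tab$beta[idx], tolerance = 1e-10)
  expect_equal(res$leads$joint_se, tab$se[idx], tolerance = 1e-10)
})

test_that("perfectly correlated significant variants yield a single lead", {
  df <- random_records(2)
  df$pos_bp <- c(1000L, 2000L)
  df$beta <- c(0.4, 0.39); df$se <- c(0.02, 0.02)
  df$pvalue <- 2 * pnorm(-abs(df$beta / df$se))
  tab <- sumstats(df, study_n = 2000)
  R <- matrix(c(1, 1, 1, 1), 2)
  ld <- ld_reference(R, tab$variant_id, tab$pos_bp)
  res <- stepwise_select(tab, ld, p_threshold = 1e-6)
  expect_length(res$lead_ids, 1)
})

test_that("stepwise joint effects agree with individual-level multivariate regression", {
  cfg <- sim_config(seed = 31, m_common = 8, m_rare = 0, causal_fraction = 0.25,
                    tau = 0.3, gamma = 0.5,
                    ld_blocks = data.frame(size = 8, rho = 0.5),
                    n_individuals = 2000)
  cohort <- simulate_cohort(cfg)
  tab <- cohort_sumstats(cohort$G, cohort$y, pos_bp = cohort$pos_bp,
                         chrom = cohort$chrom)
  ld <- ld_from_genotypes(cohort$G, pos_bp = cohort$pos_bp, chrom = cohort$chrom)
  res <- stepwise_select(tab, ld, p_threshold = 1e-5)
  expect_gt(length(res$lead_ids), 0)
  fit <- lm(cohort$y ~ cohort$G[, res$lead_ids, drop = FALSE])
  co <- summary(fit)$coefficients[-1, , drop = FALSE]
  for (i in seq_along(res$lead_ids)) {
    expect_lt(abs(res$leads$joint_beta[i] - co[i, 1]), 3 * co[i, 2])
  }
})
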