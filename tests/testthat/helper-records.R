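# in-code fixtures shared across test files

# m random valid association records spanning the frequency spectrum
random_records <- function(m, seed = 1) {
  set.seed(seed)
  f <- 10^runif(m, -4, -0.001)
  f <- ifelse(runif(m) < 0.5, f, 1 - f)          # both orientations
  beta <- rnorm(m, 0, 0.2)
  se <- runif(m, 0.005, 0.05)
  p <- 2 * pnorm(-abs(beta / se))
  p[p == 0] <- .Machine$double.xmin
  pair <- matrix(c("A", "G", "C", "T"), 2)[, sample(1:2, m, replace = TRUE)]
  data.frame(variant_id = sprintf("r%05d", seq_len(m)), chrom = "1",
             pos_bp = seq_len(m) * 1000L, effect_allele = pair[1, ],
             other_allele = pair[2, ], eaf = f, beta = beta, se = se,
             pvalue = p, stringsAsFactors = FALSE)
}

random_table <- function(m, seed = 1, study_n = 10000) {
  suppressMessages(sumstats(random_records(m, seed), study_n = study_n))
}

toy6_paths <- function() {
  list(sumstats = system.file("extdata", "toy6_sumstats.tsv", package = "trumpetr"),
       ld = system.file("extdata", "toy6_ld.tsv", package = "trumpetr"))
}

# identity-LD reference covering a table
identity_ld <- function(table) {
  m <- nrow(table)
  ld_reference(diag(m), table$variant_id, pos_bp = table$pos_bp, chrom = table$chrom)
}

# subset a sumstats table by a logical mask, revalidating into a fresh object
set_records_for_test <- function(tab, keep) {
  suppressMessages(sumstats(as.data.frame(tab)[keep, , drop = FALSE],
                            study_n = study_n(tab)))
}
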