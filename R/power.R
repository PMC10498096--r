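#' Power-curve specification
#'
#' Parameters of the analytic single-variant power model. The association test
#' is the standard 1-degree-of-freedom additive-model Wald/score chi-square;
#' under the alternative the statistic is non-central chi-square with
#' non-centrality
#' \deqn{\lambda = n \, 2f(1-f)\, \beta^2}{lambda = n * 2f(1-f) * beta^2}
#' for a quantitative trait with phenotype variance standardized to 1, and
#' \deqn{\lambda = 2f(1-f)\, \beta^2 \, n_\mathrm{cases} n_\mathrm{controls} / n}{
#' lambda = 2f(1-f) * beta^2 * n_cases*n_controls/n}
#' for a binary trait with `beta` on the log-odds scale (the usual log-OR
#' variance approximation `var(beta_hat) = n / (2f(1-f) n_cases n_controls)`).
#'
#' @param n total sample size.
#' @param alpha significance threshold, default genome-wide `5e-8`.
#' @param trait_model `"quantitative"` or `"binary"`.
#' @param n_cases,n_controls case/control counts (binary model only).
#' @param power_levels target power levels for curves, default
#'   `c(0.5, 0.7, 0.9)`.
#' @param f_min,f_max frequency-axis limits; the grid is log10-spaced so
#'   curves render smoothly at rare frequencies. Defaults `1e-5` and `0.5`
#'   (use `f_max = 1 - f_min` for the positive-effect orientation).
#' @param grid_points number of grid points, default 200.
#' @return A `power_spec` list.
#' @examples
#' spec <- power_spec(n = 351550)
#' analytic_power(0.01, 0.05, spec)
#' @export
power_spec <- function(n, alpha = 5e-8,
                       trait_model = c("quantitative", "binary"),
                       n_cases = NULL, n_controls = NULL,
                       power_levels = c(0.5, 0.7, 0.9),
                       f_min = 1e-5, f_max = 0.5, grid_points = 200L) {
  trait_model <- match.arg(trait_model)
  if (!is_scalar_number(n) || n < 1) stop2("`n` must be a positive number")
  check_prob(alpha, "alpha")
  check_prob(power_levels, "power_levels")
  check_prob(f_min, "f_min"); check_prob(f_max, "f_max")
  if (f_min >= f_max) stop2("`f_min` must be < `f_max`")
  if (trait_model == "binary") {
    if (is.null(n_cases) || is.null(n_controls)) {
      stop2("binary model requires `n_cases` and `n_controls`")
    }
    if (abs(n_cases + n_controls - n) > 0.5) stop2("`n_cases` + `n_controls` must equal `n`")
  }
  structure(list(n = n, alpha = alpha, trait_model = trait_model,
                 n_cases = n_cases, n_controls = n_controls,
                 power_levels = sort(power_levels),
                 f_min = f_min, f_max = f_max,
                 grid_points = as.integer(grid_points)),
            class = "power_spec")
}

# effective sample size multiplying 2f(1-f)beta^2 in the non-centrality
effective_n <- function(spec) {
  if (spec$trait_model == "binary") spec$n_cases * spec$n_controls / spec$n else spec$n
}

#' Non-centrality parameter of the association chi-square
#'
#' @param freq allele frequency, strictly inside (0, 1); vectorized.
#' @param beta per-allele effect (beta scale); vectorized.
#' @param spec a [power_spec].
#' @return `n_eff * 2 freq (1 - freq) * beta^2`, non-negative.
#' @export
noncentrality <- function(freq, beta, spec) {
  check_prob(freq, "freq")
  effective_n(spec) * 2 * freq * (1 - freq) * beta^2
}

#' Analytic power of the single-variant test
#'
#' Probability that a non-central chi-square(1, lambda) variate exceeds the
#' central chi-square(1) critical value at `spec$alpha`. At `beta = 0` this is
#' exactly `alpha`.
#'
#' @inheritParams noncentrality
#' @return Power in (0, 1); vectorized over `freq` and `beta`.
#' @export
analytic_power <- function(freq, beta, spec) {
  lambda <- noncentrality(freq, beta, spec)
  q <- qchisq(spec$alpha, df = 1, lower.tail = FALSE)
  pchisq(q, df = 1, ncp = lambda, lower.tail = FALSE)
}

# lambda* such that P(chisq(1, lambda) > q_alpha) = level; monotone root-find,
# bracket expanded geometrically, bisection via uniroot. Cached per call site.
lambda_for_power <- function(alpha, level, tol = 1e-10) {
  check_prob(alpha, "alpha")
  if (level <= alpha) {
    stop2("target power must exceed alpha (power below the null rejection rate is not meaningful)")
  }
  check_prob(level, "level")
  q <- qchisq(alpha, df = 1, lower.tail = FALSE)
  f <- function(l) pchisq(q, df = 1, ncp = l, lower.tail = FALSE) - level
  hi <- 10 * q
  while (f(hi) < 0) hi <- hi * 2   # expand until the target power is bracketed
  uniroot(f, c(0, hi), tol = tol * q, f.lower = alpha - level)$root
}

#' Minimum detectable effect at a target power
#'
#' Inverts [analytic_power()] in `beta`: solves once per (alpha, level) for the
#' non-centrality `lambda*` at which power equals `level` (monotone root-find
#' to a power tolerance of 1e-10), then
#' `beta = sqrt(lambda* / (n_eff * 2 freq (1 - freq)))`.
#'
#' @param freq allele frequency (vectorized).
#' @param level target power, must satisfy `alpha < level < 1`.
#' @param spec a [power_spec].
#' @return Non-negative minimum detectable `beta`; symmetric in
#'   `freq <-> 1 - freq`.
#' @export
beta_for_power <- function(freq, level, spec) {
  check_prob(freq, "freq")
  lambda <- lambda_for_power(spec$alpha, level)
  sqrt(lambda / (effective_n(spec) * 2 * freq * (1 - freq)))
}

#' Build power curves over the frequency grid
#'
#' One curve per power level in `spec$power_levels`, evaluated on a
#' log10-spaced frequency grid from `f_min` to `f_max`. Higher levels give
#' uniformly larger minimum detectable effects, so curves never cross.
#'
#' @param spec a [power_spec].
#' @return A data frame with columns `level`, `freq`, `beta_min`, class
#'   `power_curves`.
#' @examples
#' curves <- build_power_curves(power_spec(n = 351550))
#' head(curves)
#' @export
build_power_curves <- function(spec) {
  grid <- 10^seq(log10(spec$f_min), log10(spec$f_max), length.out = spec$grid_points)
  out <- do.call(rbind, lapply(spec$power_levels, function(lv) {
    data.frame(level = lv, freq = grid, beta_min = beta_for_power(grid, lv, spec))
  }))
  rownames(out) <- NULL
  structure(out, spec = spec, class = c("power_curves", "data.frame"))
}

#' Monte-Carlo power estimate (simulation oracle)
#'
#' Simulates `replicates` independent studies of size `spec$n`: genotypes
#' `g ~ Binomial(2, freq)`; quantitative phenotype
#' `y = beta * g + Normal(0, 1 - 2 freq (1 - freq) beta^2)` so the total
#' phenotypic variance is 1 (matching the analytic convention); binary
#' phenotype from a logistic model with intercept set by the case fraction.
#' Each replicate is tested with the 1-df Wald (quantitative) or score
#' (binary) test; the rejection fraction at `spec$alpha` is returned.
#'
#' `spec$alpha` may be a vector of thresholds, in which case the same
#' simulated studies are evaluated at every threshold and a vector of
#' rejection fractions is returned.
#'
#' @inheritParams noncentrality
#' @param replicates number of simulated studies, at least 100.
#' @param seed optional integer seed for reproducibility.
#' @return Empirical power (rejection fraction), one per `spec$alpha`.
#' @export
empirical_power <- function(freq, beta, spec, replicates = 1000L, seed = NULL) {
  check_prob(freq, "freq")
  if (replicates < 100) stop2("`replicates` must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  q <- qchisq(spec$alpha, df = 1, lower.tail = FALSE)
  h2 <- 2 * freq * (1 - freq) * beta^2
  if (spec$trait_model == "quantitative" && h2 >= 1) {
    stop2("2f(1-f)beta^2 >= 1: effect would explain the full phenotypic variance")
  }
  rejections <- numeric(length(q))
  done <- 0L
  chunk <- max(1L, min(replicates, as.integer(ceiling(2e6 / n))))
  while (done < replicates) {
    B <- min(chunk, replicates - done)
    G <- matrix(rbinom(n * B, 2L, freq), nrow = n)
    if (spec$trait_model == "quantitative") {
      Y <- beta * G + matrix(rnorm(n * B, sd = sqrt(1 - h2)), nrow = n)
      gbar <- colMeans(G); ybar <- colMeans(Y)
      sxx <- colSums(G * G) - n * gbar^2
      sxy <- colSums(G * Y) - n * gbar * ybar
      syy <- colSums(Y * Y) - n * ybar^2
      bhat <- sxy / sxx
      rss <- syy - bhat * sxy
      se2 <- rss / (n - 2) / sxx
      stat <- bhat^2 / se2                      # Wald chi-square, 1 df
    } else {
      frac_cases <- spec$n_cases / n
      eta <- log(frac_cases / (1 - frac_cases)) +
        beta * (G - 2 * freq)                    # centred so case fraction ~ target
      Yb <- matrix(rbinom(n * B, 1L, 1 / (1 + exp(-eta))), nrow = n)
      ybar <- colMeans(Yb); gbar <- colMeans(G)
      U <- colSums(G * Yb) - n * gbar * ybar     # score numerator
      V <- ybar * (1 - ybar) * (colSums(G * G) - n * gbar^2)
      stat <- U^2 / V                            # score chi-square, 1 df
    }
    stat[!is.finite(stat)] <- 0                  # degenerate replicate: no rejection
    rejections <- rejections + vapply(q, function(qi) sum(stat > qi), numeric(1))
    done <- done + B
  }
  rejections / replicates
}
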