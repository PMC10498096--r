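#' Trumpet-plot specification
#'
#' Encoding choices for the trumpet plot: the x-axis is allele frequency on a
#' log10 scale (compressing the common end of the spectrum so rare variants
#' stay visible), the y-axis is effect size, point area is proportional to
#' `|beta|`, and point colour encodes `-log10(p)`.
#'
#' @param orientation `"minor_allele_signed"` (frequencies in (0, 0.5],
#'   signed effects, mirrored power curves) or `"positive_effect"`
#'   (frequencies in (0, 1), effects >= 0).
#' @param f_min lower frequency-axis limit, default `1e-5`; points below it
#'   are clipped to the axis edge with a warning rather than dropped (rare
#'   singletons are the plot's point of interest).
#' @param f_max upper limit; defaults to 0.5 (signed mode) or `1 - f_min`
#'   (positive mode).
#' @param size_range minimum and maximum point sizes (plot-unit radii); the
#'   **area** interpolates linearly in `|beta|` over the retained range.
#' @param color_cap cap on `-log10(p)` for the colour scale, default 50, so
#'   genome-wide p-values spanning hundreds of orders of magnitude do not
#'   flatten the scale.
#' @param min_effect_display records with `|beta|` strictly below this are
#'   dropped (so exactly `min_effect_display` is kept); default 0.
#' @param power a [power_spec] for overlay curves, or `NULL` for none.
#' @param hover_fields fields shown on hover in the interactive rendering;
#'   subset of `variant_id`, `beta`, `gene`, `pvalue`, `trait`.
#' @return A `trumpet_spec` list.
#' @export
trumpet_spec <- function(orientation = c("minor_allele_signed", "positive_effect"),
                         f_min = 1e-5, f_max = NULL,
                         size_range = c(0.5, 3), color_cap = 50,
                         min_effect_display = 0, power = NULL,
                         hover_fields = c("variant_id", "beta", "gene", "pvalue", "trait")) {
  orientation <- match.arg(orientation)
  check_prob(f_min, "f_min")
  if (is.null(f_max)) f_max <- if (orientation == "minor_allele_signed") 0.5 else 1 - f_min
  check_prob(f_max, "f_max")
  if (f_min >= f_max) stop2("`f_min` must be < `f_max`")
  if (any(size_range <= 0) || size_range[1] > size_range[2]) {
    stop2("`size_range` must be positive and non-decreasing")
  }
  if (min_effect_display < 0) stop2("`min_effect_display` must be >= 0")
  bad <- setdiff(hover_fields, c("variant_id", "beta", "gene", "pvalue", "trait"))
  if (length(bad)) stop2("unsupported hover field(s): ", paste(bad, collapse = ", "))
  structure(list(orientation = orientation, f_min = f_min, f_max = f_max,
                 size_range = size_range, color_cap = color_cap,
                 min_effect_display = min_effect_display, power = power,
                 hover_fields = hover_fields),
            class = "trumpet_spec")
}

#' Resolve a sumstats table into render-ready plot geometry
#'
#' Applies the encodings of a [trumpet_spec] to a harmonized table: maps
#' `eaf` to x and `beta` to y, computes point sizes (linear-area scaling of
#' `|beta|`) and colour values (`-log10(p)`, capped), applies the
#' `min_effect_display` filter (inclusive: `|beta| >= threshold` is kept),
#' clips sub-axis frequencies to `f_min`, and evaluates the power curves,
#' mirrored to negative effects in signed mode. The input table must already
#' be harmonized to `spec$orientation`; inconsistent records are a fatal
#' error reporting the offending count. Filtering is the only source of
#' point-count change: retained + dropped equals the input record count.
#'
#' @param table a harmonized [sumstats] table.
#' @param spec a [trumpet_spec].
#' @return A `trumpet_data` list: `points` (x, y, size, colour value, hover
#'   payload per variant), `curves` (level, freq, beta_min, mirrored flag),
#'   `axis_ticks` (powers of ten), and retention counts.
#' @export
build_plot_data <- function(table, spec = trumpet_spec()) {
  stopifnot(inherits(spec, "trumpet_spec"))
  df <- as.data.frame(table)
  if (!nrow(df)) stop2("empty table")
  if (spec$orientation == "minor_allele_signed") {
    bad <- sum(df$eaf > 0.5)
    if (bad) stop2(bad, " record(s) with eaf > 0.5: table is not harmonized to minor_allele_signed")
  } else {
    bad <- sum(df$beta < 0)
    if (bad) stop2(bad, " record(s) with beta < 0: table is not harmonized to positive_effect")
  }
  n_input <- nrow(df)
  keep <- abs(df$beta) >= spec$min_effect_display
  df <- df[keep, , drop = FALSE]
  n_dropped <- n_input - nrow(df)

  clip_lo <- df$eaf < spec$f_min
  clip_hi <- df$eaf > spec$f_max
  n_clipped <- sum(clip_lo) + sum(clip_hi)
  if (n_clipped) {
    warning(n_clipped, " point(s) outside the frequency axis clipped to its edge",
            call. = FALSE)
  }
  x <- pmin(pmax(df$eaf, spec$f_min), spec$f_max)

  ab <- abs(df$beta)
  rng <- range(ab)
  amin <- spec$size_range[1]^2; amax <- spec$size_range[2]^2
  if (nrow(df) == 0 || diff(rng) == 0) {
    size <- rep(mean(spec$size_range), nrow(df))  # degenerate range: midpoint size
  } else {
    size <- sqrt(amin + (ab - rng[1]) / diff(rng) * (amax - amin))
  }
  color_value <- pmin(-log10(df$pvalue), spec$color_cap)

  points <- data.frame(variant_id = df$variant_id, freq = x, beta = df$beta,
                       size = size, color_value = color_value,
                       stringsAsFactors = FALSE)
  for (h in setdiff(spec$hover_fields, c("variant_id", "beta"))) points[[h]] <- df[[h]]

  curves <- NULL
  if (!is.null(spec$power)) {
    pspec <- spec$power
    pspec$f_min <- spec$f_min; pspec$f_max <- spec$f_max
    curves <- as.data.frame(build_power_curves(pspec))
  }
  structure(list(points = points, curves = curves,
                 mirrored = spec$orientation == "minor_allele_signed",
                 axis_ticks = 10^seq(ceiling(log10(spec$f_min)), 0),
                 n_input = n_input, n_dropped = n_dropped, n_clipped = n_clipped,
                 spec = spec),
            class = "trumpet_data")
}

#' @export
print.trumpet_data <- function(x, ...) {
  cat(sprintf("<trumpet_data> %d point(s) (%d dropped by the effect-size filter, %d clipped), %s curve level(s)\n",
              nrow(x$points), x$n_dropped, x$n_clipped,
              if (is.null(x$curves)) "no" else length(unique(x$curves$level))))
  invisible(x)
}
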