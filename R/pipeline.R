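#' Pipeline run configuration
#'
#' Assembles and validates the configuration of an end-to-end run:
#' read (or simulate) summary statistics, harmonize, select independent
#' significant variants, build power curves, and render the trumpet plot.
#' Defaults mirror common GWAS practice: genome-wide `alpha = 5e-8`,
#' `maf_min = 0.01` for the selection step, a 100-kb clumping window, and
#' power levels 0.5 / 0.7 / 0.9.
#'
#' @param sumstats path to a summary-statistics table, or `NULL` to simulate.
#' @param ld path to an LD matrix/genotype TSV, or `NULL` (mandatory for
#'   `method = "clump"` or `"stepwise"` on read-in data).
#' @param ld_kind `"matrix"` or `"genotypes"` (see [read_ld()]).
#' @param out_dir output directory, created if needed.
#' @param n study sample size (required when reading sumstats).
#' @param trait_model `"quantitative"` or `"binary"`.
#' @param trait_name trait label.
#' @param orientation plotting orientation (see [harmonize_table()]).
#' @param method `"clump"`, `"stepwise"` or `"none"` (plot all significant
#'   variants without LD reduction).
#' @param alpha significance threshold.
#' @param r2_threshold,window_kb,maf_min clumping parameters.
#' @param power_levels power-curve levels.
#' @param f_min frequency-axis lower limit.
#' @param min_effect static-plot effect-size display filter.
#' @param min_effect_interactive interactive display filter.
#' @param simulate a [sim_config] (used when `sumstats` is `NULL`).
#' @param seed seed forwarded to the simulator.
#' @param dialect column dialect for [read_sumstats()].
#' @return A `run_config` list.
#' @export
run_config <- function(sumstats = NULL, ld = NULL, ld_kind = "matrix",
                       out_dir = ".", n = NULL,
                       trait_model = "quantitative", trait_name = "trait",
                       orientation = "minor_allele_signed",
                       method = c("clump", "stepwise", "none"),
                       alpha = 5e-8, r2_threshold = 0.1, window_kb = 100,
                       maf_min = 0.01, power_levels = c(0.5, 0.7, 0.9),
                       f_min = 1e-5, min_effect = 0, min_effect_interactive = 0.05,
                       simulate = NULL, seed = 1L, dialect = "auto") {
  method <- match.arg(method)
  if (is.null(sumstats)) {
    if (is.null(simulate)) simulate <- sim_config(seed = seed)
    simulate$seed <- as.integer(seed)
    if (is.null(n)) n <- simulate$n_gwas
  } else if (is.null(n)) {
    stop2("`n` (study sample size) is required when reading summary statistics")
  }
  structure(list(sumstats = sumstats, ld = ld, ld_kind = ld_kind,
                 out_dir = out_dir, n = n, trait_model = trait_model,
                 trait_name = trait_name, orientation = orientation,
                 method = method, alpha = alpha, r2_threshold = r2_threshold,
                 window_kb = window_kb, maf_min = maf_min,
                 power_levels = power_levels, f_min = f_min,
                 min_effect = min_effect,
                 min_effect_interactive = min_effect_interactive,
                 simulate = simulate, seed = as.integer(seed), dialect = dialect),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys are [run_config()] arguments; a `simulate:` block holds
#' [sim_config()] arguments; a `dialect:` block maps canonical column names
#' to file column names.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) {
    raw$simulate <- do.call(sim_config, raw$simulate)
  }
  if (!is.null(raw$dialect)) raw$dialect <- unlist(raw$dialect)
  if (!is.null(raw$ld_blocks)) stop2("`ld_blocks` belongs under the `simulate:` block")
  do.call(run_config, raw)
}

#' Run the end-to-end trumpet-plot pipeline
#'
#' Executes read (or simulate) -> harmonize -> select -> power curves ->
#' plot, writing all artifacts into `config$out_dir`:
#' `selected.tsv` (independent significant variants), `curves.tsv`
#' (level, freq, beta_min), `trumpet.svg` and `trumpet.html`, and
#' `report.json` (input/retained/significant/selected counts, thresholds,
#' seed, package version). All artifacts are deterministic given the config
#' and seed. Any stage failure removes partial artifacts and rethrows with
#' the stage name.
#'
#' @param config a [run_config].
#' @return The report, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- file.path(config$out_dir,
                   c(selected = "selected.tsv", curves = "curves.tsv",
                     svg = "trumpet.svg", html = "trumpet.html",
                     report = "report.json", sumstats = "sumstats.tsv"))
  names(art) <- c("selected", "curves", "svg", "html", "report", "sumstats")
  stage <- "init"
  on_fail <- function(e) {
    unlink(art[file.exists(art)])
    stop2(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)))
  }
  tryCatch({
    stage <- "read"
    ld <- NULL
    if (is.null(config$sumstats)) {
      sim <- simulate_sumstats(config$simulate)
      table <- sim$sumstats
      ld <- sim$ld
      write_sumstats(table, art[["sumstats"]])
    } else {
      table <- read_sumstats(config$sumstats, dialect = config$dialect,
                             trait_name = config$trait_name, study_n = config$n,
                             trait_model = config$trait_model)
    }
    n_input <- nrow(table) + nrow(attr(table, "rejected"))

    stage <- "ld"
    if (config$method != "none" && is.null(ld)) {
      if (is.null(config$ld)) stop2("an ld reference is required for method '", config$method, "'")
      ld <- read_ld(config$ld, kind = config$ld_kind)
    }

    stage <- "harmonize"
    table <- harmonize_table(table, config$orientation)

    stage <- "select"
    n_sig <- sum(table$pvalue < config$alpha)
    window_bp <- as.integer(config$window_kb * 1000)
    sel <- switch(config$method,
      clump = clump(table, ld, p_threshold = config$alpha,
                    r2_threshold = config$r2_threshold,
                    window_bp = window_bp, maf_min = config$maf_min),
      stepwise = stepwise_select(table, ld, p_threshold = config$alpha,
                                 window_bp = window_bp),
      none = NULL)
    if (is.null(sel)) {
      plot_table <- set_records(table, as.data.frame(table)[table$pvalue < config$alpha, , drop = FALSE])
      n_selected <- nrow(plot_table)
    } else {
      write_selection(sel, art[["selected"]])
      keep <- table$variant_id %in% sel$lead_ids
      plot_table <- set_records(table, as.data.frame(table)[keep, , drop = FALSE])
      n_selected <- length(sel$lead_ids)
    }
    if (!nrow(plot_table)) stop2("no significant variants to plot at alpha = ", config$alpha)

    stage <- "power"
    pspec <- power_spec(n = config$n, alpha = config$alpha,
                        trait_model = "quantitative",
                        power_levels = config$power_levels, f_min = config$f_min)
    curves <- build_power_curves(pspec)
    cv <- as.data.frame(curves)
    cv$freq <- fmt_num(cv$freq, 10); cv$beta_min <- fmt_num(cv$beta_min, 10)
    data.table::fwrite(cv, art[["curves"]], sep = "\t", quote = FALSE)

    stage <- "plot"
    tspec <- trumpet_spec(orientation = config$orientation, f_min = config$f_min,
                          min_effect_display = config$min_effect, power = pspec)
    pdata <- build_plot_data(plot_table, tspec)
    render_static(pdata, art[["svg"]], format = "svg")
    render_interactive(pdata, art[["html"]],
                       min_effect = config$min_effect_interactive)

    stage <- "report"
    report <- list(
      n_input = n_input, n_rejected = nrow(attr(table, "rejected")),
      n_retained = nrow(table), n_significant = n_sig,
      n_selected = n_selected, n_plotted = nrow(pdata$points),
      n_dropped_by_display_filter = pdata$n_dropped,
      method = config$method, alpha = config$alpha,
      r2_threshold = config$r2_threshold, window_kb = config$window_kb,
      maf_min = config$maf_min, orientation = config$orientation,
      power_levels = config$power_levels, n = config$n, seed = config$seed,
      package_version = as.character(utils::packageVersion("trumpetr")))
    jsonlite::write_json(report, art[["report"]], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(report)
  }, error = on_fail)
}
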