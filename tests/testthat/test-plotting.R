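make_plot_table <- function(betas, eaf = NULL, seed = 1) {
  df <- random_records(length(betas), seed = seed)
  df$beta <- betas
  df$eaf <- eaf %||% rep(0.2, length(betas))
  df$pvalue <- 2 * pnorm(-abs(df$beta / df$se))
  df$pvalue[df$pvalue == 0] <- .Machine$double.xmin
  suppressMessages(sumstats(df, study_n = 10000))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("the display filter keeps |beta| at the threshold and counts the rest", {
  tab <- make_plot_table(c(0.01, 0.05, 0.1, -0.2))
  spec <- trumpet_spec(min_effect_display = 0.05)
  pd <- build_plot_data(tab, spec)
  expect_equal(nrow(pd$points), 3)          # 0.05 itself is kept (inclusive)
  expect_equal(pd$n_dropped, 1)
  expect_equal(pd$n_input, 4)
  pd0 <- build_plot_data(tab, trumpet_spec(min_effect_display = 0))
  expect_equal(nrow(pd0$points), nrow(tab))
  expect_equal(pd0$n_dropped, 0)
})

test_that("point geometry encodes frequency order, effect, and p-value", {
  tab <- harmonize_table(random_table(80, seed = 21), "minor_allele_signed")
  pd <- build_plot_data(tab, trumpet_spec())
  expect_equal(order(pd$points$freq), order(tab$eaf))   # monotone axis transform
  expect_equal(pd$points$beta, tab$beta)
  expect_equal(pd$points$color_value, pmin(-log10(tab$pvalue), 50))
  expect_equal(nrow(pd$points) + pd$n_dropped, pd$n_input)
})

test_that("equal effect magnitudes all get the midpoint size", {
  tab <- make_plot_table(c(0.1, -0.1, 0.1, 0.1))
  pd <- build_plot_data(tab, trumpet_spec(size_range = c(1, 3)))
  expect_equal(unique(pd$points$size), 2)
})

test_that("orientation mismatches are fatal with a count", {
  tab <- make_plot_table(c(0.1, 0.2, -0.1), eaf = c(0.7, 0.8, 0.2))
  expect_error(build_plot_data(tab, trumpet_spec("minor_allele_signed")),
               "2 record")
  expect_error(build_plot_data(tab, trumpet_spec("positive_effect")),
               "1 record")
})

test_that("sub-axis frequencies are clipped to the edge with a warning, not dropped", {
  tab <- make_plot_table(c(0.5, 0.4), eaf = c(3e-6, 0.1))
  expect_warning(pd <- build_plot_data(tab, trumpet_spec(f_min = 1e-5)), "clipped")
  expect_equal(nrow(pd$points), 2)
  expect_equal(min(pd$points$freq), 1e-5)
})

test_that("double harmonization leaves the plot data unchanged", {
  tab <- harmonize_table(random_table(60, seed = 33), "minor_allele_signed")
  spec <- trumpet_spec()
  once <- build_plot_data(tab, spec)
  twice <- build_plot_data(harmonize_table(tab, "minor_allele_signed"), spec)
  expect_equal(once$points, twice$points)
})

test_that("static rendering writes the requested formats and mirrors signed effects", {
  tab <- harmonize_table(random_table(300, seed = 13), "minor_allele_signed")
  pspec <- power_spec(n = 10000, alpha = 1e-4, power_levels = c(0.5, 0.9))
  pd <- build_plot_data(tab, trumpet_spec(power = pspec))
  svg <- withr::local_tempfile(fileext = ".svg")
  render_static(pd, svg)
  expect_true(file.exists(svg) && file.size(svg) > 1000)
  expect_match(readLines(svg, n = 2, warn = FALSE)[2], "svg")
  # signed mode: built panel spans negative and positive effects
  gb <- ggplot2::ggplot_build(ggplot2::autoplot(pd))
  yr <- gb$layout$panel_params[[1]]$y.range
  expect_lt(yr[1], 0); expect_gt(yr[2], 0)
  # curve geometry: the 0.9 locus lies strictly outside the 0.5 locus
  cv <- pd$curves
  expect_true(all(cv$beta_min[cv$level == 0.9] > cv$beta_min[cv$level == 0.5]))
  empty <- pd; empty$points <- pd$points[0, ]
  expect_error(render_static(empty, svg), "no points")
})

extract_embedded_points <- function(html_path) {
  line <- grep("^var D=", readLines(html_path, warn = FALSE), value = TRUE)
  jsonlite::fromJSON(sub(";$", "", sub("^var D=", "", line)), simplifyDataFrame = FALSE)
}

test_that("interactive HTML embeds exactly the requested hover payload", {
  tab <- harmonize_table(random_table(50, seed = 17), "minor_allele_signed")
  spec <- trumpet_spec(hover_fields = c("variant_id", "beta", "pvalue"))
  pd <- build_plot_data(tab, spec)
  html <- withr::local_tempfile(fileext = ".html")
  render_interactive(pd, html, min_effect = 0)
  D <- extract_embedded_points(html)
  expect_equal(length(D$cx), nrow(tab))
  expect_true(all(vapply(D$hover, function(h)
    identical(names(h), c("variant_id", "beta", "pvalue")), logical(1))))
})

test_that("the interactive default filter shows no more points than the static default", {
  tab <- harmonize_table(random_table(200, seed = 19), "minor_allele_signed")
  pd <- build_plot_data(tab, trumpet_spec())         # static default: no filter
  html <- withr::local_tempfile(fileext = ".html")
  render_interactive(pd, html)                       # interactive default: 0.05
  D <- extract_embedded_points(html)
  expect_lte(length(D$cx), nrow(pd$points))
  expect_equal(length(D$cx), sum(abs(pd$points$beta) >= 0.05))
})

test_that("re-rendering identical plot data is byte-identical", {
  tab <- harmonize_table(random_table(40, seed = 23), "minor_allele_signed")
  pd <- build_plot_data(tab, trumpet_spec(power = power_spec(n = 10000, alpha = 1e-4)))
  h1 <- withr::local_tempfile(fileext = ".html")
  h2 <- withr::local_tempfile(fileext = ".html")
  render_interactive(pd, h1); render_interactive(pd, h2)
  expect_identical(readBin(h1, "raw", file.size(h1)), readBin(h2, "raw", file.size(h2)))
})
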