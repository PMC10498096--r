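#' ggplot2 rendering of trumpet-plot data
#'
#' Builds the static figure: points on a log10 frequency axis with curve
#' overlays. In signed mode the power curves are drawn symmetrically at
#' `+/- beta_min`, producing the two-sided trumpet.
#'
#' @param object a [build_plot_data()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.trumpet_data <- function(object, ...) {
  pts <- object$points
  spec <- object$spec
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = freq, y = beta)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.25, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(size = size, colour = color_value),
                        alpha = 0.8) +
    ggplot2::scale_size_identity() +
    ggplot2::scale_colour_viridis_c(name = expression(-log[10](italic(P)))) +
    ggplot2::scale_x_log10(limits = c(spec$f_min, spec$f_max),
                           breaks = object$axis_ticks,
                           labels = function(b) formatC(b, format = "g")) +
    ggplot2::labs(x = "Allele frequency (log scale)", y = "Effect size (beta)") +
    ggplot2::theme_bw()
  if (!is.null(object$curves)) {
    cv <- object$curves
    cv$level <- factor(cv$level)
    p <- p + ggplot2::geom_line(
      data = cv,
      ggplot2::aes(x = freq, y = beta_min, linetype = level),
      inherit.aes = FALSE, colour = "black", linewidth = 0.5)
    if (object$mirrored) {
      p <- p + ggplot2::geom_line(
        data = cv,
        ggplot2::aes(x = freq, y = -beta_min, linetype = level),
        inherit.aes = FALSE, colour = "black", linewidth = 0.5)
    }
    p <- p + ggplot2::scale_linetype_discrete(name = "Power")
  }
  p
}

#' @export
plot.trumpet_data <- function(x, ...) print(autoplot.trumpet_data(x, ...))

#' Render the trumpet plot to a static file
#'
#' @param data a `trumpet_data` object with at least one point.
#' @param path output path; format inferred from the extension when `format`
#'   is missing.
#' @param format `"svg"`, `"pdf"` or `"png"`.
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
render_static <- function(data, path, format = c("auto", "svg", "pdf", "png"),
                          width = 9, height = 6) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  if (!format %in% c("svg", "pdf", "png")) stop2("unsupported format: ", format)
  if (!nrow(data$points)) stop2("no points to render")
  g <- autoplot.trumpet_data(data)
  switch(format,
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150))
  on.exit(grDevices::dev.off())
  print(g)
  invisible(path)
}

# viridis-like hex colour for values in [0, cap]; deterministic
viridis_hex <- function(v, cap) {
  pal <- grDevices::hcl.colors(256, "viridis")
  idx <- 1 + round(pmin(pmax(v / cap, 0), 1) * 255)
  pal[idx]
}

#' Render a self-contained interactive trumpet plot
#'
#' Writes a standalone HTML file: points and curves are laid out in R,
#' serialized as embedded JSON in a stable order and number format, and drawn
#' client-side into an SVG with a hover tooltip showing exactly the
#' `hover_fields` of the plot spec. No external assets are referenced, and
#' re-rendering identical `trumpet_data` produces byte-identical HTML.
#'
#' Following the convention of keeping interactive files small, the renderer
#' applies its own display filter: points with `|beta| < min_effect` are
#' omitted (default 0.05; the threshold is inclusive, `|beta| == min_effect`
#' is kept). Set `min_effect = 0` to show every point.
#'
#' @param data a `trumpet_data` object with at least one point.
#' @param path output HTML path.
#' @param min_effect interactive display filter on `|beta|`, default 0.05.
#' @param width,height drawing size in pixels.
#' @return `path`, invisibly.
#' @export
render_interactive <- function(data, path, min_effect = 0.05,
                               width = 900, height = 600) {
  if (!nrow(data$points)) stop2("no points to render")
  spec <- data$spec
  pts <- data$points[abs(data$points$beta) >= min_effect, , drop = FALSE]
  if (!nrow(pts)) stop2("no points remain above the interactive display filter")
  pts <- pts[order(pts$variant_id), , drop = FALSE]

  # layout: log10 x, linear y, 60px margins
  mar <- 60
  lx <- log10(c(spec$f_min, spec$f_max))
  ymax_pts <- max(abs(pts$beta))
  ymax_cv <- if (!is.null(data$curves)) {
    stats::quantile(data$curves$beta_min, 0.95)  # curves diverge at rare f; cap the panel
  } else 0
  ymax <- max(ymax_pts, ymax_cv) * 1.05
  ylim <- if (data$mirrored) c(-ymax, ymax) else c(0, ymax)
  px <- function(f) mar + (log10(f) - lx[1]) / diff(lx) * (width - 2 * mar)
  py <- function(b) height - mar - (b - ylim[1]) / diff(ylim) * (height - 2 * mar)

  hover <- lapply(seq_len(nrow(pts)), function(i) {
    payload <- lapply(spec$hover_fields, function(h) {
      v <- pts[[h]][i]
      if (is.numeric(v)) as.numeric(fmt_num(v, 6)) else v
    })
    names(payload) <- spec$hover_fields
    payload
  })
  points_json <- jsonlite::toJSON(
    list(cx = round(px(pts$freq), 2), cy = round(py(pts$beta), 2),
         r = round(pts$size * 2, 2),
         col = viridis_hex(pts$color_value, spec$color_cap),
         hover = hover),
    auto_unbox = TRUE, digits = NA, na = "null")

  curve_paths <- character(0)
  if (!is.null(data$curves)) {
    cv <- data$curves
    cv <- cv[cv$beta_min <= ymax, , drop = FALSE]
    for (lv in sort(unique(cv$level))) {
      sub <- cv[cv$level == lv, ]
      d <- paste0("M", paste(round(px(sub$freq), 2), round(py(sub$beta_min), 2),
                             sep = ",", collapse = " L"))
      curve_paths <- c(curve_paths, sprintf(
        '<path d="%s" fill="none" stroke="#333" stroke-width="1"><title>power %s</title></path>', d, fmt_num(lv, 3)))
      if (data$mirrored) {
        d2 <- paste0("M", paste(round(px(sub$freq), 2), round(py(-sub$beta_min), 2),
                                sep = ",", collapse = " L"))
        curve_paths <- c(curve_paths, sprintf(
          '<path d="%s" fill="none" stroke="#333" stroke-width="1"/>', d2))
      }
    }
  }
  ticks <- data$axis_ticks[data$axis_ticks >= spec$f_min & data$axis_ticks <= spec$f_max]
  tick_svg <- vapply(ticks, function(t) sprintf(
    '<g><line x1="%s" y1="%d" x2="%s" y2="%d" stroke="#000"/><text x="%s" y="%d" text-anchor="middle" font-size="11">%s</text></g>',
    round(px(t), 2), height - mar, round(px(t), 2), height - mar + 5,
    round(px(t), 2), height - mar + 18, formatC(t, format = "g")), character(1))

  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/><title>Trumpet plot</title>",
    "<style>body{font-family:sans-serif}#tip{position:absolute;display:none;background:#fff;border:1px solid #888;padding:4px 6px;font-size:12px;pointer-events:none;white-space:pre}</style>",
    "</head><body>",
    sprintf("<svg id=\"plot\" width=\"%d\" height=\"%d\">", width, height),
    sprintf("<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" stroke=\"#000\"/>",
            mar, height - mar, width - mar, height - mar),
    sprintf("<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" stroke=\"#000\"/>",
            mar, mar, mar, height - mar),
    if (data$mirrored) sprintf(
      "<line x1=\"%d\" y1=\"%s\" x2=\"%d\" y2=\"%s\" stroke=\"#ccc\" stroke-dasharray=\"3,3\"/>",
      mar, round(py(0), 2), width - mar, round(py(0), 2)) else character(0),
    tick_svg,
    sprintf("<text x=\"%d\" y=\"%d\" text-anchor=\"middle\" font-size=\"13\">Allele frequency (log scale)</text>",
            width %/% 2, height - 15),
    sprintf("<text x=\"15\" y=\"%d\" text-anchor=\"middle\" font-size=\"13\" transform=\"rotate(-90 15 %d)\">Effect size (beta)</text>",
            height %/% 2, height %/% 2),
    curve_paths,
    "<g id=\"pts\"></g>",
    "</svg>",
    "<div id=\"tip\"></div>",
    "<script>",
    sprintf("var D=%s;", points_json),
    "var g=document.getElementById('pts'),tip=document.getElementById('tip');",
    "for(var i=0;i<D.cx.length;i++){(function(i){",
    "var c=document.createElementNS('http://www.w3.org/2000/svg','circle');",
    "c.setAttribute('cx',D.cx[i]);c.setAttribute('cy',D.cy[i]);c.setAttribute('r',D.r[i]);",
    "c.setAttribute('fill',D.col[i]);c.setAttribute('fill-opacity','0.8');",
    "c.addEventListener('mouseover',function(e){var h=D.hover[i],s=[];",
    "for(var k in h){s.push(k+': '+h[k]);}",
    "tip.textContent=s.join('\\n');tip.style.display='block';",
    "tip.style.left=(e.pageX+12)+'px';tip.style.top=(e.pageY+12)+'px';});",
    "c.addEventListener('mouseout',function(){tip.style.display='none';});",
    "g.appendChild(c);})(i);}",
    "</script>",
    "</body></html>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(html, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
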