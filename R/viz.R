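# Attention heatmaps: 2D molecule depictions with atoms coloured on a
# symmetric diverging scale centred at coefficient 0 (scale limits are
# +/- max|c|, so the midpoint colour always means "average attention").
# The red/blue orientation is property-specific: for lipophilicity blue
# marks lipophilic-increasing atoms and red anti-lipophilic ones; for
# solubility red marks soluble-increasing atoms and blue anti-soluble ones.

.PROPERTY_COLOURS <- list(
  lipophilicity = list(positive = "#2166AC", negative = "#B2182B",
                       posLabel = "lipophilic-increasing",
                       negLabel = "anti-lipophilic"),
  solubility = list(positive = "#B2182B", negative = "#2166AC",
                    posLabel = "soluble-increasing",
                    negLabel = "anti-soluble"))

# Interpolate white -> endpoint colour; t in [0, 1].
.blend <- function(colour, t) {
  rgb <- grDevices::col2rgb(colour)
  grDevices::rgb(255 + (rgb[1] - 255) * t, 255 + (rgb[2] - 255) * t,
                 255 + (rgb[3] - 255) * t, maxColorValue = 255)
}

.coefficientColour <- function(coef, cmax, scheme) {
  if (cmax <= 0) return("#FFFFFF")
  t <- min(1, abs(coef) / cmax)
  if (coef >= 0) .blend(scheme$positive, t) else .blend(scheme$negative, t)
}

# Bond order of bond b (1-based over bonds, not directed edges).
.bondOrders <- function(graph) {
  nb <- nBonds(graph)
  if (nb == 0) return(integer(0))
  vapply(seq_len(nb), function(b)
    which.max(graph@edgeFeatures[2L * b - 1L, 1:4]), integer(1))
}

#' Render a per-atom attention heatmap
#'
#' Draws the molecule's 2D depiction with every atom coloured by its
#' attention coefficient on a symmetric diverging scale centred at zero.
#' SVG output is plain deterministic text; PNG uses the raster device.
#'
#' @param smiles SMILES of the molecule (must parse).
#' @param coefficients numeric vector, one coefficient per heavy atom (in
#'   the molecule's atom order, e.g. from [atomAttention()]).
#' @param path output file path.
#' @param property `"lipophilicity"` or `"solubility"`; sets the red/blue
#'   orientation (see above).
#' @param format `"svg"` (default) or `"png"`.
#' @param csvPath optional sidecar CSV path for (atom index, element,
#'   coefficient).
#' @return invisibly, `path`.
#' @export
renderHeatmap <- function(smiles, coefficients, path,
                          property = c("lipophilicity", "solubility"),
                          format = c("svg", "png"), csvPath = NULL) {
  property <- match.arg(property)
  format <- match.arg(format)
  graph <- molToGraph(smiles)
  n <- nAtoms(graph)
  if (length(coefficients) != n)
    stop("need one coefficient per heavy atom: got ", length(coefficients),
         " for ", n, " atoms")
  if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  scheme <- .PROPERTY_COLOURS[[property]]
  cmax <- max(abs(coefficients))
  cols <- vapply(coefficients, .coefficientColour, character(1),
                 cmax = cmax, scheme = scheme)
  legend <- sprintf("%s: %s = %s, %s = %s; scale ±%.4f",
                    property,
                    if (scheme$positive == "#2166AC") "blue" else "red",
                    scheme$posLabel,
                    if (scheme$negative == "#B2182B") "red" else "blue",
                    scheme$negLabel, cmax)
  if (format == "svg") .writeHeatmapSVG(graph, cols, legend, path)
  else .writeHeatmapPNG(graph, cols, legend, path)
  if (!is.null(csvPath)) {
    write.csv(data.frame(atom = seq_len(n), element = graph@elements,
                         coefficient = coefficients),
              csvPath, row.names = FALSE)
  }
  invisible(path)
}

# Geometry shared by both backends: scaled coordinates and per-bond segment
# lists (double/triple bonds as parallel offset lines).
.heatmapScene <- function(graph, scale = 45) {
  xy <- graph@coords
  xy <- sweep(xy, 2, apply(xy, 2, min))
  x <- xy[, 1] * scale + 60
  y <- (max(xy[, 2]) - xy[, 2]) * scale + 50   # flip y for screen coords
  segs <- NULL
  orders <- .bondOrders(graph)
  for (b in seq_len(nBonds(graph))) {
    e <- 2L * b - 1L
    i <- graph@edgeSource[e]; j <- graph@edgeTarget[e]
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    len <- sqrt(dx^2 + dy^2)
    ox <- if (len > 0) -dy / len * 3 else 0
    oy <- if (len > 0) dx / len * 3 else 0
    off <- switch(orders[b], 0, c(-1, 1), c(-1.6, 0, 1.6), c(-1, 1))
    dashed <- orders[b] == 4L
    for (k in seq_along(off)) {
      segs <- rbind(segs, data.frame(
        x1 = x[i] + ox * off[k], y1 = y[i] + oy * off[k],
        x2 = x[j] + ox * off[k], y2 = y[j] + oy * off[k],
        dashed = dashed & k > 1))
    }
  }
  list(x = x, y = y, segs = segs,
       width = max(x) + 60, height = max(y) + 70)
}

.writeHeatmapSVG <- function(graph, cols, legend, path) {
  sc <- .heatmapScene(graph)
  fmt <- function(v) formatC(v, format = "f", digits = 2)
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
    fmt(sc$width), fmt(sc$height), fmt(sc$width), fmt(sc$height)),
    '<rect width="100%" height="100%" fill="white"/>')
  if (!is.null(sc$segs)) {
    for (i in seq_len(nrow(sc$segs))) {
      s <- sc$segs[i, ]
      lines <- c(lines, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444" stroke-width="1.6"%s/>',
        fmt(s$x1), fmt(s$y1), fmt(s$x2), fmt(s$y2),
        if (s$dashed) ' stroke-dasharray="4,3"' else ""))
    }
  }
  for (i in seq_len(nAtoms(graph))) {
    lines <- c(lines, sprintf(
      '<circle cx="%s" cy="%s" r="11" fill="%s" stroke="#333333" stroke-width="0.8"/>',
      fmt(sc$x[i]), fmt(sc$y[i]), cols[i]), sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="9" text-anchor="middle" dominant-baseline="middle">%s</text>',
      fmt(sc$x[i]), fmt(sc$y[i]), graph@elements[i]))
  }
  lines <- c(lines, sprintf(
    '<text x="10" y="%s" font-family="sans-serif" font-size="10">%s</text>',
    fmt(sc$height - 10), legend), "</svg>")
  writeLines(lines, path)
}

.writeHeatmapPNG <- function(graph, cols, legend, path) {
  sc <- .heatmapScene(graph)
  grDevices::png(path, width = sc$width, height = sc$height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(NA, xlim = c(0, sc$width), ylim = c(sc$height, 0),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  if (!is.null(sc$segs))
    graphics::segments(sc$segs$x1, sc$segs$y1, sc$segs$x2, sc$segs$y2,
                       col = "#444444", lwd = 1.6,
                       lty = ifelse(sc$segs$dashed, 2, 1))
  graphics::symbols(sc$x, sc$y, circles = rep(11, length(sc$x)),
                    inches = FALSE, add = TRUE, bg = cols, fg = "#333333")
  graphics::text(sc$x, sc$y, graph@elements, cex = 0.7)
  graphics::text(10, sc$height - 10, legend, adj = 0, cex = 0.7)
}
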