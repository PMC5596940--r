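#' ThemeRiver stacked-stream layout
#'
#' Lays the per-slice topic strengths out as a symmetric stacked stream
#' ("river") flowing left to right.  At each slice anchor the stream
#' widths `w_k = s[k, t] * scale` are stacked in topic-id order starting
#' from `-(sum_k w_k) / 2`, so the band is symmetric about a straight
#' baseline.  Between anchors every stream width is interpolated with a
#' monotone piecewise-cubic (Fritsch-Carlson) scheme, which cannot
#' overshoot below the anchor values, so interpolated widths stay
#' non-negative and the stacked boundaries never cross; the band tiles
#' without gaps or overlaps by construction (boundaries are cumulative
#' sums of interpolated widths around a recentered baseline).
#'
#' @param s a `topic_strength` matrix (`K x T`, columns summing to 1) or
#'   any non-negative `K x T` matrix.
#' @param samples_per_gap interpolation points inserted between adjacent
#'   anchors (default 20).
#' @param scale total band height at the anchors (default 1).
#' @param anchor_x horizontal anchor positions: `"uniform"` (default,
#'   slices equally spaced) or a numeric vector of length `T` (e.g. slice
#'   mid-years for a calendar-proportional axis).
#' @return an object of class `river_layout`: `x` (all sample positions),
#'   `anchor_idx` (positions of the anchors within `x`), `lower` and
#'   `upper` (`length(x) x K` envelope matrices), `scale`, `K`.
#'   Errors if `T < 2`.
#' @export
river_layout <- function(s, samples_per_gap = 20L, scale = 1,
                         anchor_x = "uniform") {
  s <- unclass(s)
  stopifnot(is.matrix(s), all(s >= 0), scale > 0, samples_per_gap >= 1L)
  K <- nrow(s)
  T_ <- ncol(s)
  if (T_ < 2L) stop("a river needs at least 2 slices, got ", T_)
  xa <- if (identical(anchor_x, "uniform")) {
    as.numeric(seq_len(T_))
  } else {
    stopifnot(is.numeric(anchor_x), length(anchor_x) == T_,
              all(diff(anchor_x) > 0))
    as.numeric(anchor_x)
  }
  x <- unique(unlist(lapply(seq_len(T_ - 1L), function(t) {
    seq(xa[t], xa[t + 1L], length.out = samples_per_gap + 1L)
  })))
  anchor_idx <- match(xa, x)
  widths <- vapply(seq_len(K), function(k) {
    f <- stats::splinefun(xa, s[k, ] * scale, method = "monoH.FC")
    f(x)
  }, numeric(length(x)))
  widths <- matrix(widths, nrow = length(x), ncol = K)
  widths[widths < 0] <- 0   # guard against sub-eps rounding
  total <- rowSums(widths)
  base <- -total / 2
  cum <- matrix(0, length(x), K + 1L)
  for (k in seq_len(K)) cum[, k + 1L] <- cum[, k] + widths[, k]
  lower <- base + cum[, seq_len(K), drop = FALSE]
  upper <- base + cum[, seq_len(K) + 1L, drop = FALSE]
  structure(
    list(x = x, anchor_idx = anchor_idx, lower = lower, upper = upper,
         scale = scale, K = K),
    class = "river_layout"
  )
}

#' Render a river layout to SVG
#'
#' One closed path per topic (upper boundary forward, lower boundary
#' back), slice tick marks with labels along the horizontal axis, and a
#' legend mapping colors to topic labels.  Output is deterministic:
#' identical layouts render to byte-identical files.  Zero-strength
#' topics still emit their (zero-area) path.
#'
#' @param layout a [river_layout()].
#' @param path output SVG path.
#' @param colors one fill color per topic; the default palette cycles.
#' @param labels topic labels for the legend (default `"topic k"`).
#' @param slice_labels axis labels at the anchors (default slice index).
#' @param width,height canvas size in pixels.
#' @return `path`, invisibly.
#' @export
render_river_svg <- function(layout, path,
                             colors = NULL, labels = NULL,
                             slice_labels = NULL,
                             width = 960, height = 480) {
  stopifnot(inherits(layout, "river_layout"))
  K <- layout$K
  if (is.null(colors)) colors <- river_palette(K)
  colors <- rep_len(colors, K)
  if (is.null(labels)) labels <- paste("topic", seq_len(K))
  if (is.null(slice_labels)) {
    slice_labels <- as.character(seq_along(layout$anchor_idx))
  }
  margin <- c(top = 20, right = 150, bottom = 40, left = 20)
  plot_w <- width - margin["left"] - margin["right"]
  plot_h <- height - margin["top"] - margin["bottom"]
  xr <- range(layout$x)
  yr <- range(c(layout$lower, layout$upper))
  if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
  px <- function(x) margin["left"] + (x - xr[1L]) / diff(xr) * plot_w
  py <- function(y) margin["top"] + (yr[2L] - y) / diff(yr) * plot_h
  fmt <- function(v) sprintf("%.3f", v)

  out <- c(
    sprintf(
      paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" ",
             "height=\"%d\" viewBox=\"0 0 %d %d\">"),
      width, height, width, height
    ),
    "<rect width=\"100%\" height=\"100%\" fill=\"white\"/>"
  )
  for (k in seq_len(K)) {
    up <- paste(fmt(px(layout$x)), fmt(py(layout$upper[, k])), sep = ",")
    lo <- paste(fmt(px(rev(layout$x))), fmt(py(rev(layout$lower[, k]))),
                sep = ",")
    d <- paste0("M", up[1L], " L",
                paste(c(up[-1L], lo), collapse = " L"), " Z")
    out <- c(out, sprintf(
      "<path class=\"stream\" d=\"%s\" fill=\"%s\" stroke=\"none\"/>",
      d, colors[k]
    ))
  }
  axis_y <- margin["top"] + plot_h
  for (i in seq_along(layout$anchor_idx)) {
    ax <- px(layout$x[layout$anchor_idx[i]])
    out <- c(out,
      sprintf(
        paste0("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
               "stroke=\"black\"/>"),
        fmt(ax), fmt(axis_y), fmt(ax), fmt(axis_y + 5)
      ),
      sprintf(
        paste0("<text x=\"%s\" y=\"%s\" font-size=\"11\" ",
               "text-anchor=\"middle\">%s</text>"),
        fmt(ax), fmt(axis_y + 18), xml_escape(slice_labels[i])
      )
    )
  }
  for (k in seq_len(K)) {
    ly <- margin["top"] + (k - 1) * 16
    lx <- width - margin["right"] + 10
    out <- c(out,
      sprintf(
        paste0("<rect x=\"%s\" y=\"%s\" width=\"12\" height=\"12\" ",
               "fill=\"%s\"/>"),
        fmt(lx), fmt(ly), colors[k]
      ),
      sprintf(
        "<text x=\"%s\" y=\"%s\" font-size=\"11\">%s</text>",
        fmt(lx + 16), fmt(ly + 10), xml_escape(labels[k])
      )
    )
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}

river_palette <- function(K) {
  base <- c(
    "#4e79a7", "#f28e2b", "#e15759", "#76b7b2", "#59a14f", "#edc948",
    "#b07aa1", "#ff9da7", "#9c755f", "#bab0ac", "#1f77b4", "#ff7f0e",
    "#2ca02c", "#d62728", "#9467bd", "#8c564b", "#e377c2", "#7f7f7f",
    "#bcbd22", "#17becf"
  )
  rep_len(base, K)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}
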