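## Squarified treemap of signals per system organ class.
##
## Layout follows the classic squarified algorithm: sizes sorted in
## decreasing order are packed greedily into rows along the shorter side
## of the remaining canvas; a row is closed as soon as adding the next
## size would worsen its worst rectangle aspect ratio. Every rectangle's
## area is exactly proportional to its size, so area encodes the number
## of signals while fill color encodes the number of reports.

# worst aspect ratio of a row of areas laid along a side of length len
row_worst_ratio <- function(areas, len) {
  s <- sum(areas)
  mx <- max(areas); mn <- min(areas)
  max(len^2 * mx / s^2, s^2 / (len^2 * mn))
}

squarify_rows <- function(areas, x, y, w, h) {
  out <- vector("list", length(areas))
  n_out <- 0
  i <- 1
  while (i <= length(areas)) {
    len <- min(w, h)
    row <- areas[i]
    j <- i
    while (j < length(areas)) {
      if (row_worst_ratio(c(row, areas[j + 1]), len) <=
          row_worst_ratio(row, len)) {
        j <- j + 1
        row <- c(row, areas[j])
      } else break
    }
    thick <- sum(row) / len
    offs <- c(0, cumsum(row / thick))
    for (k in seq_along(row)) {
      n_out <- n_out + 1
      out[[n_out]] <- if (w >= h) {
        c(x = x, y = y + offs[k], width = thick, height = row[k] / thick)
      } else {
        c(x = x + offs[k], y = y, width = row[k] / thick, height = thick)
      }
    }
    if (w >= h) {
      x <- x + thick; w <- w - thick
    } else {
      y <- y + thick; h <- h - thick
    }
    i <- j + 1
  }
  do.call(rbind, out[seq_len(n_out)])
}

#' Squarified treemap layout of SOC summaries
#'
#' Computes rectangle positions on the unit canvas for a set of SOC
#' summaries; each rectangle's area is proportional to the SOC's signal
#' count (`n_signals`). Input is laid out in decreasing signal order (ties
#' by SOC name), deterministically.
#'
#' @param summaries Data frame as returned by [rollup_by_soc()] (columns
#'   `soc`, `n_signals`, `n_reports`); at least one row must have
#'   `n_signals > 0` and zero-signal rows are dropped.
#' @return Data frame with columns `soc`, `x`, `y`, `width`, `height`
#'   (normalized `[0, 1]` canvas units), `n_signals`, `n_reports`.
#' @examples
#' s <- data.frame(soc = c("A", "B"), n_signals = c(3, 1),
#'                 n_reports = c(40, 5))
#' treemap_layout(s) # areas 0.75 and 0.25
#' @export
treemap_layout <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("soc", "n_signals", "n_reports") %in% names(summaries)))
  summaries <- summaries[summaries$n_signals > 0, , drop = FALSE]
  if (nrow(summaries) == 0) {
    pv_stop("pv_empty_error", "treemap needs at least one SOC with signals")
  }
  summaries <- summaries[c_order(-summaries$n_signals, summaries$soc), ,
                         drop = FALSE]
  areas <- summaries$n_signals / sum(summaries$n_signals)
  rects <- squarify_rows(areas, 0, 0, 1, 1)
  out <- data.frame(soc = summaries$soc,
                    x = rects[, "x"], y = rects[, "y"],
                    width = rects[, "width"], height = rects[, "height"],
                    n_signals = summaries$n_signals,
                    n_reports = summaries$n_reports,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# sequential fill scale: log10(n_reports) mapped linearly onto a
# light-yellow to dark-red ramp between the data min and max
treemap_fill <- function(n_reports) {
  v <- log10(pmax(n_reports, 1))
  rng <- range(v)
  t <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0.5, length(v))
  ramp <- grDevices::colorRamp(c("#FFF7BC", "#FB6A4A", "#99000D"))
  grDevices::rgb(ramp(t), maxColorValue = 255)
}

#' Render a treemap layout to SVG
#'
#' Writes a standalone SVG in which rectangle area encodes the number of
#' signals per SOC and fill color encodes the number of reports
#' (log10-scaled light-yellow to dark-red ramp spanning the data range).
#'
#' @param layout Output of [treemap_layout()].
#' @param file Output SVG path.
#' @param width,height Canvas size in pixels.
#' @return `file`, invisibly.
#' @export
treemap_svg <- function(layout, file, width = 1000, height = 620) {
  stopifnot(is.data.frame(layout),
            all(c("soc", "x", "y", "width", "height", "n_reports") %in%
                  names(layout)))
  fills <- treemap_fill(layout$n_reports)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height),
    unlist(lapply(seq_len(nrow(layout)), function(i) {
      r <- layout[i, ]
      x <- r$x * width; y <- r$y * height
      w <- r$width * width; h <- r$height * height
      label <- sprintf("%s (%d signals, %d reports)",
                       r$soc, r$n_signals, r$n_reports)
      c(sprintf(paste0('<rect x="%.4f" y="%.4f" width="%.4f" height="%.4f" ',
                       'fill="%s" stroke="#FFFFFF" stroke-width="1.5">'),
                x, y, w, h, fills[i]),
        sprintf("<title>%s</title>", esc(label)),
        "</rect>",
        if (w > 90 && h > 18) {
          sprintf(paste0('<text x="%.4f" y="%.4f" font-size="11" ',
                         'font-family="sans-serif" fill="#1A1A1A">%s</text>'),
                  x + 4, y + 14, esc(r$soc))
        })
    })),
    "</svg>"
  )
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(file)
}
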