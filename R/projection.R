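#' Coronal projection of a labeled volume
#'
#' Projects the selected structures along the AP axis into a 2D image that
#' mimics an AP radiograph: each pixel holds the traversed structure
#' thickness in mm (occupancy count times the AP voxel size), so overlapping
#' anatomy appears denser, as on a radiograph. Rows run superior to inferior
#' (cranial at the top), columns left to right in patient coordinates.
#'
#' @param vol a `labeled_volume`.
#' @param labels integer label values to project (e.g. the scheme's
#'   vertebrae); must be non-empty.
#' @return A `projection_image`: list with `intensity` (matrix, rows = SI
#'   cranial-up, cols = LR), `pixel_spacing` (mm, row/col), `extent_s`
#'   (superior coordinate of row 1) and `source`.
#' @export
coronal_projection <- function(vol, labels) {
  stopifnot(inherits(vol, "labeled_volume"))
  labels <- as.integer(labels)
  if (length(labels) == 0L) sc_stop("format", "empty label selection")
  sel <- array(vol$labels %in% labels, dim = dim(vol$labels))
  thick <- apply(sel, c(1, 3), sum) * vol$spacing[2] # sum over AP
  img <- thick[rev(seq_len(nrow(thick))), , drop = FALSE] # cranial at top
  structure(list(intensity = img,
                 pixel_spacing = vol$spacing[c(1, 3)],
                 extent_s = (dim(vol$labels)[1] - 1) * vol$spacing[1],
                 source = vol$source),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %d x %d px, %.2f x %.2f mm/px, max thickness %.1f mm\n",
              nrow(x$intensity), ncol(x$intensity),
              x$pixel_spacing[1], x$pixel_spacing[2], max(x$intensity)))
  invisible(x)
}

#' Endplate line segments in image pixel coordinates
#'
#' Computes, for each endplate half-plane in the angle table, the segment the
#' overlay renderer draws: centred on the plane centroid's (LR, SI) position,
#' tilted by the plane's coronal angle. A +10 degree endplate draws as a line
#' whose physical slope (change in S per unit R) is -tan(10 deg): the
#' endplate line is perpendicular to the projected normal.
#'
#' @param table an `endplate_angle_table`.
#' @param image a `projection_image` from the same volume.
#' @param half_length half segment length in mm.
#' @return data.frame with one row per endplate: `level`, `half`, `angle`,
#'   and pixel-space endpoints `row0`, `col0`, `row1`, `col1` (fractional,
#'   row 1 = cranial).
#' @export
endplate_segments <- function(table, image, half_length = 25) {
  seg <- function(s, r, ang, level, half) {
    th <- ang * pi / 180
    # line direction perpendicular to the projected normal (sin th, cos th)
    dr <- cos(th) * half_length  # along +R
    ds <- -sin(th) * half_length # along +S
    data.frame(level = level, half = half, angle = ang,
               row0 = (image$extent_s - (s - ds)) / image$pixel_spacing[1] + 1,
               col0 = (r - dr) / image$pixel_spacing[2] + 1,
               row1 = (image$extent_s - (s + ds)) / image$pixel_spacing[1] + 1,
               col1 = (r + dr) / image$pixel_spacing[2] + 1,
               stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(table)), function(i) {
    rbind(seg(table$upper_s[i], table$upper_r[i], table$upper_coronal[i],
              table$level[i], "upper"),
          seg(table$lower_s[i], table$lower_r[i], table$lower_coronal[i],
              table$level[i], "lower"))
  })
  do.call(rbind, out)
}

#' Render a measurement overlay
#'
#' Writes a PNG of the coronal projection with one line per fitted endplate
#' plane (white) and the pair realizing the reported Cobb angle highlighted
#' (red); the angle value is printed in the top margin.
#'
#' @param image a `projection_image`.
#' @param table the `endplate_angle_table` of the same volume.
#' @param measurement a `cobb_measurement` to highlight.
#' @param out output PNG path.
#' @param half_length endplate line half-length in mm.
#' @return `out`, invisibly.
#' @export
render_measurement <- function(image, table, measurement, out, half_length = 25) {
  base <- image$intensity / max(image$intensity, 1e-9)
  rgb <- array(rep(base, 3), dim = c(dim(base), 3))
  segs <- endplate_segments(table, image, half_length = half_length)
  key <- paste0(segs$level, ":", segs$half)
  hot <- key %in% c(measurement$top_source, measurement$bottom_source)
  for (i in order(hot)) { # draw highlighted lines last
    col <- if (hot[i]) c(1, 0.1, 0.1) else c(1, 1, 1)
    rgb <- draw_line(rgb, segs$row0[i], segs$col0[i], segs$row1[i], segs$col1[i], col)
  }
  label <- sprintf("%.1f DEG %s-%s", measurement$angle, measurement$top,
                   measurement$bottom)
  rgb <- draw_text(rgb, 2, 2, label, c(1, 0.9, 0.2))
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({ png::writePNG(rgb, out); TRUE },
                 error = function(e) sc_stop("io", "cannot write %s: %s", out,
                                             conditionMessage(e)))
  invisible(out)
}

# simple DDA line rasterizer on an rows x cols x 3 array
draw_line <- function(rgb, r0, c0, r1, c1, col) {
  n <- max(2L, ceiling(max(abs(r1 - r0), abs(c1 - c0))) * 2L)
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  keep <- rr >= 1 & rr <= dim(rgb)[1] & cc >= 1 & cc <= dim(rgb)[2]
  rr <- rr[keep]; cc <- cc[keep]
  for (ch in 1:3) rgb[cbind(rr, cc, ch)] <- col[ch]
  rgb
}

# 3x5 bitmap glyphs for the overlay caption
glyphs <- local({
  g <- list(
    "0" = c("111","101","101","101","111"), "1" = c("010","110","010","010","111"),
    "2" = c("111","001","111","100","111"), "3" = c("111","001","111","001","111"),
    "4" = c("101","101","111","001","001"), "5" = c("111","100","111","001","111"),
    "6" = c("111","100","111","101","111"), "7" = c("111","001","010","010","010"),
    "8" = c("111","101","111","101","111"), "9" = c("111","101","111","001","111"),
    "." = c("000","000","000","000","010"), "-" = c("000","000","111","000","000"),
    " " = c("000","000","000","000","000"),
    "D" = c("110","101","101","101","110"), "E" = c("111","100","110","100","111"),
    "G" = c("111","100","101","101","111"), "L" = c("100","100","100","100","111"),
    "T" = c("111","010","010","010","010"), "S" = c("111","100","111","001","111"),
    "A" = c("010","101","111","101","101"), "B" = c("110","101","110","101","110"),
    "C" = c("111","100","100","100","111"), "1" = c("010","110","010","010","111")
  )
  lapply(g, function(rows) do.call(rbind, lapply(rows, function(r)
    as.integer(strsplit(r, "")[[1]]) == 1L)))
})

draw_text <- function(rgb, row, col, text, colr, scale = 2L) {
  chars <- strsplit(toupper(text), "")[[1]]
  x <- col
  for (ch in chars) {
    gl <- glyphs[[ch]]
    if (!is.null(gl)) {
      for (i in 1:5) for (j in 1:3) if (gl[i, j]) {
        rr <- row + (i - 1L) * scale + seq_len(scale) - 1L
        cc <- x + (j - 1L) * scale + seq_len(scale) - 1L
        rr <- rr[rr <= dim(rgb)[1]]; cc <- cc[cc <= dim(rgb)[2]]
        for (chn in 1:3) rgb[rr, cc, chn] <- colr[chn]
      }
    }
    x <- x + 4L * scale
  }
  rgb
}
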