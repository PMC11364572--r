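#' Projected endplate angles
#'
#' `coronal_angle` projects a plane's (cranially sign-normalized) normal onto
#' the coronal (LR-SI) plane and returns the signed angle in degrees between
#' the SI axis and that projection — the tilt of the endplate line as seen on
#' an AP radiograph. The sign convention is positive for normals leaning
#' toward the patient's right. `sagittal_angle` is the mirror image on the
#' sagittal (PA-SI) plane, positive for normals leaning anteriorly. Both lie
#' in (-90, 90].
#'
#' A pure sagittal tilt has coronal angle 0 and vice versa: the two
#' projections separate the components exactly.
#'
#' @param plane a [plane()].
#' @return Angle in degrees.
#' @export
coronal_angle <- function(plane) {
  n <- plane$normal
  if (sqrt(n[1]^2 + n[3]^2) < 1e-9)
    sc_stop("undefined_angle",
            "normal is parallel to the AP axis; coronal angle undefined")
  unname(atan2(n[3], n[1]) * 180 / pi)
}

#' @rdname coronal_angle
#' @export
sagittal_angle <- function(plane) {
  n <- plane$normal
  if (sqrt(n[1]^2 + n[2]^2) < 1e-9)
    sc_stop("undefined_angle",
            "normal is parallel to the LR axis; sagittal angle undefined")
  unname(atan2(n[2], n[1]) * 180 / pi)
}

#' Build the per-endplate angle table
#'
#' Orders the fitted disc planes cranial to caudal and tabulates, per disc,
#' the coronal and sagittal angles of its upper and lower half-planes. The
#' upper half of a disc measures the inferior endplate of the vertebra above
#' it; the lower half the superior endplate of the vertebra below it.
#'
#' @param discs list of `disc_planes` objects (any order); each must carry a
#'   `level` name present in the scheme.
#' @param scheme a `label_scheme` providing level names and ordering.
#' @return An `endplate_angle_table` (data.frame): one row per disc, cranial
#'   to caudal, with columns `level`, `vert_above`, `vert_below`,
#'   `upper_coronal`, `lower_coronal`, `upper_sagittal`, `lower_sagittal`,
#'   centroid coordinates of both half-planes, and half vertex counts.
#' @export
build_angle_table <- function(discs, scheme) {
  stopifnot(length(discs) >= 1L, inherits(scheme, "label_scheme"))
  rows <- lapply(discs, function(d) {
    stopifnot(inherits(d, "disc_planes"))
    i <- match(d$level, scheme$discs$name)
    if (is.na(i))
      sc_stop("unavailable_level", "disc level '%s' is not in the scheme", d$level)
    data.frame(level = d$level,
               vert_above = scheme$discs$above[i],
               vert_below = scheme$discs$below[i],
               upper_coronal = coronal_angle(d$upper_plane),
               lower_coronal = coronal_angle(d$lower_plane),
               upper_sagittal = sagittal_angle(d$upper_plane),
               lower_sagittal = sagittal_angle(d$lower_plane),
               mid_s = d$mid_plane$centroid[1],
               upper_s = d$upper_plane$centroid[1],
               upper_r = d$upper_plane$centroid[3],
               lower_s = d$lower_plane$centroid[1],
               lower_r = d$lower_plane$centroid[3],
               n_upper = d$n_upper, n_lower = d$n_lower,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$mid_s), , drop = FALSE] # cranial (large S) first
  rownames(tab) <- NULL
  if (nrow(tab) > 1L) {
    # SI extents must not interleave: each disc's lower centroid stays above
    # the next (more caudal) disc's upper centroid
    for (i in seq_len(nrow(tab) - 1L))
      if (tab$lower_s[i] <= tab$upper_s[i + 1L])
        sc_stop("ordering", "discs '%s' and '%s' have interleaved SI extents",
                tab$level[i], tab$level[i + 1L])
    # and the cranial->caudal order must match the scheme
    if (is.unsorted(match(tab$level, scheme$discs$name)))
      sc_stop("ordering", "disc SI ordering contradicts the scheme ordering")
  }
  class(tab) <- c("endplate_angle_table", "data.frame")
  tab
}

#' Enumerate all candidate Cobb angles
#'
#' For every ordered disc pair (a cranial to b), forms the candidate whose
#' top vertebra is the vertebra below disc a (superior endplate = lower half
#' of a) and whose bottom vertebra is the vertebra above disc b (inferior
#' endplate = upper half of b); the candidate angle is the absolute
#' difference of the two signed projected angles. Adjacent discs give
#' single-vertebra candidates (top = bottom).
#'
#' @param table an `endplate_angle_table`.
#' @param plane_kind `"coronal"` or `"sagittal"`.
#' @param min_span smallest number of vertebrae a candidate may span
#'   (1 = allow single-vertebra candidates).
#' @return data.frame of candidates: `top`, `bottom`, `angle`, `span`,
#'   `top_source`, `bottom_source`, `plane_kind`.
#' @export
candidate_angles <- function(table, plane_kind = c("coronal", "sagittal"),
                             min_span = 1L) {
  plane_kind <- match.arg(plane_kind)
  n <- nrow(table)
  if (n < 1L) sc_stop("no_measurement", "empty angle table")
  lower <- table[[paste0("lower_", plane_kind)]]
  upper <- table[[paste0("upper_", plane_kind)]]
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) # (a, b), a < b
  if (nrow(pairs) == 0L)
    sc_stop("no_measurement",
            "a single disc admits no endplate pair; no Cobb candidates")
  a <- pairs[, 1]; b <- pairs[, 2]
  out <- data.frame(
    top = table$vert_below[a],
    bottom = table$vert_above[b],
    angle = abs(lower[a] - upper[b]),
    span = b - a,
    top_source = paste0(table$level[a], ":lower"),
    bottom_source = paste0(table$level[b], ":upper"),
    plane_kind = plane_kind,
    disc_a = a, disc_b = b,
    stringsAsFactors = FALSE
  )
  out <- out[out$span >= min_span, , drop = FALSE]
  if (nrow(out) == 0L)
    sc_stop("no_measurement", "no candidate spans at least %d vertebra(e)", min_span)
  rownames(out) <- NULL
  out
}

#' Select the maximal Cobb angle
#'
#' The Cobb angle is realized by the most tilted endplate pair, i.e. the
#' candidate with the largest angle. Ties are broken deterministically in
#' favour of the larger vertebral span, then the more cranial top level.
#'
#' @param candidates data.frame from [candidate_angles()].
#' @param tol angles within `tol` of the maximum count as tied.
#' @return A `cobb_measurement`: `angle` (degrees, >= 0), `top`, `bottom`,
#'   `top_source`, `bottom_source`, `plane_kind`.
#' @export
max_cobb <- function(candidates, tol = 0) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    sc_stop("no_measurement", "no candidate measurements")
  tied <- which(candidates$angle >= max(candidates$angle) - tol)
  cand <- candidates[tied, , drop = FALSE]
  ord <- if (!is.null(cand$disc_a)) order(-cand$span, cand$disc_a)
         else order(-cand$span)
  cand <- cand[ord, , drop = FALSE]
  as_cobb_measurement(cand[1L, , drop = FALSE])
}

as_cobb_measurement <- function(row) {
  structure(list(angle = row$angle, top = row$top, bottom = row$bottom,
                 top_source = row$top_source, bottom_source = row$bottom_source,
                 plane_kind = row$plane_kind),
            class = "cobb_measurement")
}

#' @export
print.cobb_measurement <- function(x, ...) {
  cat(sprintf("<cobb_measurement> %.2f deg (%s) %s -> %s\n",
              x$angle, x$plane_kind, x$top, x$bottom))
  invisible(x)
}

#' Cobb angle at reader-chosen levels
#'
#' Measures the angle between the superior endplate of `top` and the
#' inferior endplate of `bottom`, the same quantity a reader obtains by
#' drawing lines at those levels.
#'
#' @param table an `endplate_angle_table`.
#' @param top,bottom vertebra level names; `top` cranial to or equal to
#'   `bottom`.
#' @param plane_kind `"coronal"` or `"sagittal"`.
#' @return A `cobb_measurement`.
#' @export
cobb_at_levels <- function(table, top, bottom, plane_kind = c("coronal", "sagittal")) {
  plane_kind <- match.arg(plane_kind)
  ia <- match(top, table$vert_below)     # disc above the top vertebra
  ib <- match(bottom, table$vert_above)  # disc below the bottom vertebra
  if (is.na(ia))
    sc_stop("unavailable_level",
            "no disc above vertebra '%s'; its superior endplate is unavailable", top)
  if (is.na(ib))
    sc_stop("unavailable_level",
            "no disc below vertebra '%s'; its inferior endplate is unavailable", bottom)
  if (ia > ib)
    sc_stop("unavailable_level", "top level '%s' is caudal to bottom level '%s'", top, bottom)
  lower <- table[[paste0("lower_", plane_kind)]]
  upper <- table[[paste0("upper_", plane_kind)]]
  as_cobb_measurement(data.frame(
    angle = abs(lower[ia] - upper[ib]), top = top, bottom = bottom,
    top_source = paste0(table$level[ia], ":lower"),
    bottom_source = paste0(table$level[ib], ":upper"),
    plane_kind = plane_kind, stringsAsFactors = FALSE))
}
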