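#' Measure the Cobb angle of a labeled spine volume
#'
#' Runs the full measurement chain on a segmentation: quality control, per-
#' disc endplate plane fitting, the endplate angle table, the candidate-angle
#' enumeration, and the maximal coronal (and optionally sagittal) Cobb angle.
#'
#' @param vol a `labeled_volume` or a path readable by
#'   [load_labeled_volume()].
#' @param scheme a `label_scheme`.
#' @param plane_kind `"coronal"`, `"sagittal"` or `"both"`.
#' @param min_span smallest vertebral span for candidates (see
#'   [candidate_angles()]).
#' @param disc_cfg settings from [disc_config()].
#' @param qc_cfg settings from [qc_config()].
#' @return A `cobb_result`: `qc` (a `qc_report`), `table`
#'   (`endplate_angle_table`), `candidates`, `max` (coronal
#'   `cobb_measurement`), `max_sagittal` (when requested), `discs` (the
#'   fitted `disc_planes`), `scheme`, `source`.
#' @export
measure_volume <- function(vol, scheme = default_scheme(),
                           plane_kind = c("coronal", "sagittal", "both"),
                           min_span = 1L, disc_cfg = disc_config(),
                           qc_cfg = qc_config()) {
  plane_kind <- match.arg(plane_kind)
  if (is.character(vol)) vol <- load_labeled_volume(vol, scheme)
  stopifnot(inherits(vol, "labeled_volume"))
  qc <- qc_segmentation(vol, scheme, qc_cfg)
  present <- unique(as.vector(vol$labels))
  disc_rows <- which(scheme$discs$label %in% present)
  if (length(disc_rows) == 0L)
    sc_stop("no_measurement", "no disc labels present in the volume")
  discs <- lapply(disc_rows, function(i) {
    st <- extract_structure(vol, scheme$discs$label[i])
    disc_planes(st$mask, st$spacing, config = disc_cfg,
                level = scheme$discs$name[i])
  })
  tab <- build_angle_table(discs, scheme)
  res <- list(qc = qc, table = tab, discs = discs, scheme = scheme,
              source = vol$source)
  if (nrow(tab) < 2L) {
    # a single disc admits no endplate pair: report the angle table only
    warning("only one disc in the field of view; no Cobb candidates")
    class(res) <- "cobb_result"
    return(res)
  }
  if (plane_kind %in% c("coronal", "both")) {
    res$candidates <- candidate_angles(tab, "coronal", min_span = min_span)
    res$max <- max_cobb(res$candidates)
  }
  if (plane_kind %in% c("sagittal", "both")) {
    res$candidates_sagittal <- candidate_angles(tab, "sagittal", min_span = min_span)
    res$max_sagittal <- max_cobb(res$candidates_sagittal)
    if (is.null(res$max)) res$max <- res$max_sagittal
  }
  class(res) <- "cobb_result"
  res
}

#' @export
print.cobb_result <- function(x, ...) {
  cat(sprintf("<cobb_result>%s\n", if (is.null(x$source)) "" else paste0(" ", x$source)))
  cat(sprintf("  QC: %s\n", if (x$qc$pass) "pass" else "FAIL"))
  if (is.null(x$max)) {
    cat(sprintf("  %d disc(s) measured; no endplate pair available\n", nrow(x$table)))
  } else {
    cat(sprintf("  max Cobb (%s): %.2f deg, %s -> %s\n", x$max$plane_kind,
                x$max$angle, x$max$top, x$max$bottom))
  }
  invisible(x)
}

#' Write a measurement report as JSON
#'
#' Serializes a `cobb_result` with a stable schema: `schema`, `source`,
#' `qc` (pass flag plus flag lists), `angle_table`, `candidates` and `max`
#' blocks.
#'
#' @param result a `cobb_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_measurement_report <- function(result, path) {
  stopifnot(inherits(result, "cobb_result"))
  meas <- function(m) if (is.null(m)) NULL else
    list(angle_deg = m$angle, top = m$top, bottom = m$bottom,
         top_source = m$top_source, bottom_source = m$bottom_source,
         plane_kind = m$plane_kind)
  payload <- list(
    schema = "spinecobb/measurement/1",
    source = result$source,
    qc = list(pass = result$qc$pass,
              disc_count_ok = result$qc$disc_count_ok,
              missing_discs = result$qc$missing_discs,
              fragmented_discs = as.list(result$qc$extra_components),
              shape_flags = result$qc$shape_flags),
    angle_table = as.data.frame(result$table)[
      c("level", "vert_above", "vert_below", "upper_coronal", "lower_coronal",
        "upper_sagittal", "lower_sagittal")],
    candidates = if (is.null(result$candidates)) NULL else
      result$candidates[c("top", "bottom", "angle", "span")],
    max = meas(result$max),
    max_sagittal = meas(result$max_sagittal)
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
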