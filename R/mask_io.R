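#' Labeled segmentation volumes
#'
#' A `labeled_volume` holds a 3D integer label array (0 = background) in a
#' fixed canonical anatomical frame together with its physical voxel spacing.
#' The canonical axis order is: axis 1 inferior to superior (S), axis 2
#' posterior to anterior (A), axis 3 left to right (R). All geometry in the
#' package assumes this frame; loading reorients files into it.
#'
#' @param labels 3D array of non-negative integers.
#' @param spacing numeric length-3, voxel size in mm along the (S, A, R) axes.
#' @param source optional provenance string (e.g. the file path).
#' @return An object of class `labeled_volume` with fields `labels`,
#'   `spacing` and `source`.
#' @export
labeled_volume <- function(labels, spacing, source = NULL) {
  if (length(dim(labels)) != 3L)
    sc_stop("format", "labels must be a 3D array")
  if (is.double(labels)) {
    if (any(labels != round(labels), na.rm = TRUE))
      sc_stop("format", "voxel values are not integers")
    storage.mode(labels) <- "integer"
  }
  if (anyNA(labels) || any(labels < 0L))
    sc_stop("format", "labels must be non-negative integers")
  labels <- array(as.integer(labels), dim = dim(labels)) # drop foreign attributes
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    sc_stop("format", "spacing must be three strictly positive values")
  structure(list(labels = labels, spacing = spacing, source = source),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s voxels, spacing %s mm (S,A,R), %d structure label(s)\n",
              paste(dim(x$labels), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Load a labeled segmentation volume
#'
#' Reads a NIfTI (`.nii`, `.nii.gz`) or MetaImage (`.mha`, `.mhd`) label
#' volume and reorients it into the canonical (S, A, R) frame using the
#' file's orientation metadata. Label values are unchanged; spacing is taken
#' from the header and permuted along with the axes.
#'
#' @param path path to the volume.
#' @param scheme optional `label_scheme`; when given, labels present in the
#'   volume but absent from the scheme (other than 0) trigger a warning.
#' @return A `labeled_volume`.
#' @export
load_labeled_volume <- function(path, scheme = NULL) {
  if (!file.exists(path))
    sc_stop("io", "file not found: %s", path)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z0-9]+)$", "\\1", basename(path)))
  if (ext %in% c(".nii", ".nii.gz")) {
    vol <- load_nifti(path)
  } else if (ext %in% c(".mha", ".mhd")) {
    vol <- load_metaimage(path)
  } else {
    sc_stop("io", "unsupported volume format '%s' (expected .nii[.gz], .mha or .mhd)", ext)
  }
  if (!is.null(scheme)) {
    known <- c(0L, scheme$vertebrae$label, scheme$discs$label, scheme$other)
    extra <- setdiff(unique(as.vector(vol$labels)), known)
    if (length(extra))
      warning(sprintf("volume %s contains labels not in the scheme: %s",
                      path, paste(extra, collapse = ", ")))
  }
  vol
}

load_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) sc_stop("io", "cannot read %s: %s", path, conditionMessage(e)))
  xf <- RNifti::xform(img)
  if (isTRUE(attr(xf, "code") == 0L))
    sc_stop("orientation", "no orientation metadata (qform/sform) in %s", path)
  RNifti::orientation(img) <- "SAR"
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  labeled_volume(arr, RNifti::pixdim(img)[1:3], source = path)
}

#' Write a labeled volume
#'
#' Writes NIfTI or MetaImage depending on the file extension. `orientation`
#' selects the on-disk axis order/direction (a three-letter code such as
#' `"SAR"`, `"RAS"`, `"LPI"`); loading the file back always returns the
#' canonical frame regardless of this choice.
#'
#' @param vol a `labeled_volume`.
#' @param path output path (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @param orientation three-letter on-disk orientation code.
#' @return `path`, invisibly.
#' @export
write_labeled_volume <- function(vol, path, orientation = "SAR") {
  stopifnot(inherits(vol, "labeled_volume"))
  perm <- orientation_permutation(orientation)
  arr <- vol$labels
  sp <- vol$spacing
  # flip axes that run opposite to canonical, then permute canonical -> disk
  for (ax in which(perm$flip)) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[ax]] <- rev(seq_len(dim(arr)[ax]))
    arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  arr <- aperm(arr, perm$axes) # disk axis i holds canonical axis perm$axes[i]
  sp_disk <- sp[perm$axes]
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z0-9]+)$", "\\1", basename(path)))
  if (ext %in% c(".nii", ".nii.gz")) {
    write_nifti_oriented(arr, sp_disk, orientation, path)
  } else if (ext %in% c(".mha", ".mhd")) {
    write_metaimage(arr, sp_disk, orientation, path)
  } else {
    sc_stop("io", "unsupported output format '%s'", ext)
  }
  invisible(path)
}

# decompose a 3-letter orientation code relative to the canonical "SAR":
# axes[i] = which canonical axis ends up on disk axis i; flip[j] = TRUE when
# canonical axis j must be reversed before permuting
orientation_permutation <- function(code) {
  code <- toupper(code)
  letters3 <- strsplit(code, "")[[1]]
  if (length(letters3) != 3L)
    sc_stop("orientation", "orientation code must have 3 letters, got '%s'", code)
  canon <- c("S", "A", "R") # positive direction of canonical axes 1..3
  axis_of <- c(S = 1L, I = 1L, A = 2L, P = 2L, R = 3L, L = 3L)
  pos_dir <- c(S = TRUE, I = FALSE, A = TRUE, P = FALSE, R = TRUE, L = FALSE)
  if (!all(letters3 %in% names(axis_of)))
    sc_stop("orientation", "invalid orientation code '%s'", code)
  axes <- unname(axis_of[letters3])
  if (length(unique(axes)) != 3L)
    sc_stop("orientation", "orientation code '%s' repeats an axis", code)
  flip <- logical(3)
  flip[axes] <- !unname(pos_dir[letters3])
  list(axes = axes, flip = flip)
}

write_nifti_oriented <- function(arr, sp_disk, code, path) {
  img <- RNifti::asNifti(arr)
  perm <- orientation_permutation(code)
  # affine column i = world direction of disk axis i (world frame = RAS)
  canon_world <- rbind(S = c(0, 0, 1), A = c(0, 1, 0), R = c(1, 0, 0)) # canonical axis -> RAS vector
  m <- matrix(0, 4, 4); m[4, 4] <- 1
  for (i in 1:3) {
    cx <- perm$axes[i]
    dir <- canon_world[cx, ] * ifelse(perm$flip[cx], -1, 1)
    m[1:3, i] <- dir * sp_disk[i]
  }
  # origin: keep the full extent in positive world coordinates
  for (w in 1:3) {
    neg <- sum(pmin(m[w, 1:3] * (dim(arr)[1:3] - 1), 0))
    m[w, 4] <- -neg
  }
  RNifti::`sform<-`(img, structure(m, code = 2L)) -> img
  RNifti::`pixdim<-`(img, sp_disk) -> img
  RNifti::writeNifti(img, path)
}

#' Extract one structure's binary mask
#'
#' @param vol a `labeled_volume`.
#' @param label integer label value.
#' @return list with `mask` (logical 3D array) and `spacing`.
#'   Raises a `spinecobb_empty_structure` error when the label is absent.
#' @export
extract_structure <- function(vol, label) {
  stopifnot(inherits(vol, "labeled_volume"))
  mask <- vol$labels == as.integer(label)
  if (!any(mask))
    sc_stop("empty_structure", "label %d not present in volume", as.integer(label))
  list(mask = mask, spacing = vol$spacing)
}

#' Quality-control configuration
#'
#' @param min_component_voxels components at or above this size count as real
#'   fragments when checking that a disc is a single connected piece.
#' @param min_coverage_fraction minimum fraction of the adjacent vertebrae's
#'   axial (in-plane) footprint a disc must cover; collapsed segmentations
#'   covering only part of the endplate fall below it.
#' @return list of thresholds.
#' @export
qc_config <- function(min_component_voxels = 100L, min_coverage_fraction = 0.6) {
  list(min_component_voxels = as.integer(min_component_voxels),
       min_coverage_fraction = min_coverage_fraction)
}

#' Quality control of a labeled segmentation
#'
#' Screens for the segmentation failure modes that can corrupt a Cobb
#' measurement: missing discs (an expected disc level with no voxels between
#' two present vertebrae), discs split into several sizeable connected
#' components, and discs whose in-plane footprint covers too small a fraction
#' of the adjacent vertebral endplates (one-sided collapse).
#'
#' @param vol a `labeled_volume`.
#' @param scheme a `label_scheme`.
#' @param config thresholds from [qc_config()].
#' @return A `qc_report` with fields `disc_count_ok`, `missing_discs`,
#'   `extra_components` (named count of sizeable fragments per flagged disc),
#'   `shape_flags` (named list of failed heuristics per disc) and `pass`.
#' @export
qc_segmentation <- function(vol, scheme, config = qc_config()) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(scheme, "label_scheme"))
  present <- unique(as.vector(vol$labels))
  vert_present <- scheme$vertebrae$label %in% present
  names(vert_present) <- scheme$vertebrae$name

  missing_discs <- character()
  extra_components <- integer()
  shape_flags <- list()

  footprint <- function(mask) sum(apply(mask, c(2, 3), any)) # axial (A,R) pixels covered

  for (i in seq_len(nrow(scheme$discs))) {
    d <- scheme$discs[i, ]
    if (!(vert_present[[d$above]] && vert_present[[d$below]])) next # disc outside FOV
    if (!(d$label %in% present)) {
      missing_discs <- c(missing_discs, d$name)
      next
    }
    mask <- vol$labels == d$label
    lab <- .label_components(mask, dim(mask))
    sizes <- tabulate(lab[lab > 0L])
    n_big <- sum(sizes >= config$min_component_voxels)
    if (n_big > 1L) extra_components[[d$name]] <- n_big
    # in-plane coverage against the mean adjacent vertebra footprint
    fp_disc <- footprint(mask)
    fp_vert <- mean(c(footprint(vol$labels == scheme$vertebrae$label[scheme$vertebrae$name == d$above]),
                      footprint(vol$labels == scheme$vertebrae$label[scheme$vertebrae$name == d$below])))
    if (fp_vert > 0 && fp_disc / fp_vert < config$min_coverage_fraction)
      shape_flags[[d$name]] <- c(shape_flags[[d$name]],
                                 sprintf("low_coverage (%.2f < %.2f)",
                                         fp_disc / fp_vert, config$min_coverage_fraction))
  }

  structure(list(disc_count_ok = length(missing_discs) == 0L && length(extra_components) == 0L,
                 missing_discs = missing_discs,
                 extra_components = extra_components,
                 shape_flags = shape_flags,
                 pass = length(missing_discs) == 0L && length(extra_components) == 0L &&
                        length(shape_flags) == 0L),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s\n", if (x$pass) "PASS" else "FAIL"))
  if (length(x$missing_discs))
    cat("  missing discs:", paste(x$missing_discs, collapse = ", "), "\n")
  if (length(x$extra_components))
    cat("  fragmented discs:",
        paste(sprintf("%s (%d pieces)", names(x$extra_components), x$extra_components),
              collapse = ", "), "\n")
  for (nm in names(x$shape_flags))
    cat(sprintf("  shape flag %s: %s\n", nm, paste(x$shape_flags[[nm]], collapse = "; ")))
  invisible(x)
}
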