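#' Extract a surface mesh from a binary mask
#'
#' Extracts the iso-0.5 surface of a binary mask as a triangle mesh by
#' tetrahedral decomposition of the voxel grid (a table-free marching-cubes
#' variant). Vertices are returned in physical millimetres in the canonical
#' (S, A, R) frame: voxel centre `(i, j, k)` (1-based) maps to
#' `((i-1)*spacing[1], (j-1)*spacing[2], (k-1)*spacing[3])`. The mask is
#' implicitly padded with background so the mesh is always closed.
#'
#' @param mask logical 3D array.
#' @param spacing voxel size in mm per axis.
#' @return A `surface_mesh`: list with `vertices` (n x 3 matrix, mm) and
#'   `faces` (m x 3 integer matrix of 1-based vertex indices).
#' @export
extract_mesh <- function(mask, spacing) {
  if (!is.logical(mask)) mask <- mask != 0
  if (length(dim(mask)) != 3L) sc_stop("format", "mask must be a 3D array")
  if (any(spacing <= 0)) sc_stop("format", "spacing must be positive")
  if (!any(mask)) sc_stop("empty_structure", "mask is empty")
  # crop to the bounding box for speed, restore the physical offset afterwards
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  if (any(hi - lo + 1L < 2L))
    sc_stop("degenerate_structure", "mask spans fewer than 2 voxels along an axis")
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  res <- .mesh_from_mask(as.logical(sub), dim(sub), as.numeric(spacing))
  offset <- (lo - 1) * spacing
  res$vertices <- sweep(res$vertices, 2, offset, `+`)
  colnames(res$vertices) <- c("S", "A", "R")
  structure(res, class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_surface_area(x)))
  invisible(x)
}

#' Total surface area of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return Area in mm^2.
#' @export
mesh_surface_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Export a mesh as ASCII PLY
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a plane
#'
#' A plane is a unit normal plus a point (its centroid), both in canonical
#' (S, A, R) millimetre coordinates. The normal is sign-normalized to point
#' cranially (non-negative S component; ties resolved toward non-negative R,
#' then A).
#'
#' @param normal length-3 numeric.
#' @param centroid length-3 numeric point on the plane.
#' @return An object of class `plane`.
#' @export
plane <- function(normal, centroid) {
  normal <- as.numeric(normal); centroid <- as.numeric(centroid)
  stopifnot(length(normal) == 3L, length(centroid) == 3L,
            all(is.finite(normal)), all(is.finite(centroid)))
  len <- sqrt(sum(normal^2))
  if (len < 1e-12) sc_stop("degenerate_fit", "zero-length normal")
  normal <- normal / len
  eps <- 1e-12
  flip <- normal[1] < -eps ||
    (abs(normal[1]) <= eps && (normal[3] < -eps ||
                               (abs(normal[3]) <= eps && normal[2] < 0)))
  if (flip) normal <- -normal
  names(normal) <- names(centroid) <- c("S", "A", "R")
  structure(list(normal = normal, centroid = centroid), class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane> normal (%.4f, %.4f, %.4f), centroid (%.1f, %.1f, %.1f) mm\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Fit a plane to points by PCA
#'
#' The centroid is the arithmetic mean of the points; the normal is the
#' eigenvector of the point covariance matrix with the smallest eigenvalue,
#' sign-normalized cranially.
#'
#' @param points n x 3 matrix of (S, A, R) coordinates, n >= 3.
#' @return A [plane()].
#' @export
fit_plane_pca <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    sc_stop("degenerate_fit", "need at least 3 points, got %d", nrow(points))
  ctr <- colMeans(points)
  cv <- stats::cov(points)
  if (any(!is.finite(cv))) sc_stop("degenerate_fit", "non-finite covariance")
  eg <- eigen(cv, symmetric = TRUE)
  # collinear clouds have two (near-)zero eigenvalues: no unique normal
  if (eg$values[2] <= max(eg$values[1], 1) * 1e-12)
    sc_stop("degenerate_fit", "points are collinear; plane normal undefined")
  plane(eg$vectors[, 3], ctr)
}

signed_distances <- function(points, pl) {
  as.vector(sweep(as.matrix(points), 2, pl$centroid) %*% pl$normal)
}

#' Split a disc mesh into upper and lower vertex sets
#'
#' Vertices with positive signed distance to the mid-plane (whose normal
#' points cranially) form the upper half; vertices on or below the plane the
#' lower half.
#'
#' @param mesh a `surface_mesh`.
#' @param mid_plane a [plane()], normally the PCA fit of all vertices.
#' @param min_vertices minimum vertex count per half.
#' @return list with `upper` and `lower` vertex matrices.
#' @export
split_disc <- function(mesh, mid_plane, min_vertices = 30L) {
  s <- signed_distances(mesh$vertices, mid_plane)
  upper <- mesh$vertices[s > 0, , drop = FALSE]
  lower <- mesh$vertices[s <= 0, , drop = FALSE]
  if (nrow(upper) < min_vertices || nrow(lower) < min_vertices)
    sc_stop("degenerate_disc",
            "disc half too small after split (upper %d, lower %d, need %d)",
            nrow(upper), nrow(lower), min_vertices)
  list(upper = upper, lower = lower)
}

#' Disc geometry configuration
#'
#' @param min_half_vertices minimum mesh vertices per disc half for a stable
#'   plane fit.
#' @return list of settings.
#' @export
disc_config <- function(min_half_vertices = 30L) {
  list(min_half_vertices = as.integer(min_half_vertices))
}

#' Fit endplate planes through one disc
#'
#' Runs the per-disc measurement chain: surface mesh extraction, PCA
#' mid-plane fit, upper/lower vertex split, and a PCA plane fit per half.
#' The two half-planes approximate the adjacent vertebral endplates: the
#' upper half the inferior endplate of the vertebra above, the lower half
#' the superior endplate of the vertebra below.
#'
#' @param mask logical 3D disc mask (canonical frame).
#' @param spacing voxel size in mm.
#' @param config settings from [disc_config()].
#' @param level optional disc level name, attached to results and errors.
#' @return A `disc_planes` object: `level`, `mid_plane`, `upper_plane`,
#'   `lower_plane`, `n_upper`, `n_lower`.
#' @export
disc_planes <- function(mask, spacing, config = disc_config(), level = NULL) {
  withCallingHandlers({
    mesh <- extract_mesh(mask, spacing)
    mid <- fit_plane_pca(mesh$vertices)
    halves <- split_disc(mesh, mid, min_vertices = config$min_half_vertices)
    up <- fit_plane_pca(halves$upper)
    lo <- fit_plane_pca(halves$lower)
    structure(list(level = level, mid_plane = mid, upper_plane = up,
                   lower_plane = lo, n_upper = nrow(halves$upper),
                   n_lower = nrow(halves$lower)),
              class = "disc_planes")
  }, error = function(e) {
    if (!is.null(level) && inherits(e, "spinecobb_error") && is.null(e$data$level)) {
      e$data <- c(e$data, list(level = level))
      e$message <- sprintf("[disc %s] %s", level, conditionMessage(e))
      stop(e)
    }
  })
}

#' @export
print.disc_planes <- function(x, ...) {
  cat(sprintf("<disc_planes>%s upper %.2f deg / lower %.2f deg (coronal), %d/%d vertices\n",
              if (is.null(x$level)) "" else paste0(" ", x$level),
              coronal_angle(x$upper_plane), coronal_angle(x$lower_plane),
              x$n_upper, x$n_lower))
  invisible(x)
}
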