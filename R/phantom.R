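#' Synthetic lumbar spine phantom configuration
#'
#' Defines a stack of alternating vertebral bodies and intervertebral discs
#' (elliptic cylinders with planar, tilted end surfaces) whose endplate
#' tilts — and hence every candidate Cobb angle — are known analytically.
#' Each structure's cylinder axis follows the curve (the mean tilt of its two
#' bounding surfaces), so discs are tilted as rigid bodies rather than
#' sheared, as in a real scoliotic spine.
#'
#' @param n_vertebrae number of vertebrae (>= 2).
#' @param endplate_tilts coronal tilt of each disc surface in degrees: an
#'   (n_vertebrae - 1) x 2 matrix with columns `upper`, `lower` (cranial to
#'   caudal), or a vector `upper1, lower1, upper2, ...`. Positive tilt means
#'   the endplate normal leans to the patient's right. Default all zero.
#' @param sagittal_tilt global sagittal tilt in degrees applied to every
#'   surface (and the stacking axis), emulating lumbar lordosis segments.
#' @param vert_lr,vert_ap vertebral body diameters (mm) left-right and
#'   anterior-posterior.
#' @param disc_lr,disc_ap disc diameters (mm).
#' @param body_height,disc_height nominal heights (mm) along SI.
#' @param spacing voxel size mm (S, A, R); the high-resolution acquisition
#'   default is `c(0.90, 0.47, 0.47)`, the standard-resolution alternative
#'   `c(3.29, 0.59, 0.59)`.
#' @param margin empty border around the stack (mm).
#' @param defects optional list of disc-collapse specs, each
#'   `list(level = <disc name or index>, coverage = <fraction in (0, 1]>)`:
#'   the disc's LR extent is shrunk to that fraction of the endplate and
#'   shifted to one side, emulating a one-sided collapsed segmentation.
#' @param endplate_dome doming depth (mm) of the disc surfaces: each disc is
#'   biconvex, bulging into the adjacent vertebra by this amount at its
#'   centre. The dome is symmetric about the disc axis, so the PCA-fitted
#'   endplate plane of a domed surface still carries the configured tilt;
#'   curvature also breaks the coherent voxelization artifacts that
#'   perfectly planar surfaces produce at coarse slice spacing.
#' @param noise_amp boundary jitter amplitude (mm): a smooth seeded random
#'   field added to each interface surface before rasterization.
#' @param noise_cell correlation length of the jitter field (mm).
#' @param seed integer seed for the jitter field.
#' @param id phantom identifier used in tables and reports.
#' @return A `phantom_config`.
#' @export
phantom_config <- function(n_vertebrae = 5L, endplate_tilts = NULL,
                           sagittal_tilt = 0, vert_lr = 46, vert_ap = 32,
                           disc_lr = 46, disc_ap = 32, body_height = 28,
                           disc_height = 10, spacing = c(0.90, 0.47, 0.47),
                           margin = 6, defects = NULL, endplate_dome = 1.5,
                           noise_amp = 0, noise_cell = 6, seed = 1L,
                           id = "phantom") {
  n_vertebrae <- as.integer(n_vertebrae)
  stopifnot(n_vertebrae >= 2L)
  nd <- n_vertebrae - 1L
  if (is.null(endplate_tilts)) endplate_tilts <- matrix(0, nd, 2)
  if (is.null(dim(endplate_tilts)))
    endplate_tilts <- matrix(endplate_tilts, ncol = 2, byrow = TRUE)
  endplate_tilts <- as.matrix(endplate_tilts)
  colnames(endplate_tilts) <- c("upper", "lower")
  if (nrow(endplate_tilts) != nd)
    sc_stop("infeasible_config", "need tilts for %d discs, got %d rows",
            nd, nrow(endplate_tilts))
  if (any(abs(endplate_tilts) >= 45) || abs(sagittal_tilt) >= 45)
    sc_stop("infeasible_config", "tilts must lie within (-45, 45) degrees")
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (!is.null(defects)) {
    if (!is.null(defects$level)) defects <- list(defects) # single spec
    for (d in defects)
      if (is.null(d$coverage) || d$coverage <= 0 || d$coverage > 1)
        sc_stop("infeasible_config", "defect coverage must lie in (0, 1]")
  }
  structure(list(n_vertebrae = n_vertebrae, endplate_tilts = endplate_tilts,
                 sagittal_tilt = sagittal_tilt, vert_lr = vert_lr,
                 vert_ap = vert_ap, disc_lr = disc_lr, disc_ap = disc_ap,
                 body_height = body_height, disc_height = disc_height,
                 spacing = spacing, margin = margin, defects = defects,
                 endplate_dome = endplate_dome,
                 noise_amp = noise_amp, noise_cell = noise_cell,
                 seed = as.integer(seed), id = id),
            class = "phantom_config")
}

# run code under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# interface description shared by the rasterizer and the truth builder:
# interfaces bottom (caudal) to top, structures between consecutive ones
phantom_layout <- function(config) {
  n <- config$n_vertebrae
  nd <- n - 1L
  u <- config$endplate_tilts[, "upper"] # cranial -> caudal disc order
  l <- config$endplate_tilts[, "lower"]
  # structures cranial -> caudal: V1 D1 V2 ... Vn; reversed for stacking
  struct_kind <- rep(c("vert", "disc"), length.out = 2L * n - 1L)
  struct_idx <- rep(seq_len(n), each = 2L)[seq_len(2L * n - 1L)] # V i / D i
  heights <- ifelse(struct_kind == "vert", config$body_height, config$disc_height)
  # internal interface tilts, cranial -> caudal: below V1 is D1 upper, then D1
  # lower, then D2 upper, ... (interface i sits below structure i)
  tilt_cc <- as.vector(rbind(u, l)) # u1 l1 u2 l2 ...
  # reverse to caudal -> cranial stacking order, add flat caps
  tilts <- c(0, rev(tilt_cc), 0)
  heights_bt <- rev(heights)
  z <- config$margin + c(0, cumsum(heights_bt))
  phi <- config$sagittal_tilt * pi / 180
  # axis tilt per structure (bottom -> top): mean of bounding interfaces,
  # with caps inheriting the internal neighbour so end vertebrae stay aligned
  nb <- length(tilts)
  t_axis <- numeric(length(heights_bt))
  for (k in seq_along(t_axis)) {
    lo <- if (k == 1L) tilts[2] else tilts[k]
    hi <- if (k == length(t_axis)) tilts[nb - 1L] else tilts[k + 1L]
    t_axis[k] <- (lo + hi) / 2
  }
  # lateral (R) and sagittal (A) drift of interface centres
  X <- Y <- numeric(nb)
  for (k in seq_along(heights_bt)) {
    dz <- heights_bt[k]
    X[k + 1L] <- X[k] + dz * tan(t_axis[k] * pi / 180)
    Y[k + 1L] <- Y[k] + dz * tan(phi)
  }
  kinds_bt <- rev(struct_kind)
  idx_bt <- rev(struct_idx)
  # disc surfaces dome into the adjacent vertebra: -1 = disc above the
  # interface (bulge down), +1 = disc below (bulge up), 0 = flat end caps
  dome_sign <- c(0, rep(c(-1, 1), n - 1L), 0)
  # headroom so tilted surfaces never cross the volume floor/ceiling
  zpad <- max(abs(tan(tilts * pi / 180))) * max(config$vert_lr, config$disc_lr) / 2 +
    abs(tan(phi)) * max(config$vert_ap, config$disc_ap) / 2 +
    config$endplate_dome
  z <- z + zpad
  list(tilts = tilts, z = z, X = X, Y = Y, t_axis = t_axis,
       kinds = kinds_bt, idx = idx_bt, phi = phi, zpad = zpad,
       dome_sign = dome_sign)
}

#' Analytic ground truth of a phantom
#'
#' @param config a `phantom_config`.
#' @param scheme label scheme (defaults to [default_scheme()] of matching
#'   size).
#' @return A `phantom_truth`: per-disc true endplate angles, the full
#'   candidate matrix, the true maximal Cobb measurement, and the scheme.
#' @export
phantom_truth <- function(config, scheme = default_scheme(config$n_vertebrae)) {
  nd <- config$n_vertebrae - 1L
  discs <- data.frame(level = scheme$discs$name,
                      vert_above = scheme$discs$above,
                      vert_below = scheme$discs$below,
                      upper_coronal = config$endplate_tilts[, "upper"],
                      lower_coronal = config$endplate_tilts[, "lower"],
                      upper_sagittal = rep(config$sagittal_tilt, nd),
                      lower_sagittal = rep(config$sagittal_tilt, nd),
                      stringsAsFactors = FALSE)
  pairs <- which(upper.tri(matrix(0, nd, nd)), arr.ind = TRUE)
  a <- pairs[, 1]; b <- pairs[, 2]
  cand <- if (length(a)) {
    data.frame(top = discs$vert_below[a], bottom = discs$vert_above[b],
               angle = abs(discs$lower_coronal[a] - discs$upper_coronal[b]),
               span = b - a,
               top_source = paste0(discs$level[a], ":lower"),
               bottom_source = paste0(discs$level[b], ":upper"),
               plane_kind = "coronal", disc_a = a, disc_b = b,
               stringsAsFactors = FALSE)
  } else {
    data.frame(top = character(), bottom = character(), angle = numeric(),
               span = integer(), top_source = character(),
               bottom_source = character(), plane_kind = character(),
               disc_a = integer(), disc_b = integer(), stringsAsFactors = FALSE)
  }
  structure(list(id = config$id, discs = discs, candidates = cand,
                 max = if (nrow(cand)) max_cobb(cand) else NULL,
                 scheme = scheme, config = config, voxel_counts = NULL),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s: %d discs, true max Cobb %.2f deg (%s -> %s)\n",
              x$id, nrow(x$discs), x$max$angle, x$max$top, x$max$bottom))
  invisible(x)
}

#' Generate a labeled phantom volume with known ground truth
#'
#' Rasterizes the configured spine onto a voxel grid. Structure labels follow
#' the scheme; the volume is returned in the canonical (S, A, R) frame.
#' Deterministic for a fixed config (the jitter field is seeded).
#'
#' @param config a `phantom_config`.
#' @param scheme label scheme; defaults to a SPIDER-style scheme of matching
#'   size.
#' @return list with `volume` (a `labeled_volume`) and `truth` (a
#'   `phantom_truth` with voxel counts filled in).
#' @export
generate_phantom <- function(config, scheme = default_scheme(config$n_vertebrae)) {
  stopifnot(inherits(config, "phantom_config"))
  lay <- phantom_layout(config)
  sp <- config$spacing
  n_struct <- length(lay$kinds)

  ad <- config$disc_lr / 2; bd <- config$disc_ap / 2
  # interface surface in drift-relative coordinates (no grid offset)
  surf_rel <- function(j, px, py) {
    rho2 <- pmin(1, ((px - lay$X[j]) / ad)^2 + ((py - lay$Y[j]) / bd)^2)
    lay$z[j] - tan(lay$tilts[j] * pi / 180) * (px - lay$X[j]) -
      tan(lay$phi) * (py - lay$Y[j]) +
      lay$dome_sign[j] * config$endplate_dome * (1 - rho2)
  }

  # feasibility: bounding surfaces of every structure must not intersect
  # anywhere over the cross-section (evaluated without jitter)
  for (k in seq_len(n_struct)) {
    a <- (if (lay$kinds[k] == "vert") config$vert_lr else config$disc_lr) / 2
    b <- (if (lay$kinds[k] == "vert") config$vert_ap else config$disc_ap) / 2
    mx <- (lay$X[k] + lay$X[k + 1L]) / 2
    my <- (lay$Y[k] + lay$Y[k + 1L]) / 2
    pts <- rbind(c(mx, my), c(mx + a, my), c(mx - a, my), c(mx, my + b), c(mx, my - b))
    f_lo <- surf_rel(k, pts[, 1], pts[, 2])
    f_up <- surf_rel(k + 1L, pts[, 1], pts[, 2])
    if (min(f_up - f_lo) < max(1, 4 * config$noise_amp))
      sc_stop("infeasible_config",
              "surfaces of structure %d intersect: tilts too large for the %s height",
              k, lay$kinds[k])
  }

  # grid extents
  a_max <- max(config$vert_lr, config$disc_lr) / 2
  b_max <- max(config$vert_ap, config$disc_ap) / 2
  x0 <- config$margin + a_max - min(lay$X) # world R of caudal interface centre
  y0 <- config$margin + b_max - min(lay$Y)
  ext_z <- max(lay$z) + config$margin + lay$zpad
  ext_x <- x0 + max(lay$X) + a_max + config$margin
  ext_y <- y0 + max(lay$Y) + b_max + config$margin
  dims <- as.integer(ceiling(c(ext_z, ext_y, ext_x) / sp)) + 1L
  zs <- (seq_len(dims[1]) - 1) * sp[1]
  ys <- (seq_len(dims[2]) - 1) * sp[2]
  xs <- (seq_len(dims[3]) - 1) * sp[3]
  Xm <- matrix(xs, dims[2], dims[3], byrow = TRUE)
  Ym <- matrix(ys, dims[2], dims[3])

  # seeded smooth jitter per interface: coarse white noise, bilinear interp
  jitter_fields <- NULL
  if (config$noise_amp > 0) {
    jitter_fields <- with_seed(config$seed, {
      cgx <- seq(min(xs) - config$noise_cell, max(xs) + config$noise_cell,
                 by = config$noise_cell)
      cgy <- seq(min(ys) - config$noise_cell, max(ys) + config$noise_cell,
                 by = config$noise_cell)
      lapply(seq_along(lay$z), function(j) {
        coarse <- matrix(stats::rnorm(length(cgy) * length(cgx), 0, config$noise_amp),
                         length(cgy), length(cgx))
        bilinear_grid(coarse, cgy, cgx, ys, xs)
      })
    })
  }
  surface_at <- function(j) {
    f <- surf_rel(j, Xm - x0, Ym - y0)
    if (!is.null(jitter_fields)) f <- f + jitter_fields[[j]]
    f
  }

  defect_for <- function(level_name) {
    if (is.null(config$defects)) return(NULL)
    for (d in config$defects) {
      lv <- d$level
      if (is.numeric(lv)) lv <- scheme$discs$name[lv]
      if (identical(lv, level_name)) return(d)
    }
    NULL
  }

  labels <- array(0L, dim = dims)
  counts <- integer()
  for (k in seq_len(n_struct)) {
    is_vert <- lay$kinds[k] == "vert"
    si <- lay$idx[k]
    if (is_vert) {
      lab <- scheme$vertebrae$label[match(si, seq_len(config$n_vertebrae))]
      name <- scheme$vertebrae$name[si]
      a <- config$vert_lr / 2; b <- config$vert_ap / 2
    } else {
      lab <- scheme$discs$label[si]
      name <- scheme$discs$name[si]
      a <- config$disc_lr / 2; b <- config$disc_ap / 2
    }
    shift <- 0
    if (!is_vert) {
      d <- defect_for(name)
      if (!is.null(d)) {
        a_new <- a * d$coverage
        shift <- -(a - a_new) # collapse toward the patient's left
        a <- a_new
      }
    }
    f_lo <- surface_at(k)
    f_up <- surface_at(k + 1L)
    zr <- range(c(f_lo, f_up))
    kz <- which(zs > zr[1] - sp[1] & zs <= zr[2] + sp[1])
    tax <- tan(lay$t_axis[k] * pi / 180)
    nvox <- 0L
    for (iz in kz) {
      z <- zs[iz]
      cx <- x0 + lay$X[k] + (z - lay$z[k]) * tax + shift
      cy <- y0 + lay$Y[k] + (z - lay$z[k]) * tan(lay$phi)
      mem <- (z > f_lo) & (z <= f_up) &
        (((Xm - cx) / a)^2 + ((Ym - cy) / b)^2 <= 1)
      if (any(mem)) {
        sl <- labels[iz, , ]
        sl[mem] <- lab
        labels[iz, , ] <- sl
        nvox <- nvox + sum(mem)
      }
    }
    counts[[name]] <- nvox
  }

  truth <- phantom_truth(config, scheme)
  truth$voxel_counts <- counts
  list(volume = labeled_volume(labels, sp, source = config$id), truth = truth)
}

# bilinear interpolation of a coarse grid onto fine coordinate vectors
bilinear_grid <- function(coarse, gy, gx, ys, xs) {
  iy <- findInterval(ys, gy, all.inside = TRUE)
  ix <- findInterval(xs, gx, all.inside = TRUE)
  ty <- (ys - gy[iy]) / diff(gy)[iy]
  tx <- (xs - gx[ix]) / diff(gx)[ix]
  f00 <- coarse[iy, ix, drop = FALSE]
  f10 <- coarse[iy + 1L, ix, drop = FALSE]
  f01 <- coarse[iy, ix + 1L, drop = FALSE]
  f11 <- coarse[iy + 1L, ix + 1L, drop = FALSE]
  Ty <- matrix(ty, length(ys), length(xs))
  Tx <- matrix(tx, length(ys), length(xs), byrow = TRUE)
  f00 * (1 - Ty) * (1 - Tx) + f10 * Ty * (1 - Tx) +
    f01 * (1 - Ty) * Tx + f11 * Ty * Tx
}

#' Rigidly rotate a labeled volume
#'
#' Applies a global rotation about the LR or AP axis through the volume
#' centre, resampling labels with nearest-neighbour interpolation. Used to
#' probe the sagittal-tilt invariance of the coronal Cobb angle.
#'
#' @param vol a `labeled_volume`.
#' @param axis `"LR"` (rotation in the sagittal plane) or `"AP"` (coronal).
#' @param degrees rotation angle, |degrees| < 30.
#' @return A rotated `labeled_volume`. Warns when structure voxels are
#'   clipped at the volume boundary.
#' @export
apply_global_rotation <- function(vol, axis = c("LR", "AP"), degrees) {
  axis <- match.arg(axis)
  stopifnot(inherits(vol, "labeled_volume"))
  if (abs(degrees) >= 30)
    sc_stop("infeasible_config", "|degrees| must be < 30")
  if (degrees == 0) return(vol)
  d <- dim(vol$labels); sp <- vol$spacing
  th <- degrees * pi / 180
  # rotation mixes axis pair (p, q); the remaining axis is untouched
  pq <- if (axis == "LR") c(1L, 2L) else c(1L, 3L)
  ep <- (d[pq[1]] - 1) * sp[pq[1]] # physical extents in the rotation plane
  eq <- (d[pq[2]] - 1) * sp[pq[2]]
  # output grid large enough for the rotated bounding box
  np <- as.integer(ceiling((abs(cos(th)) * ep + abs(sin(th)) * eq) / sp[pq[1]])) + 1L
  nq <- as.integer(ceiling((abs(sin(th)) * ep + abs(cos(th)) * eq) / sp[pq[2]])) + 1L
  dn <- d; dn[pq[1]] <- np; dn[pq[2]] <- nq
  tp <- (seq_len(np) - 1) * sp[pq[1]] - (np - 1) * sp[pq[1]] / 2
  tq <- (seq_len(nq) - 1) * sp[pq[2]] - (nq - 1) * sp[pq[2]] / 2
  P <- matrix(tp, np, nq)
  Q <- matrix(tq, np, nq, byrow = TRUE)
  sP <- cos(th) * P + sin(th) * Q # inverse rotation of target coords
  sQ <- -sin(th) * P + cos(th) * Q
  ip <- round((sP + ep / 2) / sp[pq[1]]) + 1L
  iq <- round((sQ + eq / 2) / sp[pq[2]]) + 1L
  ok <- ip >= 1L & ip <= d[pq[1]] & iq >= 1L & iq <= d[pq[2]]
  new <- array(0L, dn)
  if (axis == "LR") {
    # slices along R unchanged
    m <- ifelse(ok, ip + (iq - 1L) * d[1], NA_integer_)
    old2 <- matrix(vol$labels, d[1] * d[2], d[3])
    new2 <- old2[as.vector(m), , drop = FALSE]
    new2[is.na(as.vector(m)), ] <- 0L
    new <- array(new2, dn)
  } else {
    # rotate in (S, R); loop over A slices via matrix indexing
    m_i <- as.vector(ifelse(ok, ip, NA_integer_))
    m_k <- as.vector(ifelse(ok, iq, NA_integer_))
    valid <- !is.na(m_i)
    for (j in seq_len(d[2])) {
      sl <- vol$labels[, j, ]
      out <- integer(np * nq)
      out[valid] <- sl[cbind(m_i[valid], m_k[valid])]
      new[, j, ] <- out
    }
  }
  storage.mode(new) <- "integer"
  lost <- sum(vol$labels > 0L) - sum(new > 0L)
  if (lost > 0.005 * sum(vol$labels > 0L))
    warning(sprintf("rotation clipped %d structure voxels at the volume boundary", lost))
  labeled_volume(new, sp, source = vol$source)
}

#' Simulate reader measurements on a phantom
#'
#' Emulates a panel of readers measuring the Cobb angle: each reader starts
#' from the true maximal-angle levels, perturbs the top and bottom level to
#' an adjacent valid level with a given probability, and reads off the true
#' angle at the chosen levels plus Gaussian noise (floored at 0).
#'
#' @param truth a `phantom_truth`.
#' @param n_readers number of readers (>= 2).
#' @param angle_noise_sd Gaussian measurement noise SD in degrees.
#' @param level_error_prob per-endpoint probability of slipping to an
#'   adjacent level.
#' @param seed integer seed.
#' @return data.frame with columns `case`, `source`, `top`, `bottom`,
#'   `angle`.
#' @export
simulate_readers <- function(truth, n_readers = 3L, angle_noise_sd = 2.5,
                             level_error_prob = 0.2, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"), n_readers >= 2L)
  ord <- scheme_vertebra_order(truth$scheme)
  valid_top <- unique(truth$discs$vert_below)   # vertebrae with a disc above
  valid_bot <- unique(truth$discs$vert_above)   # vertebrae with a disc below
  angle_at <- function(top, bottom) {
    hit <- truth$candidates$top == top & truth$candidates$bottom == bottom
    truth$candidates$angle[hit][1]
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n_readers), function(r) {
      top <- truth$max$top; bottom <- truth$max$bottom
      top <- perturb_level(top, valid_top, ord, level_error_prob,
                           upper_bound = bottom)
      bottom <- perturb_level(bottom, valid_bot, ord, level_error_prob,
                              lower_bound = top)
      data.frame(case = truth$id, source = sprintf("reader%d", r),
                 top = top, bottom = bottom,
                 angle = max(0, angle_at(top, bottom) +
                               stats::rnorm(1, 0, angle_noise_sd)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Sample a random degenerative-scoliosis study phantom
#'
#' Draws a phantom configuration representative of a lumbar degenerative
#' scoliosis study case: a five-vertebra field of view, a C-shaped coronal
#' curve with its maximal Cobb angle between 5 and 40 degrees, mild per-disc
#' wedging (within +/- 2 degrees), a random supine sagittal tilt, and slight
#' boundary roughness. Deterministic per seed.
#'
#' Disc mean tilts follow a two-sided ramp: the most cranial and caudal
#' discs carry the extreme tilts (+/- half the curve magnitude) and the
#' intermediate discs interpolate, so the maximizing endplate pair is the
#' classic end-vertebra pair of the curve.
#'
#' @param seed integer seed.
#' @param spacing voxel spacing, default the high-resolution acquisition.
#' @param ... overrides passed on to [phantom_config()].
#' @return A `phantom_config`.
#' @export
random_study_config <- function(seed, spacing = c(0.90, 0.47, 0.47), ...) {
  with_seed(seed, {
    curve <- stats::runif(1, 6, 38)
    s2 <- stats::runif(1, 0.2, 0.8)
    s3 <- -stats::runif(1, 0.2, 0.8)
    means <- curve / 2 * c(1, s2, s3, -1)
    wedge <- stats::runif(4, -2, 2)
    tilts <- cbind(upper = means - wedge / 2, lower = means + wedge / 2)
    phantom_config(n_vertebrae = 5L, endplate_tilts = tilts,
                   sagittal_tilt = stats::runif(1, -12, 12),
                   vert_lr = 46, vert_ap = 32, disc_lr = 46, disc_ap = 32,
                   spacing = spacing, noise_amp = 0.3, seed = seed,
                   id = sprintf("study-%d", seed), ...)
  })
}

# move a level to an adjacent valid one with probability p, respecting
# the cranio-caudal ordering constraint against the other endpoint
perturb_level <- function(level, valid, ord, p, lower_bound = NULL,
                          upper_bound = NULL) {
  if (stats::runif(1) >= p) return(level)
  vi <- sort(match(valid, ord))
  cur <- match(level, ord)
  nb <- vi[abs(vi - cur) == 1L]
  if (!is.null(lower_bound)) nb <- nb[nb >= match(lower_bound, ord)]
  if (!is.null(upper_bound)) nb <- nb[nb <= match(upper_bound, ord)]
  if (length(nb) == 0L) return(level)
  ord[nb[sample.int(length(nb), 1L)]]
}
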