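test_that("box meshes have the right physical bounding box at both spacings", {
  mask <- array(FALSE, c(14, 14, 8))
  mask[3:12, 3:12, 3:6] <- TRUE # 10 x 10 x 4 voxels
  for (sp in list(c(1, 1, 1), c(0.90, 0.47, 0.47))) {
    mesh <- extract_mesh(mask, sp)
    spans <- apply(mesh$vertices, 2, function(v) diff(range(v)))
    expect_lt(max(abs(spans - c(10, 10, 4) * sp)), max(sp)) # within one voxel
  }
})

test_that("mesh area of a phantom disc is within 10% of the analytic area", {
  cfg <- phantom_config(n_vertebrae = 2L, endplate_dome = 0, id = "flat1")
  ph <- generate_phantom(cfg)
  st <- extract_structure(ph$volume, 201L)
  mesh <- extract_mesh(st$mask, st$spacing)
  a <- cfg$disc_lr / 2; b <- cfg$disc_ap / 2; h <- cfg$disc_height
  perim <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  analytic <- 2 * pi * a * b + perim * h
  expect_lt(abs(mesh_surface_area(mesh) / analytic - 1), 0.10)
})

test_that("degenerate masks raise classed errors", {
  expect_error(extract_mesh(array(FALSE, c(4, 4, 4)), c(1, 1, 1)),
               class = "spinecobb_empty_structure")
  thin <- array(FALSE, c(5, 5, 5)); thin[3, 2:4, 2:4] <- TRUE
  expect_error(extract_mesh(thin, c(1, 1, 1)),
               class = "spinecobb_degenerate_structure")
})

test_that("PCA plane fit recovers exact planes and behaves under noise", {
  set.seed(42)
  g <- as.matrix(expand.grid(S = 0, A = seq(-10, 10, 0.5), R = seq(-15, 15, 0.5)))
  flat <- cbind(S = 7, g[, "A"], g[, "R"])
  pf <- fit_plane_pca(flat)
  expect_equal(unname(pf$normal), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(unname(pf$centroid[1]), 7)

  # plane tilted 10 degrees about the AP axis: normal known analytically
  th <- 10 * pi / 180
  rot <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  tilted <- flat %*% t(rot)
  pt <- fit_plane_pca(tilted)
  true_n <- as.vector(rot %*% c(1, 0, 0))
  expect_lt(acos(min(1, abs(sum(pt$normal * true_n)))), 1e-6) # radians

  # sigma = 0.2 mm jitter: recovered normal within 0.5 degrees
  worst <- 0
  for (i in 1:20) {
    noisy <- tilted + matrix(rnorm(length(tilted), 0, 0.2), ncol = 3)
    pn <- fit_plane_pca(noisy)
    worst <- max(worst, acos(min(1, abs(sum(pn$normal * true_n)))) * 180 / pi)
  }
  expect_lt(worst, 0.5)

  expect_error(fit_plane_pca(flat[1:2, ]), class = "spinecobb_degenerate_fit")
  line <- cbind(seq_len(10), seq_len(10), seq_len(10))
  expect_error(fit_plane_pca(line), class = "spinecobb_degenerate_fit")
})

test_that("PCA fit is invariant to point order, translation, and equivariant under rotation", {
  set.seed(7)
  pts <- cbind(S = rnorm(200, 0, 0.3), A = runif(200, -10, 10), R = runif(200, -14, 14))
  base <- fit_plane_pca(pts)
  perm <- fit_plane_pca(pts[sample(nrow(pts)), ])
  expect_equal(perm$normal, base$normal, tolerance = 1e-12)
  shifted <- fit_plane_pca(sweep(pts, 2, c(5, -3, 11), `+`))
  expect_equal(shifted$normal, base$normal, tolerance = 1e-9)
  expect_equal(unname(shifted$centroid - base$centroid), c(5, -3, 11), tolerance = 1e-9)

  th <- 23 * pi / 180
  rot <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  rotated <- fit_plane_pca(pts %*% t(rot))
  expected <- as.vector(rot %*% base$normal)
  expect_lt(min(sum((rotated$normal - expected)^2),
                sum((rotated$normal + expected)^2)), 1e-16)
})

test_that("splitting a symmetric mesh gives equal halves; empty halves error", {
  mask <- array(FALSE, c(16, 16, 16)); mask[4:13, 4:13, 4:13] <- TRUE
  mesh <- extract_mesh(mask, c(1, 1, 1))
  mid <- fit_plane_pca(mesh$vertices)
  halves <- split_disc(mesh, mid)
  total <- nrow(mesh$vertices)
  expect_equal(nrow(halves$upper) + nrow(halves$lower), total)
  expect_lt(abs(nrow(halves$upper) - nrow(halves$lower)), 0.01 * total)

  below <- plane(c(1, 0, 0), c(-100, 0, 0)) # all vertices strictly above
  expect_error(split_disc(mesh, below), class = "spinecobb_degenerate_disc")
})

test_that("half-plane fits recover mildly wedged discs within 1 degree", {
  dp <- single_disc(8, 5)
  expect_lt(abs(coronal_angle(dp$upper_plane) - 8), 1)
  expect_lt(abs(coronal_angle(dp$lower_plane) - 5), 1)
  # upper centroid is superior to the lower centroid
  expect_gt(dp$upper_plane$centroid[1], dp$lower_plane$centroid[1])

  flat <- single_disc(0, 0)
  expect_lt(abs(coronal_angle(flat$upper_plane)), 0.5)
  expect_lt(abs(coronal_angle(flat$lower_plane)), 0.5)
})

test_that("strongly wedged discs pull both half-planes toward the mean tilt", {
  # known limitation of half-disc plane fitting: the lateral annulus surface
  # follows the mean disc orientation, so each half-plane is attenuated
  # toward it, roughly a quarter of the wedge angle per endplate
  dp <- single_disc(8, -3) # 11-degree wedge, mean 2.5
  up <- coronal_angle(dp$upper_plane)
  lo <- coronal_angle(dp$lower_plane)
  expect_lt(up, 8); expect_gt(up, 2.5)
  expect_gt(lo, -3); expect_lt(lo, 2.5)
  expect_lt(abs(up - 8), 0.35 * 11)
  expect_lt(abs(lo + 3), 0.35 * 11)
})

test_that("plane fits agree across acquisition resolutions", {
  for (tilts in list(c(10, 10), c(-6, -8))) {
    hi <- single_disc(tilts[1], tilts[2], spacing = hi_spacing)
    std <- single_disc(tilts[1], tilts[2], spacing = std_spacing)
    expect_lt(abs(coronal_angle(hi$upper_plane) - coronal_angle(std$upper_plane)), 2)
    expect_lt(abs(coronal_angle(hi$lower_plane) - coronal_angle(std$lower_plane)), 2)
  }
})

test_that("meshes export as readable PLY", {
  mask <- array(FALSE, c(6, 6, 6)); mask[2:5, 2:5, 2:5] <- TRUE
  mesh <- extract_mesh(mask, c(1, 1, 1))
  f <- tempfile(fileext = ".ply")
  write_ply(mesh, f)
  lines <- readLines(f)
  expect_equal(lines[1], "ply")
  expect_equal(sum(grepl("^element", lines)), 2)
  nv <- as.integer(sub("element vertex ", "", lines[grepl("element vertex", lines)]))
  expect_equal(nv, nrow(mesh$vertices))
})
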