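test_that("projected angles follow the documented conventions", {
  up <- plane(c(1, 0, 0), c(0, 0, 0))
  expect_equal(coronal_angle(up), 0)
  expect_equal(sagittal_angle(up), 0)

  # SI axis rotated 10 degrees about the AP axis leans right: +10
  th <- 10 * pi / 180
  tilted <- plane(c(cos(th), 0, sin(th)), c(0, 0, 0))
  expect_equal(coronal_angle(tilted), 10, tolerance = 1e-9)
  expect_equal(sagittal_angle(tilted), 0, tolerance = 1e-9)

  # a pure 20-degree sagittal tilt leaves the coronal angle at 0
  ph <- 20 * pi / 180
  sagittal <- plane(c(cos(ph), sin(ph), 0), c(0, 0, 0))
  expect_equal(coronal_angle(sagittal), 0, tolerance = 1e-9)
  expect_equal(sagittal_angle(sagittal), 20, tolerance = 1e-9)
  pure15 <- plane(c(cos(15 * pi / 180), sin(15 * pi / 180), 0), c(0, 0, 0))
  expect_equal(sagittal_angle(pure15), 15, tolerance = 1e-9)

  # pure AP normal has no coronal projection
  expect_error(coronal_angle(plane(c(0, 1, 0), c(0, 0, 0))),
               class = "spinecobb_undefined_angle")
})

test_that("angle tables match phantom truth and reject interleaved discs", {
  ph <- curved_phantom()
  res <- measure_volume(ph$volume, ph$truth$scheme)
  tab <- res$table
  expect_s3_class(tab, "endplate_angle_table")
  expect_equal(tab$level, ph$truth$discs$level)
  expect_lt(max(abs(tab$upper_coronal - ph$truth$discs$upper_coronal)), 1)
  expect_lt(max(abs(tab$lower_coronal - ph$truth$discs$lower_coronal)), 1)
  expect_true(all(diff(tab$mid_s) < 0)) # strictly cranial -> caudal
  expect_true(all(abs(tab$upper_coronal) < 90) && all(abs(tab$lower_coronal) < 90))

  # flat phantom: all coronal angles near zero
  fl <- flat_phantom()
  tf <- measure_volume(fl$volume, fl$truth$scheme)$table
  expect_lt(max(abs(tf$upper_coronal)), 0.5)
  expect_lt(max(abs(tf$lower_coronal)), 0.5)

  # interleaved SI extents are refused
  sch <- ph$truth$scheme
  st1 <- extract_structure(ph$volume, 204L)
  d1 <- disc_planes(st1$mask, st1$spacing, level = "L1-L2")
  d2 <- d1; d2$level <- "L2-L3" # same geometry claimed one level lower
  expect_error(build_angle_table(list(d1, d2), sch), class = "spinecobb_ordering")
})

test_that("candidate enumeration has n(n-1)/2 rows with correct arithmetic", {
  set.seed(11)
  for (n in c(2, 4, 6)) {
    tab <- random_angle_table(n)
    cand <- candidate_angles(tab)
    expect_equal(nrow(cand), n * (n - 1) / 2)
    # every pair's angle is |lower(a) - upper(b)|
    for (r in seq_len(nrow(cand))) {
      a <- cand$disc_a[r]; b <- cand$disc_b[r]
      expect_equal(cand$angle[r], abs(tab$lower_coronal[a] - tab$upper_coronal[b]))
      expect_equal(cand$top[r], tab$vert_below[a])
      expect_equal(cand$bottom[r], tab$vert_above[b])
    }
  }
  # worked example: lower(a) = +7, upper(b) = -8 gives 15
  tab <- random_angle_table(2)
  tab$lower_coronal[1] <- 7; tab$upper_coronal[2] <- -8
  expect_equal(candidate_angles(tab)$angle, 15)

  # min_span filters single-vertebra candidates
  tab4 <- random_angle_table(4)
  expect_true(all(candidate_angles(tab4, min_span = 2)$span >= 2))
})

test_that("max_cobb equals an independent brute-force enumeration exactly", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:7, 1)
    tab <- random_angle_table(n)
    got <- max_cobb(candidate_angles(tab))
    # independent oracle: explicit double loop over disc pairs
    best <- -Inf; best_pair <- NULL
    for (a in seq_len(n - 1)) for (b in seq((a + 1), n)) {
      ang <- abs(tab$lower_coronal[a] - tab$upper_coronal[b])
      if (ang > best) { best <- ang; best_pair <- c(a, b) }
    }
    expect_identical(got$angle, best)
    expect_identical(got$top, tab$vert_below[best_pair[1]])
    expect_identical(got$bottom, tab$vert_above[best_pair[2]])
  }
})

test_that("max_cobb ties break toward larger span, then more cranial top", {
  tab <- random_angle_table(4)
  tab$lower_coronal <- c(10, 10, 0, 0)
  tab$upper_coronal <- c(0, 0, -10, -10)
  cand <- candidate_angles(tab)
  # pairs (1,3), (1,4), (2,3), (2,4) all give 20
  got <- max_cobb(cand)
  expect_equal(got$angle, 20)
  expect_equal(got$top_source, "L1-L2:lower") # span 3, most cranial
  expect_equal(got$bottom_source, "L4-L5:upper")
})

test_that("cobb_at_levels is consistent with and dominated by max_cobb", {
  ph <- curved_phantom()
  res <- measure_volume(ph$volume, ph$truth$scheme)
  m <- res$max
  same <- cobb_at_levels(res$table, m$top, m$bottom)
  expect_equal(same$angle, m$angle)

  verts <- ph$truth$scheme$vertebrae$name
  for (i in 2:4) for (j in i:4) { # all measurable pairs
    v <- cobb_at_levels(res$table, verts[i], verts[j])
    expect_lte(v$angle, m$angle + 1e-12)
  }
  # analytic check at a non-apex pair
  v23 <- cobb_at_levels(res$table, "L3", "L3")
  truth <- abs(ph$truth$discs$lower_coronal[2] - ph$truth$discs$upper_coronal[3])
  expect_lt(abs(v23$angle - truth), 1)

  expect_error(cobb_at_levels(res$table, "L1", "L4"),
               class = "spinecobb_unavailable_level")
  expect_error(cobb_at_levels(res$table, "L4", "L2"),
               class = "spinecobb_unavailable_level")
})

test_that("a single-disc field of view yields a table but no Cobb candidates", {
  cfg <- phantom_config(n_vertebrae = 2L, endplate_tilts = rbind(c(6, 4)),
                        spacing = std_spacing, id = "one-disc")
  ph <- generate_phantom(cfg)
  expect_warning(res <- measure_volume(ph$volume, ph$truth$scheme),
                 "one disc")
  expect_equal(nrow(res$table), 1)
  expect_null(res$max)
  expect_error(candidate_angles(res$table), class = "spinecobb_no_measurement")
})

test_that("left-right mirroring negates coronal angles but keeps Cobb magnitudes", {
  ph <- curved_phantom()
  res <- measure_volume(ph$volume, ph$truth$scheme)
  mir <- ph$volume
  mir$labels <- mir$labels[, , rev(seq_len(dim(mir$labels)[3])), drop = FALSE]
  resm <- measure_volume(labeled_volume(mir$labels, mir$spacing), ph$truth$scheme)
  expect_equal(resm$table$upper_coronal, -res$table$upper_coronal, tolerance = 0.05)
  expect_equal(resm$table$lower_coronal, -res$table$lower_coronal, tolerance = 0.05)
  expect_equal(sort(resm$candidates$angle), sort(res$candidates$angle), tolerance = 0.1)
  expect_equal(resm$max$angle, res$max$angle, tolerance = 0.1)
})

test_that("measurement reports serialize with a stable schema", {
  ph <- curved_phantom()
  res <- measure_volume(ph$volume, ph$truth$scheme, plane_kind = "both")
  f <- tempfile(fileext = ".json")
  write_measurement_report(res, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$schema, "spinecobb/measurement/1")
  expect_true(j$qc$pass)
  expect_equal(length(j$angle_table), 4)
  expect_equal(j$max$top, res$max$top)
  expect_equal(j$max$angle_deg, res$max$angle, tolerance = 1e-9)
  expect_false(is.null(j$max_sagittal))
})
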