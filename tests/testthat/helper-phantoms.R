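# Shared phantom fixtures, generated once per session.
# Most tests run at the standard acquisition resolution (3.29 x 0.59 x 0.59
# mm) to keep volumes small; geometry-accuracy tests use the high-resolution
# spacing where the measurement contract demands it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

std_spacing <- c(3.29, 0.59, 0.59)
hi_spacing <- c(0.90, 0.47, 0.47)

# gentle 4-disc curve at the high-resolution spacing: the workhorse fixture
# (geometry assertions at the 1-degree level need the fine slice spacing)
curved_phantom <- function() cached("curved", {
  cfg <- phantom_config(endplate_tilts = cbind(c(8, 3, -3, -8), c(8, 3, -3, -8)),
                        spacing = hi_spacing, id = "curved")
  generate_phantom(cfg)
})

# same curve at the standard (coarse) spacing: small and fast, for IO/QC tests
std_curved_phantom <- function() cached("std_curved", {
  cfg <- phantom_config(endplate_tilts = cbind(c(8, 3, -3, -8), c(8, 3, -3, -8)),
                        spacing = std_spacing, id = "std_curved")
  generate_phantom(cfg)
})

flat_phantom <- function() cached("flat", {
  generate_phantom(phantom_config(spacing = std_spacing, id = "flat"))
})

# one isolated disc with the given endplate tilts
single_disc <- function(upper, lower, spacing = hi_spacing, ...) {
  cfg <- phantom_config(n_vertebrae = 2L, endplate_tilts = rbind(c(upper, lower)),
                        spacing = spacing, ...)
  ph <- generate_phantom(cfg)
  st <- extract_structure(ph$volume, 201L)
  disc_planes(st$mask, st$spacing, level = "L4-L5")
}

# random angle table (no geometry) for combinatorial oracles
random_angle_table <- function(n_discs, scheme = default_scheme(n_discs + 1L)) {
  tab <- data.frame(level = scheme$discs$name,
                    vert_above = scheme$discs$above,
                    vert_below = scheme$discs$below,
                    upper_coronal = runif(n_discs, -20, 20),
                    lower_coronal = runif(n_discs, -20, 20),
                    upper_sagittal = runif(n_discs, -20, 20),
                    lower_sagittal = runif(n_discs, -20, 20),
                    mid_s = seq(n_discs, 1), upper_s = seq(n_discs, 1) + 0.4,
                    upper_r = 0, lower_s = seq(n_discs, 1) - 0.4, lower_r = 0,
                    n_upper = 100L, n_lower = 100L,
                    stringsAsFactors = FALSE)
  class(tab) <- c("endplate_angle_table", "data.frame")
  tab
}
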