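test_that("phantom spec validates masses, grid and density", {
  expect_error(phantom_spec(body_weight_g = -1), "body_weight_g")
  expect_error(phantom_spec(organ_masses_g = c(liver = -1)), "positive")
  expect_error(phantom_spec(organ_masses_g = c(liver = 30)), "exceed")
  sp <- phantom_spec()
  expect_equal(sp$grid, c(160L, 160L, 440L))
})

test_that("built phantom achieves region masses and conserves total mass", {
  ph <- small_phantom()
  rt <- ph$region_table
  organs <- rt[rt$region != "body", ]
  expect_true(all(abs(organs$achieved_mass_g / organs$target_mass_g - 1) <= 0.05))
  # voxel-count bookkeeping reproduces achieved masses exactly
  vol <- ph$voxel_size_mm^3 * ph$density_g_cm3 / 1000
  cnt <- tabulate(ph$labels[ph$labels > 0], nbins = max(rt$id))
  expect_equal(cnt[rt$id] * vol, rt$achieved_mass_g)
  # total within 1 % of body weight + tumour
  spec <- ph$provenance
  expect_equal(sum(rt$achieved_mass_g), spec$body_weight_g + spec$tumor_mass_g,
               tolerance = 0.01)
})

test_that("voxelisation is deterministic", {
  sp <- phantom_spec(grid = c(60L, 60L, 160L), voxel_size_mm = 0.6)
  p1 <- build_phantom(sp)
  p2 <- build_phantom(sp)
  expect_identical(p1$labels, p2$labels)
})

test_that("tumour is a 1:2:2 ellipsoid attached outside the body on the +x flank", {
  ph <- small_phantom()
  rt <- ph$region_table
  tum_id <- rt$id[rt$region == "tumor"]
  body_id <- rt$id[rt$region == "body"]
  w <- which(ph$labels == tum_id, arr.ind = TRUE)
  ext <- apply(w, 2, function(i) diff(range(i)) + 1) * ph$voxel_size_mm
  # short axis along x, half the two long axes
  expect_equal(unname(ext[2] / ext[1]), 2, tolerance = 0.15)
  expect_equal(unname(ext[3] / ext[1]), 2, tolerance = 0.15)
  # semi-axis a from the mass: (4/3) pi (a)(2a)(2a) = V => a = (3V/16pi)^(1/3)
  V <- rt$achieved_mass_g[rt$region == "tumor"] * 1000
  a <- (3 * V / (16 * pi))^(1/3)
  expect_equal(unname(ext[1] / 2), a, tolerance = 0.15)
  expect_equal(a, 3.10, tolerance = 0.02)   # 0.5 g at unit density
  # strictly to the right of every body voxel centroid, outside the contour
  wb <- which(ph$labels == body_id, arr.ind = TRUE)
  expect_gt(mean(w[, 1]), max(wb[, 1]) - max(ext) / ph$voxel_size_mm)
  expect_gt(mean(w[, 1]), mean(wb[, 1]))
})

test_that("submandibular gland is a sphere with radius from its mass", {
  ph <- small_phantom()
  rt <- ph$region_table
  id <- rt$id[rt$region == "submandibular"]
  w <- which(ph$labels == id, arr.ind = TRUE)
  ext <- apply(w, 2, function(i) diff(range(i)) + 1) * ph$voxel_size_mm
  m <- rt$achieved_mass_g[rt$region == "submandibular"]
  r <- (3 * m * 1000 / (4 * pi))^(1/3)
  expect_equal(r, 2.88, tolerance = 0.05)   # 0.1 g at unit density
  expect_true(all(abs(ext / (2 * r) - 1) < 0.2))
  expect_lt(stats::sd(ext), 0.75)           # near-spherical extents
})

test_that("achieved masses are resolution-independent within quantisation", {
  fine <- build_phantom(phantom_spec(grid = c(100L, 100L, 280L), voxel_size_mm = 0.4))
  coarse <- build_phantom(phantom_spec(grid = c(50L, 50L, 140L), voxel_size_mm = 0.8))
  mf <- region_masses(fine); mc <- region_masses(coarse)
  org <- setdiff(names(mf), "body")
  expect_true(all(abs(mc[org] / mf[org] - 1) < 0.1))
})

test_that("too-small regions raise a resolution error", {
  expect_error(build_phantom(phantom_spec(
    organ_masses_g = c(liver = 1.3, speck = 0.0005),
    grid = c(40L, 40L, 110L), voxel_size_mm = 1)), "resolution")
})

test_that("centroid distances are a metric diagnostic", {
  ph <- small_phantom()
  d <- region_centroid_distances(ph)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  expect_true(all(d[upper.tri(d)] > 0))
  # grid arithmetic on a hand-built phantom: two voxels 10 apart at 0.5 mm
  toy <- structure(list(
    labels = {
      a <- array(0L, c(20L, 4L, 4L)); a[3, 2, 2] <- 1L; a[13, 2, 2] <- 2L; a
    },
    region_table = data.frame(id = 1:2, region = c("p", "q"),
                              target_mass_g = 1, achieved_mass_g = 1),
    voxel_size_mm = 0.5, density_g_cm3 = 1, provenance = NULL),
    class = "voxel_phantom")
  expect_equal(region_centroid_distances(toy)["p", "q"], 5)
})

test_that("phantom export round-trips through binary + JSON sidecar", {
  ph <- build_phantom(phantom_spec(grid = c(40L, 40L, 110L), voxel_size_mm = 1))
  base <- tempfile()
  write_phantom(ph, base)
  back <- read_phantom(base)
  expect_identical(back$labels, ph$labels)
  expect_equal(back$region_table$achieved_mass_g, ph$region_table$achieved_mass_g)
  expect_equal(back$voxel_size_mm, ph$voxel_size_mm)
})
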