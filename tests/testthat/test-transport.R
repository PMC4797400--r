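nuc <- nuclide_data()

test_that("electron self-irradiation of a large region reaches equilibrium", {
  cube <- water_cube(100, 2)   # 100 mm water cube >> 2 mm beta range
  s <- simulate_s_factors(cube, nuc, n_histories = 2e4, seed = 1,
                          include_photons = FALSE)
  self_kev <- s$s["water", "water"] * s$masses_g[["water"]] / 1.602176634e-13
  expect_equal(self_kev, nuc$mean_beta_energy_kev, tolerance = 0.02)
})

test_that("simulation is deterministic for a fixed seed and config errors are caught", {
  cube <- water_cube(40, 2)
  s1 <- simulate_s_factors(cube, nuc, n_histories = 2000, seed = 9)
  s2 <- simulate_s_factors(cube, nuc, n_histories = 2000, seed = 9)
  expect_identical(s1$s, s2$s)
  s3 <- simulate_s_factors(cube, nuc, n_histories = 2000, seed = 10)
  expect_false(identical(s1$s, s3$s))
  expect_error(simulate_s_factors(cube, nuc, n_histories = 10, seed = 1), "1000")
  expect_error(simulate_s_factors(cube, nuc, n_histories = 2000, seed = 1,
                                  cutoff_kev = 0.5), "cutoff")
  expect_error(simulate_s_factors(cube, nuc, n_histories = 2000, seed = 1,
                                  cutoff_kev = 500), "cutoff")
  expect_error(simulate_s_factors(cube, nuc, n_histories = 2000), "seed")
})

test_that("Monte Carlo uncertainty scales as 1/sqrt(N)", {
  ph <- two_block_phantom(block_mm = 20, gap_mm = 20, voxel_mm = 2,
                          lateral_mm = 60)
  sN <- simulate_s_factors(ph, nuc, n_histories = 5000, seed = 4,
                           sources = "a", n_batches = 50)
  s4N <- simulate_s_factors(ph, nuc, n_histories = 20000, seed = 4,
                            sources = "a", n_batches = 50)
  ratio <- sN$rel_unc["b", "a"] / s4N$rel_unc["b", "a"]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
})

test_that("photon cross-dose over 10+ cm of water is attenuated away", {
  # 208 keV photons only, two 10 mm blocks separated by 160 mm of water
  mono <- custom_nuclide(lines = data.frame(energy_kev = 208.37, intensity = 1))
  ph <- two_block_phantom(block_mm = 10, gap_mm = 160, voxel_mm = 2,
                          lateral_mm = 50)
  s <- simulate_s_factors(ph, mono, n_histories = 3e4, seed = 5,
                          include_electrons = FALSE, sources = "a")
  expect_lt(s$s["b", "a"], 1e-3 * s$s["a", "a"])
})

test_that("energy is conserved: deposited never exceeds emitted", {
  ph <- small_phantom()
  s <- simulate_s_factors(ph, nuc, n_histories = 5000, seed = 6)
  expect_true(all(s$energy$deposited_kev <= s$energy$emitted_kev * (1 + 1e-12)))
  # mass-weighted dose totals stay below the mean energy per decay
  m <- s$masses_g[rownames(s$s)]
  tot_kev <- colSums(s$s * m) / 1.602176634e-13
  expect_true(all(tot_kev <= nuc$mean_energy_per_decay_kev))
  # and every self S-factor is positive
  rn <- intersect(rownames(s$s), colnames(s$s))
  expect_true(all(diag(s$s[rn, rn]) > 0))
})

test_that("photon transport obeys reciprocity between equal distant regions", {
  mono <- custom_nuclide(lines = data.frame(energy_kev = 208.37, intensity = 1))
  ph <- two_block_phantom(block_mm = 16, gap_mm = 30, voxel_mm = 2,
                          lateral_mm = 60)
  s <- simulate_s_factors(ph, mono, n_histories = 4e4, seed = 8,
                          include_electrons = FALSE, sources = c("a", "b"))
  m <- s$masses_g
  lhs <- m[["b"]] * s$s["b", "a"]
  rhs <- m[["a"]] * s$s["a", "b"]
  sig <- sqrt((lhs * s$rel_unc["b", "a"])^2 + (rhs * s$rel_unc["a", "b"])^2)
  expect_lt(abs(lhs - rhs), 3 * sig)
})

test_that("self/cross split sums sources and keeps self <= total", {
  s <- matrix(c(1e-9, 2e-10, 1e-10, 8e-10), 2, 2,
              dimnames = list(target = c("x", "y"), source = c("x", "y")))
  sv <- split_self_vs_cross(s, c(x = 1e9, y = 2e9))
  expect_equal(sv$total_gy_per_mbq[sv$region == "x"], 1e9 * 1e-9 + 2e9 * 1e-10)
  expect_equal(sv$self_gy_per_mbq[sv$region == "x"], 1e9 * 1e-9)
  expect_true(all(sv$self_gy_per_mbq <= sv$total_gy_per_mbq))
  # single-source system: self equals total for that source
  sv1 <- split_self_vs_cross(s, c(x = 1e9, y = 0))
  expect_equal(sv1$self_gy_per_mbq[sv1$region == "x"],
               sv1$total_gy_per_mbq[sv1$region == "x"])
  # zero activity everywhere gives zero dose
  sv0 <- split_self_vs_cross(s, c(x = 0, y = 0))
  expect_true(all(sv0$total_gy_per_mbq == 0))
  expect_error(split_self_vs_cross(s, c(z = 1)), "mismatch")
})

test_that("S-matrix CSV round-trips and serves as an import path", {
  ph <- water_cube(40, 2)
  s <- simulate_s_factors(ph, nuc, n_histories = 2000, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_s_matrix_csv(s, path)
  back <- read_s_matrix_csv(path)
  expect_equal(back$s, s$s, tolerance = 1e-12)
  expect_error(read_s_matrix_csv({
    p <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p, row.names = FALSE); p
  }), "columns")
})
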