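# shared fixtures: built in code, no stored binaries

# single-region water cube (edge_mm per side), used for electron-equilibrium
# and photon checks
water_cube <- function(edge_mm = 100, voxel_mm = 2) {
  n <- as.integer(round(edge_mm / voxel_mm))
  dims <- c(n, n, n)
  mass <- prod(dims) * voxel_mm^3 / 1000  # g at unit density
  structure(list(
    labels = array(1L, dims),
    region_table = data.frame(id = 1L, region = "water",
                              target_mass_g = mass, achieved_mass_g = mass),
    voxel_size_mm = voxel_mm, density_g_cm3 = 1, provenance = NULL),
    class = "voxel_phantom")
}

# two equal cubes of water embedded in a water column, separated along z by
# `gap_mm` of medium; used for attenuation and reciprocity checks
two_block_phantom <- function(block_mm = 10, gap_mm = 120, voxel_mm = 2,
                              lateral_mm = 50) {
  nb <- as.integer(block_mm / voxel_mm)
  ngap <- as.integer(gap_mm / voxel_mm)
  nxy <- as.integer(lateral_mm / voxel_mm)
  nz <- 2L * nb + ngap
  labels <- array(3L, c(nxy, nxy, nz))          # region 3: surrounding medium
  mid <- as.integer(nxy / 2)
  sel <- (mid - nb %/% 2 + 1L):(mid + (nb - nb %/% 2))
  labels[sel, sel, 1:nb] <- 1L
  labels[sel, sel, (nb + ngap + 1L):nz] <- 2L
  vol <- voxel_mm^3 / 1000
  cnt <- c(sum(labels == 1L), sum(labels == 2L), sum(labels == 3L))
  structure(list(
    labels = labels,
    region_table = data.frame(id = 1:3, region = c("a", "b", "medium"),
                              target_mass_g = cnt * vol,
                              achieved_mass_g = cnt * vol),
    voxel_size_mm = voxel_mm, density_g_cm3 = 1, provenance = NULL),
    class = "voxel_phantom")
}

# nuclide with a custom beta spectrum / photon line set, written to temp CSVs
custom_nuclide <- function(spectrum = NULL, lines = NULL, half_life_days = 6.647) {
  sf <- lf <- NULL
  if (!is.null(spectrum)) {
    sf <- tempfile(fileext = ".csv")
    utils::write.csv(spectrum, sf, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(lines)) {
    lf <- tempfile(fileext = ".csv")
    utils::write.csv(lines, lf, row.names = FALSE, quote = FALSE)
  }
  nuclide_data(half_life_days, spectrum_file = sf, lines_file = lf)
}

# small mouse phantom reused across tests (built once per test run)
small_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph))
      ph <<- build_phantom(phantom_spec(grid = c(80L, 80L, 220L),
                                        voxel_size_mm = 0.5))
    ph
  }
})

# hand-rolled product-limit estimator: independent oracle for survfit-based
# kaplan_meier()
product_limit_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}
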