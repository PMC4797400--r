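#' Nuclide decay data for the transport engine
#'
#' Loads the physical decay data used throughout the pipeline: half-life,
#' a tabulated beta spectrum (1-keV bins, probability density per keV), and
#' discrete photon lines. The package ships Lu-177 data assembled from a
#' standard decay-data compilation (half-life 6.647 d; beta branches with
#' endpoints near 176, 249 and 498 keV; gamma lines at 112.95 keV, 6.2 %,
#' and 208.37 keV, 10.4 %, plus minor lines). Other nuclides can be supplied
#' by pointing `spectrum_file` / `lines_file` at CSVs with the same columns.
#'
#' @param half_life_days physical half-life in days.
#' @param spectrum_file CSV with columns `energy_kev`, `density_per_kev`
#'   (bin midpoints on a uniform grid). Defaults to the bundled Lu-177 table.
#' @param lines_file CSV with columns `energy_kev`, `intensity` (photons per
#'   decay). Defaults to the bundled Lu-177 table.
#' @return An object of class `nuclide_data` with elements `half_life_days`,
#'   `beta_spectrum`, `photon_lines`, `beta_yield`, `mean_beta_energy_kev`,
#'   `mean_photon_energy_kev` and `mean_energy_per_decay_kev`.
#' @examples
#' nuc <- nuclide_data()
#' nuc$mean_energy_per_decay_kev
#' @export
nuclide_data <- function(half_life_days = 6.647,
                         spectrum_file = NULL,
                         lines_file = NULL) {
  if (!is.numeric(half_life_days) || half_life_days <= 0)
    stop("half_life_days must be a positive number")
  if (is.null(spectrum_file))
    spectrum_file <- system.file("extdata", "lu177_beta_spectrum.csv",
                                 package = "mousedose", mustWork = TRUE)
  if (is.null(lines_file))
    lines_file <- system.file("extdata", "lu177_photon_lines.csv",
                              package = "mousedose", mustWork = TRUE)
  sp <- utils::read.csv(spectrum_file)
  stopifnot(all(c("energy_kev", "density_per_kev") %in% names(sp)))
  ln <- utils::read.csv(lines_file)
  stopifnot(all(c("energy_kev", "intensity") %in% names(ln)))
  if (any(sp$energy_kev <= 0) || any(sp$density_per_kev < 0))
    stop("beta spectrum energies must be positive and densities non-negative")
  if (any(ln$energy_kev <= 0) || any(ln$intensity <= 0))
    stop("photon line energies and intensities must be positive")

  de <- diff(sp$energy_kev)
  bin_w <- if (length(de)) stats::median(de) else 1
  yield <- sum(sp$density_per_kev) * bin_w
  mean_beta <- sum(sp$energy_kev * sp$density_per_kev) * bin_w / yield
  mean_photon <- sum(ln$energy_kev * ln$intensity)

  structure(list(
    half_life_days = half_life_days,
    beta_spectrum = sp,
    bin_width_kev = bin_w,
    photon_lines = ln,
    beta_yield = yield,
    mean_beta_energy_kev = mean_beta,
    mean_photon_energy_kev = mean_photon,
    mean_energy_per_decay_kev = yield * mean_beta + mean_photon
  ), class = "nuclide_data")
}

#' @export
print.nuclide_data <- function(x, ...) {
  cat(sprintf("<nuclide_data> T1/2 = %.4g d, beta yield %.4f, mean beta %.1f keV, %d photon lines, <E>/decay %.1f keV\n",
              x$half_life_days, x$beta_yield, x$mean_beta_energy_kev,
              nrow(x$photon_lines), x$mean_energy_per_decay_kev))
  invisible(x)
}

#' Physical decay constant
#'
#' lambda_phys = ln(2) / T1/2, in inverse hours, as used in the
#' decay-corrected cumulated-activity integral.
#'
#' @param nuclide a `nuclide_data` object, or a bare half-life in days.
#' @return decay constant per hour.
#' @examples
#' physical_decay_constant(nuclide_data())  # ~4.35e-3 / h for Lu-177
#' @export
physical_decay_constant <- function(nuclide = nuclide_data()) {
  hl_days <- if (inherits(nuclide, "nuclide_data")) nuclide$half_life_days else nuclide
  if (!is.numeric(hl_days) || hl_days <= 0) stop("half-life must be positive")
  log(2) / (hl_days * 24)
}

#' Sample electron energies from the tabulated beta spectrum
#'
#' Inverse-CDF sampling of the binned spectrum (uniform within a bin).
#' A seed is mandatory so that every Monte Carlo draw is reproducible.
#'
#' @param nuclide a `nuclide_data` object.
#' @param n number of draws.
#' @param seed integer seed; omitting it is an error, not a fallback to the
#'   global RNG state.
#' @return numeric vector of energies in keV, in (0, E_max].
#' @export
sample_beta_energy <- function(nuclide, n, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is required: unseeded sampling would not be reproducible")
  stopifnot(inherits(nuclide, "nuclide_data"), n >= 1)
  sp <- nuclide$beta_spectrum
  w <- nuclide$bin_width_kev
  p <- sp$density_per_kev * w
  cdf <- cumsum(p) / sum(p)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  u <- stats::runif(n)
  idx <- findInterval(u, cdf) + 1L
  idx[idx > nrow(sp)] <- nrow(sp)
  lo <- sp$energy_kev[idx] - w / 2
  # uniform within the selected bin
  lo + stats::runif(n) * w
}

# save/restore of the global RNG state so seeded helpers do not clobber
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
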