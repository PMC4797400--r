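# Builds the 1-keV-binned Lu-177 beta spectrum table shipped in
# inst/extdata/lu177_beta_spectrum.csv.
#
# Branch endpoints and intensities follow a standard decay-data compilation
# (ENSDF-style values): endpoints ~176.5, 248.6 and 497.8 keV. Each branch is
# given the allowed spectral shape
#     n(E) dE  ~  F(Z, E) * p * W * (W0 - W)^2 dE
# with W total energy in electron-mass units, p momentum, and F the
# non-relativistic Fermi function F = 2*pi*eta / (1 - exp(-2*pi*eta)),
# eta = +alpha * Z * W / p for beta-minus (daughter Z = 72, Hf-177).
# The summed spectrum is normalised to unit yield per decay. Sub-5-keV
# conversion/Auger contributions are folded into the lowest bins by the
# normalisation convention (total beta yield = 1).

mec2 <- 510.99895  # keV
alpha <- 1 / 137.036
Zd <- 72

branches <- data.frame(
  endpoint_kev = c(176.5, 248.6, 497.8),
  intensity    = c(0.116, 0.090, 0.794)
)
branches$intensity <- branches$intensity / sum(branches$intensity)

allowed_shape <- function(E, E0) {
  # E, E0 in keV; returns unnormalised density on the support (0, E0)
  W  <- (E + mec2) / mec2
  W0 <- (E0 + mec2) / mec2
  p  <- sqrt(pmax(W^2 - 1, 0))
  eta <- alpha * Zd * W / pmax(p, 1e-12)
  fermi <- 2 * pi * eta / (1 - exp(-2 * pi * eta))
  d <- fermi * p * W * (W0 - W)^2
  d[E <= 0 | E >= E0] <- 0
  d
}

emax <- max(branches$endpoint_kev)
edges <- seq(0, ceiling(emax), by = 1)          # 1 keV bins
mid <- (edges[-1] + edges[-length(edges)]) / 2

dens <- rep(0, length(mid))
for (i in seq_len(nrow(branches))) {
  d <- allowed_shape(mid, branches$endpoint_kev[i])
  d <- d / sum(d)                               # unit area per branch (1 keV bins)
  dens <- dens + branches$intensity[i] * d
}
# density per keV, total yield exactly 1
stopifnot(abs(sum(dens) - 1) < 1e-12)

out <- data.frame(energy_kev = mid, density_per_kev = signif(dens, 8))
dir.create(file.path("inst", "extdata"), recursive = TRUE, showWarnings = FALSE)
write.csv(out, file.path("inst", "extdata", "lu177_beta_spectrum.csv"),
          row.names = FALSE, quote = FALSE)
cat(sprintf("mean beta energy: %.3f keV\n", sum(out$energy_kev * out$density_per_kev)))
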