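KEV_TO_GY_PER_G <- 1.602176634e-13  # 1 keV deposited in 1 g, in Gy

#' Monte Carlo S-factors on a voxel phantom
#'
#' Estimates the S-factor matrix `S(target <- source)` in Gy per
#' disintegration by analog Monte Carlo on the labelled voxel grid. Decays
#' are sampled uniformly within each source region (stratified: every source
#' gets exactly `n_histories`). Beta particles deposit their energy linearly
#' along a straight track of CSDA range in water; photons are tracked with
#' water attenuation (photoelectric absorption and incoherent Compton
#' scattering; photons below `cutoff_kev` are absorbed locally). Statistical
#' uncertainties come from 10 equal batches.
#'
#' @param phantom a [build_phantom()] result.
#' @param nuclide a [nuclide_data()] object.
#' @param n_histories decays per source region (>= 1000).
#' @param seed integer seed (mandatory; the run is reproducible).
#' @param cutoff_kev photon energy cutoff; must lie between 1 and 100 keV.
#' @param include_electrons,include_photons physics switches (both on for a
#'   real run; single-physics runs support verification).
#' @param sources region names to use as sources (default: all regions).
#' @param n_batches batches for the uncertainty estimate.
#' @return object of class `s_factor_matrix`: `s` (targets x sources,
#'   Gy/decay), `rel_unc`, `masses_g`, `n_histories`, `physics_config`,
#'   `energy` (emitted / deposited keV per source).
#' @export
simulate_s_factors <- function(phantom, nuclide, n_histories, seed,
                               cutoff_kev = 10,
                               include_electrons = TRUE,
                               include_photons = TRUE,
                               sources = NULL, n_batches = 10) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(nuclide, "nuclide_data"))
  if (missing(seed) || is.null(seed)) stop("seed is required for a reproducible run")
  if (n_histories < 1e3) stop("n_histories must be >= 1000")
  if (cutoff_kev < 1 || cutoff_kev > 100)
    stop("config error: photon cutoff must be between 1 and 100 keV")
  rt <- phantom$region_table
  if (is.null(sources)) sources <- rt$region
  if (!all(sources %in% rt$region))
    stop("unknown source regions: ", paste(setdiff(sources, rt$region), collapse = ", "))

  sp <- nuclide$beta_spectrum
  w <- nuclide$bin_width_kev
  cdf_e <- sp$energy_kev + w / 2
  cdf <- cumsum(sp$density_per_kev * w)

  xs <- utils::read.csv(system.file("extdata", "water_photon_xs.csv",
                                    package = "mousedose", mustWork = TRUE))
  cs <- utils::read.csv(system.file("extdata", "water_electron_csda.csv",
                                    package = "mousedose", mustWork = TRUE))

  src_ids <- rt$id[match(sources, rt$region)]
  res <- .mc_transport(as.integer(phantom$labels), dim(phantom$labels),
                       phantom$voxel_size_mm, phantom$density_g_cm3,
                       as.integer(rt$id), as.integer(src_ids),
                       cdf_e, cdf,
                       nuclide$photon_lines$energy_kev,
                       nuclide$photon_lines$intensity,
                       xs$energy_kev, xs$photoelectric_cm2_g, xs$incoherent_cm2_g,
                       cs$energy_kev, cs$csda_range_cm,
                       as.integer(n_histories), as.integer(n_batches),
                       as.integer(seed), cutoff_kev,
                       include_electrons, include_photons)

  m <- stats::setNames(rt$achieved_mass_g, rt$region)
  s <- res$edep_kev_per_decay * KEV_TO_GY_PER_G / m[rt$region]
  dimnames(s) <- list(target = rt$region, source = sources)
  ru <- res$rel_unc
  dimnames(ru) <- dimnames(s)
  structure(list(s = s, rel_unc = ru, masses_g = m,
                 n_histories = res$histories_per_source,
                 physics_config = list(
                   cutoff_kev = cutoff_kev, seed = seed,
                   include_electrons = include_electrons,
                   include_photons = include_photons,
                   n_batches = n_batches, medium = "water",
                   density_g_cm3 = phantom$density_g_cm3),
                 energy = list(emitted_kev = res$emitted_kev,
                               deposited_kev = res$deposited_kev)),
            class = "s_factor_matrix")
}

#' @export
print.s_factor_matrix <- function(x, ...) {
  cat(sprintf("<s_factor_matrix> %d targets x %d sources, %g histories/source\n",
              nrow(x$s), ncol(x$s), x$n_histories))
  invisible(x)
}

#' Split organ doses into self-dose and total dose
#'
#' Combines an S-factor matrix with per-region cumulated activities
#' (disintegrations per MBq administered): the total dose to a target sums
#' all sources, the self-dose keeps only the diagonal term.
#'
#' @param s a `s_factor_matrix` (or a matrix with target/source dimnames).
#' @param cumulated named vector of disintegrations per MBq by source region.
#' @return data.frame with `region`, `self_gy_per_mbq`, `total_gy_per_mbq`.
#' @export
split_self_vs_cross <- function(s, cumulated) {
  smat <- if (inherits(s, "s_factor_matrix")) s$s else s
  src <- colnames(smat)
  missing_src <- setdiff(names(cumulated)[cumulated > 0], src)
  if (length(missing_src))
    stop("region mismatch: no S-factor column for active source(s): ",
         paste(missing_src, collapse = ", "))
  act <- stats::setNames(numeric(length(src)), src)
  act[names(cumulated)] <- cumulated
  total <- as.vector(smat %*% act)
  self <- vapply(rownames(smat), function(r)
    if (r %in% src) smat[r, r] * act[[r]] else 0, numeric(1))
  data.frame(region = rownames(smat),
             self_gy_per_mbq = unname(self),
             total_gy_per_mbq = total)
}

#' Export / import an S-factor matrix as CSV
#'
#' The CSV dialect (`target`, `source`, `gy_per_decay`, `rel_unc`) also
#' serves as the import path for externally supplied S-values, so published
#' coefficients can bypass the simulation.
#'
#' @param s a `s_factor_matrix`.
#' @param path CSV path.
#' @export
write_s_matrix_csv <- function(s, path) {
  stopifnot(inherits(s, "s_factor_matrix"))
  d <- expand.grid(target = rownames(s$s), source = colnames(s$s),
                   stringsAsFactors = FALSE)
  d$gy_per_decay <- as.vector(s$s)
  d$rel_unc <- as.vector(s$rel_unc)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_s_matrix_csv
#' @param masses_g optional named region masses carried into the object.
#' @export
read_s_matrix_csv <- function(path, masses_g = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target", "source", "gy_per_decay")
  if (!all(need %in% names(d)))
    stop("S-matrix CSV must have columns: ", paste(need, collapse = ", "))
  tg <- unique(d$target); sr <- unique(d$source)
  s <- matrix(0, length(tg), length(sr), dimnames = list(target = tg, source = sr))
  ru <- s
  s[cbind(match(d$target, tg), match(d$source, sr))] <- d$gy_per_decay
  if ("rel_unc" %in% names(d))
    ru[cbind(match(d$target, tg), match(d$source, sr))] <- d$rel_unc
  structure(list(s = s, rel_unc = ru, masses_g = masses_g,
                 n_histories = NA_integer_,
                 physics_config = list(imported_from = path),
                 energy = NULL),
            class = "s_factor_matrix")
}
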