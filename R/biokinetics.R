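#' Time-activity curve container
#'
#' Holds decay-corrected activity measurements for one source region:
#' times in hours post-injection and values in either percent injected
#' activity per organ (`per_organ`) or per gram (`per_gram`).
#'
#' @param region region label.
#' @param times_h hours post-injection, strictly increasing, all >= 0.
#' @param values activity fraction (%IA or %IA/g), all >= 0.
#' @param value_kind `"per_gram"` or `"per_organ"`.
#' @param n_animals animals contributing per time point (recycled).
#' @return object of class `tac`.
#' @export
time_activity_curve <- function(region, times_h, values,
                                value_kind = c("per_gram", "per_organ"),
                                n_animals = NA_integer_) {
  value_kind <- match.arg(value_kind)
  times_h <- as.numeric(times_h); values <- as.numeric(values)
  if (length(times_h) != length(values))
    stop("times_h and values must have equal length")
  if (any(times_h < 0)) stop("times must be >= 0")
  if (any(diff(times_h) <= 0)) stop("times must be strictly increasing")
  if (any(values < 0)) stop("activity values must be >= 0")
  structure(list(region = as.character(region), times_h = times_h,
                 values = values, value_kind = value_kind,
                 n_animals = rep_len(as.integer(n_animals), length(times_h))),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s (%s), %d points over %.0f-%.0f h\n", x$region,
              x$value_kind, length(x$times_h), min(x$times_h), max(x$times_h)))
  invisible(x)
}

#' Read time-activity curves from CSV
#'
#' Strict-header reader for the delimited biokinetics dialect:
#' columns `region`, `time_h`, `value`, `value_kind`, `n`. Replicate rows at
#' one (region, time) are averaged (and their n summed) before curve
#' construction.
#'
#' @param path CSV file path.
#' @return named list of [time_activity_curve()] objects, one per region.
#' @export
read_tac_csv <- function(path) {
  if (!file.exists(path)) stop("TAC file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "time_h", "value", "value_kind", "n")
  if (!identical(intersect(need, names(d)), need))
    stop("TAC file must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (r in unique(d$region)) {
    dr <- d[d$region == r, , drop = FALSE]
    vk <- unique(dr$value_kind)
    if (length(vk) != 1) stop("mixed value_kind within region ", r)
    agg <- stats::aggregate(cbind(value = dr$value) ~ time_h, data = dr, FUN = mean)
    nagg <- stats::aggregate(cbind(n = dr$n) ~ time_h, data = dr, FUN = sum)
    o <- order(agg$time_h)
    out[[r]] <- time_activity_curve(r, agg$time_h[o], agg$value[o], vk,
                                    nagg$n[match(agg$time_h[o], nagg$time_h)])
  }
  out
}

#' Write time-activity curves to CSV
#' @param tacs named list of `tac` objects.
#' @param path output CSV path.
#' @export
write_tac_csv <- function(tacs, path) {
  rows <- do.call(rbind, lapply(tacs, function(tc) {
    data.frame(region = tc$region, time_h = tc$times_h, value = tc$values,
               value_kind = tc$value_kind, n = tc$n_animals)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

biexp_model <- function(par, t) par[1] * exp(-par[2] * t) + par[3] * exp(-par[4] * t)

#' Fit a bi-exponential model to a time-activity curve
#'
#' Least-squares fit of `A1*exp(-lambda1*t) + A2*exp(-lambda2*t)` to
#' decay-corrected data. Physical decay is *not* part of the fitted model;
#' it is applied analytically inside the cumulated-activity integral via
#' `lambda_phys`. One amplitude may be negative so the model can describe an
#' uptake phase (rise to a late maximum, as antibody tumour curves do);
#' non-negativity is enforced on the model value over 0 to 2 * t_max, not
#' on the amplitudes.
#'
#' The optimisation is a deterministic multi-start: amplitudes are solved by
#' linear least squares on a fixed log-spaced grid of rate pairs spanning
#' 1e-4 to 1 per hour, and the best starts are polished with
#' Levenberg-Marquardt ([minpack.lm::nls.lm]). Ties are broken by lowest
#' residual norm, then lowest `lambda1`.
#'
#' @param tac a [time_activity_curve()] with at least 4 distinct points.
#' @param lambda_phys physical decay constant (per hour); used only for the
#'   integrability check and carried into the fit object.
#' @return object of class `biexp_fit` with elements `A1, lambda1, A2,
#'   lambda2, lambda_phys, residual_norm, region, value_kind`.
#'   Components are ordered with `lambda1 >= lambda2` (the fast component
#'   first); if one amplitude is negligible the surviving component is
#'   reported first and the other is zeroed.
#' @export
fit_biexponential <- function(tac, lambda_phys) {
  stopifnot(inherits(tac, "tac"))
  t <- tac$times_h; y <- tac$values
  if (length(unique(t)) < 4)
    stop("insufficient data: need >= 4 distinct time points for a bi-exponential fit")
  if (all(y == 0))
    stop("degenerate fit: all activity values are zero")
  if (!is.numeric(lambda_phys) || lambda_phys < 0)
    stop("lambda_phys must be a non-negative rate (per hour)")

  rates <- c(0, 10^seq(-4, 0, length.out = 9))
  starts <- list()
  for (i in seq_along(rates)) for (j in seq_along(rates)) {
    if (j <= i) next
    l1 <- rates[j]; l2 <- rates[i]   # l1 > l2
    X <- cbind(exp(-l1 * t), exp(-l2 * t))
    ab <- tryCatch(stats::lsfit(X, y, intercept = FALSE)$coefficients,
                   error = function(e) NULL)
    if (is.null(ab) || any(!is.finite(ab))) next
    rss <- sum((y - X %*% ab)^2)
    starts[[length(starts) + 1]] <- list(par = c(ab[1], l1, ab[2], l2), rss = rss)
  }
  starts <- starts[order(vapply(starts, `[[`, 0, "rss"))]
  starts <- starts[seq_len(min(8, length(starts)))]

  span <- 2 * max(t)
  tchk <- seq(0, span, length.out = 201)
  admissible <- function(p) {
    # rates must keep the cumulated-activity integral convergent, and the
    # model value must stay non-negative (to numerical tolerance) over the
    # fitted span
    p[2] + lambda_phys > 0 && p[4] + lambda_phys > 0 &&
      p[1] + p[3] >= -1e-4 * max(abs(y)) &&
      min(biexp_model(p, tchk)) >= -1e-4 * max(abs(y))
  }
  best <- NULL
  consider <- function(best, p, rss) {
    if (!admissible(p)) return(best)
    if (is.null(best) || rss < best$rss - 1e-12 * (1 + best$rss) ||
        (abs(rss - best$rss) <= 1e-12 * (1 + best$rss) && p[2] < best$par[2]))
      best <- list(par = p, rss = rss)
    best
  }
  polish <- function(par, fn) tryCatch(
    minpack.lm::nls.lm(par = par, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  for (s in starts) {
    fit <- polish(s$par, function(p) y - biexp_model(p, t))
    if (!is.null(fit)) best <- consider(best, fit$par, sum(fit$fvec^2))
    # the raw grid candidate is an admissible fallback when the local
    # optimiser wanders into an inadmissible minimum
    best <- consider(best, s$par, s$rss)
  }
  if (is.null(best)) {
    # constrained rescue: penalise negative model values so the optimiser
    # stays in the admissible set
    scale <- max(abs(y))
    fit <- polish(starts[[1]]$par, function(p)
      c(y - biexp_model(p, t), 1e4 * pmin(biexp_model(p, tchk) / scale, 0)))
    if (!is.null(fit))
      best <- consider(best, fit$par, sum((y - biexp_model(fit$par, t))^2))
  }
  if (is.null(best)) stop("bi-exponential fit failed for region ", tac$region)

  p <- best$par
  # canonical component order: fast rate first; drop a negligible component
  amax <- max(abs(p[c(1, 3)]))
  if (abs(p[3]) <= 1e-7 * amax) {
    p <- c(p[1], p[2], 0, 0)
  } else if (abs(p[1]) <= 1e-7 * amax) {
    p <- c(p[3], p[4], 0, 0)
  } else if (p[4] > p[2]) {
    p <- p[c(3, 4, 1, 2)]
  }
  # clamp a tiny negative initial value left by the penalised rescue
  if (p[1] + p[3] < 0) p[1] <- -p[3]
  structure(list(A1 = unname(p[1]), lambda1 = unname(p[2]),
                 A2 = unname(p[3]), lambda2 = unname(p[4]),
                 lambda_phys = lambda_phys,
                 residual_norm = sqrt(best$rss),
                 region = tac$region, value_kind = tac$value_kind),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit> %s: A1=%.4g (l1=%.4g/h), A2=%.4g (l2=%.4g/h), ||r||=%.3g\n",
              x$region, x$A1, x$lambda1, x$A2, x$lambda2, x$residual_norm))
  invisible(x)
}

#' Cumulated activity of a bi-exponential fit
#'
#' Closed form of the decay-weighted integral
#' `integral_0^inf (A1 e^{-l1 t} + A2 e^{-l2 t}) e^{-lphys t} dt
#'  = A1/(l1+lphys) + A2/(l2+lphys)`,
#' in %IA.h (or %IA/g.h for per-gram curves).
#'
#' @param fit a `biexp_fit`.
#' @return cumulated activity (same activity unit as the fit, times hours).
#' @export
cumulated_activity <- function(fit) {
  stopifnot(inherits(fit, "biexp_fit"))
  term <- function(A, l) {
    if (A == 0) return(0)
    d <- l + fit$lambda_phys
    if (d <= 0) stop("divergent integral: lambda + lambda_phys <= 0 with nonzero amplitude")
    A / d
  }
  term(fit$A1, fit$lambda1) + term(fit$A2, fit$lambda2)
}

#' Derive the red-marrow curve from the blood curve
#'
#' The red-marrow activity concentration is taken proportional to the blood
#' concentration with ratio 0.36, the standard marrow/blood partition for an
#' intact antibody.
#'
#' @param blood_tac per-gram blood [time_activity_curve()].
#' @param ratio marrow-to-blood concentration ratio.
#' @return per-gram marrow `tac` on the same time grid.
#' @export
marrow_curve_from_blood <- function(blood_tac, ratio = 0.36) {
  stopifnot(inherits(blood_tac, "tac"))
  if (blood_tac$value_kind != "per_gram")
    stop("unit mismatch: the marrow-from-blood rule applies to per-gram concentrations")
  time_activity_curve("marrow", blood_tac$times_h, ratio * blood_tac$values,
                      "per_gram", blood_tac$n_animals)
}

#' Disintegrations in a region per MBq administered
#'
#' Converts a cumulated activity in %IA.h (per organ) or %IA/g.h (per gram,
#' requiring the region mass) into MBq.h per MBq administered, then into
#' number of disintegrations via 3.6e9 per MBq.h.
#'
#' @param cumulated cumulated activity (%IA.h or %IA/g.h), or a `biexp_fit`
#'   from which it is computed.
#' @param region_mass_g region mass in grams (required for per-gram input).
#' @param value_kind `"per_organ"` or `"per_gram"`; defaults to the fit's.
#' @return disintegrations per MBq administered.
#' @export
decays_per_mbq_administered <- function(cumulated, region_mass_g = NULL,
                                        value_kind = NULL) {
  if (inherits(cumulated, "biexp_fit")) {
    if (is.null(value_kind)) value_kind <- cumulated$value_kind
    cumulated <- cumulated_activity(cumulated)
  }
  if (is.null(value_kind)) stop("value_kind is required for a bare cumulated value")
  value_kind <- match.arg(value_kind, c("per_organ", "per_gram"))
  mbq_h <- if (value_kind == "per_gram") {
    if (is.null(region_mass_g) || !is.finite(region_mass_g))
      stop("region mass is required to convert per-gram cumulated activity")
    cumulated * region_mass_g / 100
  } else cumulated / 100
  mbq_h * 3.6e9
}

#' Export bi-exponential fits as JSON
#' @param fits list of `biexp_fit` objects.
#' @param path output path.
#' @export
write_fits_json <- function(fits, path) {
  x <- lapply(fits, function(f) f[c("region", "value_kind", "A1", "lambda1",
                                    "A2", "lambda2", "lambda_phys",
                                    "residual_norm")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
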