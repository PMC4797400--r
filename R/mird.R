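#' Organ mean absorbed doses per the MIRD scheme
#'
#' `D(rT) = sum_rS  Atilde(rS) * S(rT <- rS)`: each target's dose
#' coefficient (Gy per MBq administered) is the cumulated-activity-weighted
#' sum of S-factors over source regions.
#'
#' @param cumulated named vector of disintegrations per MBq administered,
#'   by source region (see [decays_per_mbq_administered()]).
#' @param s an `s_factor_matrix` (simulated or imported).
#' @return data.frame `region`, `self_gy_per_mbq`, `total_gy_per_mbq`
#'   (class `dose_coefficients`).
#' @export
organ_dose <- function(cumulated, s) {
  if (any(cumulated < 0)) stop("cumulated activities must be >= 0")
  out <- split_self_vs_cross(s, cumulated)
  class(out) <- c("dose_coefficients", "data.frame")
  out
}

#' Coefficients from a published self/total table
#'
#' Wraps a table of per-organ self and total dose coefficients (Gy/MBq) --
#' e.g. reference values from a published study -- into the same
#' `dose_coefficients` object that [organ_dose()] produces, so downstream
#' dose tables and planning work identically for simulated and imported
#' coefficients.
#'
#' @param path CSV with columns `organ`, `kinetics`, `self_gy_per_mbq`,
#'   `total_gy_per_mbq`; defaults to the bundled reference table for the
#'   Lu-177 anti-hK2 antibody in LNCaP-xenografted mice.
#' @param kinetics which kinetics block to use: `"lu177"` (direct Lu-177
#'   biokinetics) or `"in111"` (In-111 surrogate kinetics).
#' @return `dose_coefficients` data.frame.
#' @export
reference_dose_coefficients <- function(path = NULL, kinetics = c("lu177", "in111")) {
  kinetics <- match.arg(kinetics)
  if (is.null(path))
    path <- system.file("extdata", "reference_dose_coefficients.csv",
                        package = "mousedose", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- d[d$kinetics == kinetics, c("organ", "self_gy_per_mbq", "total_gy_per_mbq")]
  names(d)[1] <- "region"
  rownames(d) <- NULL
  class(d) <- c("dose_coefficients", "data.frame")
  d
}

#' Absolute dose table at given administered activities
#'
#' Multiplies total dose coefficients by administered activities; reported
#' values are rounded to two significant figures (the raw products are kept
#' in the `raw` attribute).
#'
#' @param coefficients a `dose_coefficients` data.frame.
#' @param activities_mbq administered activities in MBq, all > 0.
#' @return `dose_report`: data.frame with one row per region, columns
#'   `self_gy_per_mbq`, `total_gy_per_mbq` and `dose_gy_<A>MBq` per activity.
#' @export
dose_table <- function(coefficients, activities_mbq) {
  stopifnot(is.data.frame(coefficients))
  if (any(activities_mbq <= 0)) stop("administered activities must be > 0")
  out <- coefficients
  raw <- outer(coefficients$total_gy_per_mbq, activities_mbq)
  colnames(raw) <- sprintf("dose_gy_%gMBq", activities_mbq)
  rounded <- signif(raw, 2)
  out <- cbind(out, as.data.frame(rounded))
  attr(out, "raw") <- raw
  attr(out, "activities_mbq") <- activities_mbq
  class(out) <- c("dose_report", class(coefficients))
  out
}

#' @export
print.dose_report <- function(x, ...) {
  cat("Absorbed dose per injected activity (Gy/MBq) and absolute doses (Gy)\n")
  y <- x
  y$self_gy_per_mbq <- round(y$self_gy_per_mbq, 2)
  y$total_gy_per_mbq <- round(y$total_gy_per_mbq, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Export a dose report
#' @param report a `dose_report`.
#' @param path CSV path.
#' @export
write_dose_report_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
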