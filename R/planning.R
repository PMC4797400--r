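#' Therapy-planning constraint
#'
#' The prescription inverts a normal-organ dose limit. The default limiting
#' region is the red bone marrow with a tolerable absorbed dose of 12 Gy,
#' the commonly adopted marrow tolerance for mice.
#'
#' @param limiting_region region label.
#' @param dose_limit_gy tolerated absorbed dose (Gy), > 0.
#' @return `planning_constraint` list.
#' @export
planning_constraint <- function(limiting_region = "marrow", dose_limit_gy = 12) {
  if (!is.numeric(dose_limit_gy) || dose_limit_gy <= 0)
    stop("dose_limit_gy must be > 0")
  structure(list(limiting_region = limiting_region,
                 dose_limit_gy = dose_limit_gy),
            class = "planning_constraint")
}

#' Prescribe the administered activity from a dose limit
#'
#' Returns `dose_limit / total coefficient` of the limiting region. The
#' unrounded value is exact (at it, the limiting organ receives exactly the
#' limit); `reported_mbq` rounds to the nearest integer MBq for reporting,
#' and downstream doses are conventionally quoted at the rounded value.
#'
#' @param coefficients `dose_coefficients` data.frame.
#' @param constraint a [planning_constraint()].
#' @return list `prescribed_mbq` (exact), `reported_mbq` (integer-rounded),
#'   `limiting_region`, `dose_limit_gy`, `coefficient_gy_per_mbq`.
#' @export
prescribe_activity <- function(coefficients, constraint = planning_constraint()) {
  stopifnot(is.data.frame(coefficients), inherits(constraint, "planning_constraint"))
  i <- match(constraint$limiting_region, coefficients$region)
  if (is.na(i))
    stop("limiting region '", constraint$limiting_region, "' not in coefficients")
  k <- coefficients$total_gy_per_mbq[i]
  if (!is.finite(k) || k <= 0)
    stop("unconstrained plan: limiting region has zero dose coefficient")
  a <- constraint$dose_limit_gy / k
  list(prescribed_mbq = a, reported_mbq = round(a),
       limiting_region = constraint$limiting_region,
       dose_limit_gy = constraint$dose_limit_gy,
       coefficient_gy_per_mbq = k)
}

#' Organ doses at a prescribed activity
#'
#' @param coefficients `dose_coefficients` data.frame.
#' @param prescribed_mbq administered activity (MBq), >= 0.
#' @return named vector of region doses (Gy) = total coefficient x activity.
#' @export
doses_at_prescription <- function(coefficients, prescribed_mbq) {
  stopifnot(is.data.frame(coefficients), prescribed_mbq >= 0)
  stats::setNames(coefficients$total_gy_per_mbq * prescribed_mbq,
                  coefficients$region)
}

#' Full therapy plan as a list (exportable as JSON)
#'
#' @inheritParams prescribe_activity
#' @return list with the prescription and the organ doses at both the exact
#'   and the reported (integer MBq) prescription.
#' @export
therapy_plan <- function(coefficients, constraint = planning_constraint()) {
  p <- prescribe_activity(coefficients, constraint)
  p$doses_gy_at_reported <- as.list(doses_at_prescription(coefficients, p$reported_mbq))
  p$doses_gy_at_exact <- as.list(doses_at_prescription(coefficients, p$prescribed_mbq))
  p
}
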