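#' Caliper tumour volume
#'
#' Rotated-ellipsoid approximation `V = w^2 * l / 2` with width `w` and
#' length `l` in mm (width is the shorter caliper axis).
#'
#' @param w,l caliper width and length in mm, both > 0.
#' @return volume in mm^3.
#' @export
tumor_volume <- function(w, l) {
  if (any(w <= 0) || any(l <= 0)) stop("caliper dimensions must be > 0")
  0.5 * w^2 * l
}

#' Humane-endpoint evaluation
#'
#' An animal reaches the endpoint when body weight drops below 80 % of its
#' day-0 baseline or when the largest tumour diameter exceeds 15 mm. Both
#' rules are strict inequalities: exactly 20 % loss or exactly 15 mm does
#' not trigger.
#'
#' @param width_mm,length_mm caliper measurements (mm).
#' @param body_weight_g current weight (g).
#' @param baseline_weight_g day-0 weight (g); required.
#' @param max_diameter_mm diameter threshold (default 15).
#' @param weight_loss_fraction tolerated loss fraction (default 0.2).
#' @return logical: `TRUE` if the endpoint is reached.
#' @export
evaluate_endpoint <- function(width_mm, length_mm, body_weight_g,
                              baseline_weight_g,
                              max_diameter_mm = 15,
                              weight_loss_fraction = 0.2) {
  if (missing(baseline_weight_g) || is.null(baseline_weight_g) ||
      any(is.na(baseline_weight_g)))
    stop("baseline weight (day 0) is required for endpoint evaluation")
  (body_weight_g < (1 - weight_loss_fraction) * baseline_weight_g) |
    (pmax(width_mm, length_mm) > max_diameter_mm)
}

#' Kaplan-Meier survival with median survival time
#'
#' Product-limit estimate via [survival::survfit]; the median is the
#' earliest time at which the survival function drops to 0.5 or below, and
#' is reported as `NA` if the curve stays above 0.5 through follow-up (the
#' convention used when too few animals reach the endpoint).
#'
#' @param records data.frame with columns `group`, `event_time` (days) and
#'   `event` (1 = endpoint reached, 0 = censored).
#' @return list: `fit` (the survfit object), `median_days` (named by group),
#'   `curves` (data.frame group, time, surv).
#' @export
kaplan_meier <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("group", "event_time", "event") %in% names(records)))
  if (any(records$event_time <= 0)) stop("event times must be > 0")
  fit <- survival::survfit(survival::Surv(event_time, event) ~ group,
                           data = records)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(records$group), length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, surv = sm$surv)
  med <- vapply(unique(records$group), function(g) {
    cg <- curves[curves$group == g, , drop = FALSE]
    i <- which(cg$surv <= 0.5)
    if (length(i)) min(cg$time[i]) else NA_real_
  }, numeric(1))
  list(fit = fit, median_days = med, curves = curves)
}

#' Percent change in tumour volume over time
#'
#' Per animal, 100 * V(t) / V(day 0); the group summary averages only the
#' animals still on study at each day (attrition-aware mean), which is
#' flagged in the output.
#'
#' @param measurements data.frame with columns `animal_id`, `group`, `day`,
#'   `width_mm`, `length_mm`.
#' @return list: `per_animal` (animal_id, group, day, volume_mm3,
#'   pct_of_baseline), `per_group` (group, day, mean_pct, n_alive),
#'   `summary_convention`.
#' @export
percent_volume_change <- function(measurements) {
  need <- c("animal_id", "group", "day", "width_mm", "length_mm")
  stopifnot(is.data.frame(measurements), all(need %in% names(measurements)))
  m <- measurements[order(measurements$animal_id, measurements$day), ]
  m$volume_mm3 <- ifelse(m$width_mm > 0 & m$length_mm > 0,
                         0.5 * m$width_mm^2 * m$length_mm, 0)
  base <- m[m$day == 0, c("animal_id", "volume_mm3")]
  names(base)[2] <- "v0"
  if (any(base$v0 <= 0)) stop("zero baseline volume at day 0")
  m <- merge(m, base, by = "animal_id")
  missing_base <- setdiff(unique(m$animal_id), base$animal_id)
  if (length(missing_base)) stop("no day-0 measurement for: ",
                                 paste(missing_base, collapse = ", "))
  m$pct_of_baseline <- 100 * m$volume_mm3 / m$v0
  per_group <- do.call(rbind, lapply(split(m, m[c("day", "group")], drop = TRUE),
    function(d) data.frame(group = d$group[1], day = d$day[1],
                           mean_pct = mean(d$pct_of_baseline),
                           n_alive = nrow(d))))
  per_group <- per_group[order(per_group$group, per_group$day), ]
  rownames(per_group) <- NULL
  list(per_animal = m[c("animal_id", "group", "day", "volume_mm3", "pct_of_baseline")],
       per_group = per_group,
       summary_convention = "mean over animals still on study at each day")
}

#' Survival records from longitudinal caliper/weight data
#'
#' Applies the endpoint rule to each animal's measurement series and emits
#' one survival record per animal: the first day the endpoint is reached
#' (event = 1) or the end of follow-up (event = 0, censored).
#'
#' @param measurements data.frame with columns `animal_id`, `group`, `day`,
#'   `width_mm`, `length_mm`, `weight_g`.
#' @param followup_days end of the study window (censoring time).
#' @return data.frame `animal_id`, `group`, `event_time`, `event`.
#' @export
survival_records <- function(measurements, followup_days = 120) {
  need <- c("animal_id", "group", "day", "width_mm", "length_mm", "weight_g")
  stopifnot(is.data.frame(measurements), all(need %in% names(measurements)))
  out <- lapply(split(measurements, measurements$animal_id), function(d) {
    d <- d[order(d$day), ]
    base <- d$weight_g[d$day == 0]
    if (!length(base)) stop("no day-0 weight for animal ", d$animal_id[1])
    hit <- evaluate_endpoint(d$width_mm, d$length_mm, d$weight_g, base[1])
    hit <- hit & d$day > 0 & d$day <= followup_days
    if (any(hit))
      data.frame(animal_id = d$animal_id[1], group = d$group[1],
                 event_time = min(d$day[hit]), event = 1L)
    else
      data.frame(animal_id = d$animal_id[1], group = d$group[1],
                 event_time = followup_days, event = 0L)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
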