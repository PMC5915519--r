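#' Tumor volume from caliper measurements
#'
#' The standard ellipsoid approximation for subcutaneous xenografts:
#' `volume = length * width^2 / 2` (mm^3), with the two caliper axes
#' canonicalised so that length is the larger one -- raw data entry order
#' then does not matter.
#'
#' @param length,width Caliper axes in mm, non-negative (vectorised).
#' @return Tumor volume in mm^3.
#' @examples
#' tumor_volume(10, 5)   # 125
#' tumor_volume(5, 10)   # same after canonicalisation
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0, na.rm = TRUE) || any(width < 0, na.rm = TRUE)) {
    stop("caliper axes must be non-negative", call. = FALSE)
  }
  l <- pmax(length, width)
  w <- pmin(length, width)
  l * w^2 / 2
}

#' Validate a table of per-animal longitudinal records
#'
#' One row per animal and measurement day, with caliper axes and body
#' weight. `group_mbq` is the administered activity (0 = control). Every
#' animal must have a day-0 observation, the baseline for relative tumor
#' volume and weight change.
#'
#' @param data A data frame with columns `animal_id`, `group_mbq`, `day`,
#'   `length_mm`, `width_mm`, `weight_g`.
#' @return A tibble of class `animal_records`.
#' @export
animal_records <- function(data) {
  data <- tibble::as_tibble(data)
  needed <- c("animal_id", "group_mbq", "day", "length_mm", "width_mm", "weight_g")
  miss <- setdiff(needed, names(data))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  num <- c("group_mbq", "day", "length_mm", "width_mm", "weight_g")
  if (any(sapply(data[num], function(v) any(v < 0, na.rm = TRUE)))) {
    stop("measurements and days must be non-negative", call. = FALSE)
  }
  chk <- data |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(has_day0 = any(.data$day == 0),
                     sorted = !is.unsorted(.data$day), .groups = "drop")
  if (any(!chk$has_day0)) {
    stop("animals without a day-0 baseline: ",
         paste(chk$animal_id[!chk$has_day0], collapse = ", "), call. = FALSE)
  }
  if (any(!chk$sorted)) {
    stop("days must be non-decreasing within an animal", call. = FALSE)
  }
  structure(dplyr::arrange(data, .data$group_mbq, .data$animal_id, .data$day),
            class = c("animal_records", class(data)))
}

#' Read per-animal records from CSV
#'
#' Expects columns `animal_id`, `group_mbq`, `day`, `length_mm`, `width_mm`,
#' `weight_g`; lines starting with `#` are ignored.
#'
#' @param path Path to the CSV file.
#' @return An [animal_records()] tibble.
#' @export
read_animal_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  animal_records(readr::read_csv(path, comment = "#", show_col_types = FALSE,
                                 progress = FALSE))
}

# Per-animal value at a day: exact match or linear interpolation between the
# flanking observation days; no extrapolation outside the observed range.
value_at_day <- function(days, values, day) {
  if (day < min(days) || day > max(days)) {
    stop("day ", day, " outside the observed range [", min(days), ", ", max(days), "]",
         call. = FALSE)
  }
  stats::approx(days, values, xout = day, ties = "ordered")$y
}

#' Per-animal series relative to the day-0 baseline
#'
#' Each animal's tumor volume (or body weight) expressed as a percentage of
#' its own day-0 value; day 0 maps to exactly 100%.
#'
#' @param records An [animal_records()] tibble.
#' @param quantity `"tumor_volume"` or `"body_weight"`.
#' @return A tibble with columns `animal_id`, `group_mbq`, `day`,
#'   `relative_pct`.
#' @export
relative_series <- function(records, quantity = c("tumor_volume", "body_weight")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(records, "animal_records"))
  val <- if (quantity == "tumor_volume") {
    tumor_volume(records$length_mm, records$width_mm)
  } else {
    records$weight_g
  }
  out <- records |>
    dplyr::mutate(.value = val) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(.baseline = .data$.value[.data$day == 0][1]) |>
    dplyr::ungroup()
  if (any(out$.baseline <= 0)) {
    stop("zero day-0 baseline for: ",
         paste(unique(out$animal_id[out$.baseline <= 0]), collapse = ", "),
         call. = FALSE)
  }
  out |>
    dplyr::transmute(.data$animal_id, .data$group_mbq, .data$day,
                     relative_pct = 100 * .data$.value / .data$.baseline)
}

#' Signed percent change from a relative value
#'
#' Converts a relative value (percent of day-0 baseline) into a signed
#' change: negative for shrinkage. A day-21 relative tumor volume of 9.6%
#' is a decrease of 90.4%.
#'
#' @param relative_pct Relative value in percent of baseline (>= 0).
#' @return `relative_pct - 100` (vectorised).
#' @export
percent_change <- function(relative_pct) {
  if (any(relative_pct < 0)) stop("relative percent must be >= 0", call. = FALSE)
  relative_pct - 100
}

#' Per-group summary of relative values at a study day
#'
#' Averages per-animal relative values (mean of ratios, not ratio of group
#' means -- the convention behind published relative-tumor-volume summaries),
#' linearly interpolating animals not measured on the exact day.
#'
#' @param records An [animal_records()] tibble.
#' @param day Study day.
#' @param quantity `"tumor_volume"` or `"body_weight"`.
#' @return A tibble with one row per `group_mbq`: `mean_pct`, `sd_pct`, `n`.
#' @export
group_summary <- function(records, day, quantity = c("tumor_volume", "body_weight")) {
  quantity <- match.arg(quantity)
  rel <- relative_series(records, quantity)
  per_animal <- rel |>
    dplyr::group_by(.data$animal_id, .data$group_mbq) |>
    dplyr::summarise(rel_at_day = value_at_day(.data$day, .data$relative_pct, !!day),
                     .groups = "drop")
  per_animal |>
    dplyr::group_by(.data$group_mbq) |>
    dplyr::summarise(mean_pct = mean(.data$rel_at_day),
                     sd_pct = stats::sd(.data$rel_at_day),
                     n = dplyr::n(), .groups = "drop")
}

#' Endpoint rules for survival analysis and husbandry
#'
#' Defaults follow common practice for subcutaneous xenograft therapy
#' studies: euthanasia when body-weight loss exceeds 20% of baseline or the
#' tumor reaches 800 mm^3; for survival analysis a 500 mm^3 volume is used
#' as the event in addition to the weight rule. The weight comparison is
#' strict (loss must exceed the limit); volume thresholds are inclusive.
#'
#' @param weight_loss_limit Fractional weight loss triggering euthanasia
#'   (default 0.20, strict `>`).
#' @param humane_volume Husbandry volume endpoint in mm^3 (default 800).
#' @param analysis_volume Survival-analysis volume endpoint in mm^3
#'   (default 500).
#' @param study_end Study length in days (default 56); animals with no event
#'   are censored here or at their last observation, whichever is earlier.
#' @return A list of class `endpoint_rules`.
#' @export
endpoint_rules <- function(weight_loss_limit = 0.20, humane_volume = 800,
                           analysis_volume = 500, study_end = 56) {
  if (weight_loss_limit <= 0 || humane_volume <= 0 || analysis_volume <= 0 ||
      study_end <= 0) {
    stop("all endpoint thresholds must be positive", call. = FALSE)
  }
  if (analysis_volume > humane_volume) {
    stop("`analysis_volume` must not exceed `humane_volume`", call. = FALSE)
  }
  structure(list(weight_loss_limit = weight_loss_limit,
                 humane_volume = humane_volume,
                 analysis_volume = analysis_volume,
                 study_end = study_end),
            class = "endpoint_rules")
}

#' Derive endpoint events from longitudinal records
#'
#' Scans each animal's trajectory for the first day an active rule fires.
#' In `"analysis"` mode (Kaplan-Meier input) the event is tumor volume at or
#' above `analysis_volume` OR weight loss strictly greater than
#' `weight_loss_limit`; in `"husbandry"` mode the volume threshold is
#' `humane_volume`. Animals with no event are censored at the earlier of
#' their last observation and `study_end`.
#'
#' @param records An [animal_records()] tibble.
#' @param rules An [endpoint_rules()].
#' @param mode `"analysis"` or `"husbandry"`.
#' @return A tibble of class `endpoint_events` with columns `animal_id`,
#'   `group_mbq`, `day`, `status` (`"event"`/`"censored"`) and `reason`.
#' @export
apply_endpoints <- function(records, rules = endpoint_rules(),
                            mode = c("analysis", "husbandry")) {
  mode <- match.arg(mode)
  stopifnot(inherits(records, "animal_records"), inherits(rules, "endpoint_rules"))
  vol_limit <- if (mode == "analysis") rules$analysis_volume else rules$humane_volume
  out <- records |>
    dplyr::mutate(volume = tumor_volume(.data$length_mm, .data$width_mm)) |>
    dplyr::group_by(.data$animal_id, .data$group_mbq) |>
    dplyr::group_modify(function(d, key) {
      w0 <- d$weight_g[d$day == 0][1]
      loss <- 1 - d$weight_g / w0
      vol_hit <- d$volume >= vol_limit
      wt_hit <- loss > rules$weight_loss_limit
      hit <- which(vol_hit | wt_hit)
      if (length(hit) > 0) {
        i <- hit[1]
        tibble::tibble(day = d$day[i], status = "event",
                       reason = if (vol_hit[i]) "tumor_volume" else "weight_loss")
      } else {
        tibble::tibble(day = min(max(d$day), rules$study_end),
                       status = "censored", reason = "no_event")
      }
    }) |>
    dplyr::ungroup()
  structure(out, class = c("endpoint_events", class(out)))
}

#' Per-animal weight-failure flags
#'
#' Flags each animal whose body-weight loss from baseline strictly exceeds
#' the tolerability limit at any observation -- the dose-limiting-toxicity
#' marker feeding [determine_mtd()]. An animal reaching the limit exactly is
#' not flagged.
#'
#' @param records An [animal_records()] tibble.
#' @param rules An [endpoint_rules()].
#' @return A tibble with columns `animal_id`, `group_mbq`, `weight_failure`.
#' @export
weight_failures <- function(records, rules = endpoint_rules()) {
  stopifnot(inherits(records, "animal_records"))
  records |>
    dplyr::group_by(.data$animal_id, .data$group_mbq) |>
    dplyr::summarise(
      weight_failure = {
        w0 <- .data$weight_g[.data$day == 0][1]
        any(1 - .data$weight_g / w0 > rules$weight_loss_limit)
      },
      .groups = "drop")
}

#' Maximum tolerated dose from per-group weight outcomes
#'
#' The MTD is the highest tested activity at which no animal triggers the
#' weight-loss euthanasia rule (strict loss > limit). Accepts either raw
#' [animal_records()] (failures are derived via [weight_failures()]) or a
#' pre-computed flag table with columns `group_mbq` and `weight_failure` --
#' useful when only per-group outcomes, not trajectories, are available.
#' Control animals (0 MBq) do not define an MTD.
#'
#' @param x An [animal_records()] tibble or a data frame with `group_mbq`
#'   and logical `weight_failure`.
#' @param rules An [endpoint_rules()] (used only for raw records).
#' @return The MTD in MBq, or `NA` when every tested activity produces a
#'   weight failure.
#' @export
determine_mtd <- function(x, rules = endpoint_rules()) {
  flags <- if (inherits(x, "animal_records")) {
    weight_failures(x, rules)
  } else if (is.data.frame(x) && all(c("group_mbq", "weight_failure") %in% names(x))) {
    tibble::as_tibble(x)
  } else {
    stop("`x` must be animal_records or a table with group_mbq + weight_failure",
         call. = FALSE)
  }
  flags <- dplyr::filter(flags, .data$group_mbq > 0)
  if (nrow(flags) == 0) stop("no non-control groups", call. = FALSE)
  by_group <- flags |>
    dplyr::group_by(.data$group_mbq) |>
    dplyr::summarise(tolerated = !any(.data$weight_failure), .groups = "drop")
  ok <- by_group$group_mbq[by_group$tolerated]
  if (length(ok) == 0) NA_real_ else max(ok)
}

#' Growth-curve plot for a therapy cohort
#'
#' Group-mean relative tumor volume over time, one line per administered
#' activity.
#'
#' @param records An [animal_records()] tibble.
#' @param quantity `"tumor_volume"` or `"body_weight"`.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(records, quantity = c("tumor_volume", "body_weight")) {
  quantity <- match.arg(quantity)
  rel <- relative_series(records, quantity)
  dat <- rel |>
    dplyr::group_by(.data$group_mbq, .data$day) |>
    dplyr::summarise(mean_pct = mean(.data$relative_pct), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$mean_pct,
                                    colour = factor(.data$group_mbq))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Day", colour = "MBq",
                  y = sprintf("%s (%% of day 0)",
                              if (quantity == "tumor_volume") "Relative tumor volume"
                              else "Relative body weight"))
}
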