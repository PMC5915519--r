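#' Integration options for time-integrated activity
#'
#' The sampled interval is always integrated by the trapezoidal rule; the
#' options control what happens before the first and after the last sample.
#'
#' Head policies: `"zero-origin"` draws a trapezoid from (0, 0) to the first
#' sample (activity ramps up from injection); `"plateau"` assumes the first
#' sampled value held from t = 0 (rectangle); `"start-at-first"` ignores the
#' pre-sample interval entirely. Tail policies: `"physical-decay"` lets the
#' last sample decay at the physical rate, contributing
#' `a(t_last) * half_life / ln 2` exactly; `"fitted-effective-decay"` fits a
#' log-linear effective rate to the last `fit_tail_points` samples and uses
#' `a(t_last) / lambda_eff`, falling back to physical decay (with a warning)
#' when the terminal samples are not decreasing.
#'
#' @param head `"zero-origin"` (default), `"plateau"` or `"start-at-first"`.
#' @param tail `"physical-decay"` (default) or `"fitted-effective-decay"`.
#' @param fit_tail_points Number of terminal samples for the fitted tail
#'   (>= 2).
#' @return A list of class `integration_options`.
#' @export
integration_options <- function(head = c("zero-origin", "plateau", "start-at-first"),
                                tail = c("physical-decay", "fitted-effective-decay"),
                                fit_tail_points = 3L) {
  head <- match.arg(head)
  tail <- match.arg(tail)
  if (tail == "fitted-effective-decay" && fit_tail_points < 2) {
    stop("`fit_tail_points` must be >= 2 for a fitted tail", call. = FALSE)
  }
  structure(list(head = head, tail = tail,
                 fit_tail_points = as.integer(fit_tail_points)),
            class = "integration_options")
}

#' Time-integrated activity per gram of a sampled activity curve
#'
#' Integrates the physical activity-concentration curve a(t) (fraction of
#' injected activity per gram) over all time: trapezoid over the samples,
#' plus a head segment before the first sample and an analytic exponential
#' tail beyond the last, per [integration_options()]. The result -- the
#' cumulated activity per gram and per unit injected activity -- is the
#' time-integral term of the MIRD absorbed-dose formula.
#'
#' @param curve An `activity_curve` from [to_physical_concentration()], or
#'   any data frame with columns `time_h` and `a_per_g`.
#' @param scheme A [decay_scheme()] (supplies the physical tail rate).
#' @param opts An [integration_options()].
#' @return Time-integrated activity in fraction-hours per gram, with
#'   attribute `breakdown` (head / trapezoid / tail contributions).
#' @examples
#' bd <- read_biodistribution(
#'   system.file("extdata", "table1_biodistribution.csv", package = "alphadose"))
#' cv <- to_physical_concentration(bd, "PC12 tumor", at211_scheme())
#' time_integrated_activity(cv, at211_scheme())
#' @export
time_integrated_activity <- function(curve, scheme, opts = integration_options()) {
  stopifnot(inherits(scheme, "decay_scheme"), inherits(opts, "integration_options"))
  t <- curve$time_h
  a <- curve$a_per_g
  if (length(t) == 0) stop("empty activity curve", call. = FALSE)
  if (length(t) < 2 && opts$head == "start-at-first") {
    stop("need >= 2 samples when the head segment is discarded", call. = FALSE)
  }
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing", call. = FALSE)
  if (any(a < 0)) stop("activity must be non-negative", call. = FALSE)

  head_part <- switch(opts$head,
    "zero-origin"    = t[1] * a[1] / 2,
    "plateau"        = t[1] * a[1],
    "start-at-first" = 0
  )
  trap_part <- if (length(t) > 1) {
    sum(diff(t) * (a[-length(a)] + a[-1]) / 2)
  } else 0

  lambda_phys <- log(2) / scheme$half_life_h
  lambda <- lambda_phys
  if (opts$tail == "fitted-effective-decay") {
    k <- min(opts$fit_tail_points, length(t))
    ti <- utils::tail(t, k)
    ai <- utils::tail(a, k)
    if (k < 2 || any(ai <= 0) || stats::coef(stats::lm(log(ai) ~ ti))[2] >= 0) {
      warning("terminal samples not decreasing; falling back to physical-decay tail",
              call. = FALSE)
    } else {
      lambda <- -unname(stats::coef(stats::lm(log(ai) ~ ti))[2])
    }
  }
  tail_part <- a[length(a)] / lambda

  structure(head_part + trap_part + tail_part,
            breakdown = c(head = head_part, trapezoid = trap_part, tail = tail_part))
}

#' Absorbed-dose coefficient from time-integrated activity
#'
#' MIRD local-deposition dose for an alpha emitter (absorbed fraction 1,
#' self-dose only): every decay deposits the branch-weighted mean alpha
#' energy in the source tissue itself. Per MBq injected,
#' `D = TIA [fraction h/g] * 3600 [s/h] * 1e6 [decay/s/MBq] * Ebar [J] * 1000 [g/kg]`,
#' giving Gy per MBq.
#'
#' @param tia Time-integrated activity, fraction-hours per gram (>= 0).
#' @param scheme A [decay_scheme()].
#' @return Absorbed-dose coefficient in Gy/MBq.
#' @export
absorbed_dose_coefficient <- function(tia, scheme) {
  stopifnot(inherits(scheme, "decay_scheme"))
  if (any(tia < 0)) stop("time-integrated activity must be >= 0", call. = FALSE)
  as.numeric(tia) * 3600 * 1e6 * mean_alpha_energy(scheme) * 1000
}

#' Absorbed-dose coefficients for every organ of a biodistribution table
#'
#' Runs the full pipeline -- physical-concentration conversion, trapezoidal
#' time-integrated activity with head/tail policy, MIRD energy conversion --
#' for each per-gram organ row. Whole-organ rows (e.g. thyroid %ID) are
#' converted to per-gram with a user-supplied organ mass, and skipped with a
#' warning when no mass is given.
#'
#' @param table A [biodist_table()].
#' @param scheme A [decay_scheme()].
#' @param opts An [integration_options()].
#' @param organ_masses Optional named numeric vector of organ masses in grams
#'   for whole-organ rows, e.g. `c(Thyroid = 0.003)`.
#' @return A tibble of class `dose_table` with columns `organ`, `tia_fh_per_g`
#'   and `dose_gy_per_mbq`, plus `head`/`trapezoid`/`tail` contribution
#'   columns (Gy/MBq); integration options are carried in the `options`
#'   attribute.
#' @examples
#' bd <- read_biodistribution(
#'   system.file("extdata", "table1_biodistribution.csv", package = "alphadose"))
#' organ_dose_table(bd, at211_scheme())
#' @export
organ_dose_table <- function(table, scheme, opts = integration_options(),
                             organ_masses = NULL) {
  stopifnot(inherits(table, "biodist_table"))
  organs <- unique(table$organ)
  units <- table |> dplyr::distinct(.data$organ, .data$unit)
  per_organ <- units$organ[units$unit == "pct_id_per_organ"]
  skipped <- setdiff(per_organ, names(organ_masses))
  if (length(skipped) > 0) {
    warning("skipping whole-organ rows without a mass: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  kept <- setdiff(organs, skipped)
  k_energy <- 3600 * 1e6 * mean_alpha_energy(scheme) * 1000
  res <- purrr::map_dfr(kept, function(org) {
    if (org %in% per_organ) {
      row <- dplyr::filter(table, .data$organ == !!org)
      a <- row$mean / organ_masses[[org]] / 100
      if (is_decay_corrected(table)) a <- a * decay_factor(row$time_h, scheme$half_life_h)
      curve <- tibble::tibble(organ = org, time_h = row$time_h, a_per_g = a)
    } else {
      curve <- to_physical_concentration(table, org, scheme)
    }
    tia <- time_integrated_activity(curve, scheme, opts)
    parts <- attr(tia, "breakdown") * k_energy
    tibble::tibble(organ = org, tia_fh_per_g = as.numeric(tia),
                   dose_gy_per_mbq = as.numeric(tia) * k_energy,
                   head = parts[["head"]], trapezoid = parts[["trapezoid"]],
                   tail = parts[["tail"]])
  })
  structure(res, options = opts, scheme = scheme$name,
            class = c("dose_table", class(res)))
}

#' Absorbed dose for an administered activity
#'
#' @param coefficient Absorbed-dose coefficient in Gy/MBq (>= 0).
#' @param administered Administered activity in MBq (>= 0).
#' @return Absorbed dose in Gy (vectorised product).
#' @examples
#' dose_for_activity(10.21, 1.11)  # tumor dose at the MTD, ~11.3 Gy
#' @export
dose_for_activity <- function(coefficient, administered) {
  if (any(coefficient < 0) || any(administered < 0)) {
    stop("coefficient and administered activity must be >= 0", call. = FALSE)
  }
  coefficient * administered
}

#' @export
print.dose_table <- function(x, ...) {
  opts <- attr(x, "options")
  cat(sprintf("<dose_table> scheme = %s, head = %s, tail = %s\n",
              attr(x, "scheme"), opts$head, opts$tail))
  NextMethod()
}

#' @rdname organ_dose_table
#' @param x A `dose_table`.
#' @param ... Unused.
#' @export
tidy.dose_table <- function(x, ...) {
  tibble::as_tibble(x)[, c("organ", "dose_gy_per_mbq", "tia_fh_per_g")]
}

#' @rdname organ_dose_table
#' @export
autoplot.dose_table <- function(x, ...) {
  dat <- dplyr::arrange(tibble::as_tibble(x), .data$dose_gy_per_mbq)
  dat$organ <- factor(dat$organ, levels = dat$organ)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dose_gy_per_mbq, y = .data$organ)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "Absorbed-dose coefficient (Gy/MBq)", y = NULL)
}
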