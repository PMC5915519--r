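#' Survival fraction from a dose-response plate
#'
#' Normalises per-concentration MTT-style readouts (absorbance, counts) to
#' the untreated control: `100 * mean(readout at c) / mean(readout at 0)`.
#' The 0 kBq/mL control therefore maps to exactly 100%. Per-concentration
#' SDs are the replicate SDs on the same normalised scale. Optional blank
#' (background well) subtraction is applied to every readout first.
#'
#' @param plate A data frame with columns `conc_kbq_ml`, `readout` (and
#'   optionally `replicate`).
#' @param blank Background readout subtracted from every well (default 0).
#' @return A tibble with columns `conc_kbq_ml`, `mean_pct`, `sd_pct`, `n`.
#' @export
survival_fraction <- function(plate, blank = 0) {
  if (!all(c("conc_kbq_ml", "readout") %in% names(plate))) {
    stop("`plate` needs columns `conc_kbq_ml` and `readout`", call. = FALSE)
  }
  if (any(plate$conc_kbq_ml < 0)) stop("concentrations must be >= 0", call. = FALSE)
  plate <- dplyr::mutate(plate, readout = .data$readout - blank)
  ctl <- plate$readout[plate$conc_kbq_ml == 0]
  if (length(ctl) == 0 || mean(ctl) <= 0) {
    stop("a 0 kBq/mL control with positive mean readout is required", call. = FALSE)
  }
  plate |>
    dplyr::group_by(.data$conc_kbq_ml) |>
    dplyr::summarise(mean_pct = 100 * mean(.data$readout) / mean(ctl),
                     sd_pct = 100 * stats::sd(.data$readout) / mean(ctl),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$conc_kbq_ml)
}

#' Percentage of positive cells
#'
#' Fraction of scored cells positive for a marker (e.g. comet-assay DNA
#' double-strand breaks), as a percentage.
#'
#' @param positives Number of positive cells (0 <= positives <= total).
#' @param total Total cells scored (> 0).
#' @return `100 * positives / total` (vectorised).
#' @export
positive_fraction <- function(positives, total) {
  if (any(total <= 0)) stop("`total` must be positive", call. = FALSE)
  if (any(positives < 0) || any(positives > total)) {
    stop("`positives` must lie in [0, total]", call. = FALSE)
  }
  100 * positives / total
}

#' Monoexponential dose-response fit
#'
#' Least-squares fit of `S(c) = 100 * exp(-k * c)` to the normalised
#' survival fractions of a plate -- a single-hit inactivation model in
#' activity concentration, used mainly for parameter-recovery checks of the
#' synthetic generator.
#'
#' @param plate A plate data frame as in [survival_fraction()], or a
#'   pre-normalised table with columns `conc_kbq_ml` and `mean_pct`.
#' @return A list of class `expsurv_fit`: `k` (per kBq/mL), `fitted`,
#'   `residuals`, `data`.
#' @examples
#' pl <- gen_invitro(k = 0.5, cv = 0, seed = 1)
#' fit_monoexponential_survival(pl)$k
#' @export
fit_monoexponential_survival <- function(plate) {
  sf <- if ("mean_pct" %in% names(plate)) {
    tibble::as_tibble(plate)
  } else {
    survival_fraction(plate)
  }
  if (nrow(sf) < 3) stop("need >= 3 concentrations", call. = FALSE)
  if (any(sf$mean_pct <= 0)) {
    stop("survival fractions must be positive", call. = FALSE)
  }
  # log-linear through-origin slope as the starting value
  k0 <- max(0, -sum(sf$conc_kbq_ml * log(sf$mean_pct / 100)) /
              max(sum(sf$conc_kbq_ml^2), .Machine$double.eps))
  k <- if (sum((sf$mean_pct - 100 * exp(-k0 * sf$conc_kbq_ml))^2) < 1e-12) {
    k0  # log-linear start is already exact (noise-free data)
  } else {
    fit <- stats::nls(mean_pct ~ 100 * exp(-k * conc_kbq_ml), data = sf,
                      start = list(k = k0),
                      control = stats::nls.control(warnOnly = TRUE))
    max(0, unname(stats::coef(fit)["k"]))
  }
  fitted <- 100 * exp(-k * sf$conc_kbq_ml)
  structure(list(k = k, fitted = fitted, residuals = sf$mean_pct - fitted,
                 data = sf),
            class = "expsurv_fit")
}

#' @rdname fit_monoexponential_survival
#' @param x An `expsurv_fit`.
#' @param ... Unused.
#' @export
tidy.expsurv_fit <- function(x, ...) {
  tibble::tibble(term = "k", estimate = x$k)
}

#' @rdname fit_monoexponential_survival
#' @export
glance.expsurv_fit <- function(x, ...) {
  tibble::tibble(k = x$k, rss = sum(x$residuals^2), n = nrow(x$data))
}

#' @export
print.expsurv_fit <- function(x, ...) {
  cat(sprintf("Monoexponential survival fit: k = %.4g per kBq/mL (RSS %.3g, %d concentrations)\n",
              x$k, sum(x$residuals^2), nrow(x$data)))
  invisible(x)
}

#' @rdname fit_monoexponential_survival
#' @export
autoplot.expsurv_fit <- function(x, ...) {
  grid <- tibble::tibble(
    conc_kbq_ml = seq(0, max(x$data$conc_kbq_ml), length.out = 200))
  grid$mean_pct <- 100 * exp(-x$k * grid$conc_kbq_ml)
  ggplot2::ggplot(x$data, ggplot2::aes(x = .data$conc_kbq_ml, y = .data$mean_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "Activity concentration (kBq/mL)", y = "Survival (% of control)")
}
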