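#' Define a radionuclide decay scheme
#'
#' A decay scheme bundles the physical constants needed for alpha dosimetry:
#' the physical half-life and the alpha branches, each a branching fraction
#' together with the alpha-particle energy it emits. Short-lived daughters
#' that decay essentially in place (e.g. the 0.52 s 211Po daughter of 211At)
#' are folded in as branches of the parent.
#'
#' @param name Nuclide label, e.g. `"At-211"`.
#' @param half_life_h Physical half-life in hours; must be positive.
#' @param branches A data frame with columns `fraction` (branching fraction,
#'   each in \[0, 1\], summing to at most 1 within a small tolerance) and
#'   `energy_mev` (alpha energy in MeV, non-negative).
#' @return An object of class `decay_scheme`: a list with elements `name`,
#'   `half_life_h` and `branches` (a tibble).
#' @examples
#' sc <- decay_scheme("demo", 10, data.frame(fraction = 1, energy_mev = 5))
#' mean_alpha_energy(sc)
#' @export
decay_scheme <- function(name, half_life_h, branches) {
  if (!is.numeric(half_life_h) || length(half_life_h) != 1 || !is.finite(half_life_h) ||
      half_life_h <= 0) {
    stop("`half_life_h` must be a single positive number", call. = FALSE)
  }
  branches <- tibble::as_tibble(branches)
  if (!all(c("fraction", "energy_mev") %in% names(branches))) {
    stop("`branches` needs columns `fraction` and `energy_mev`", call. = FALSE)
  }
  if (nrow(branches) == 0) stop("`branches` must have at least one row", call. = FALSE)
  if (any(branches$fraction < 0 | branches$fraction > 1)) {
    stop("branch fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sum(branches$fraction) > 1 + 1e-6) {
    stop("branch fractions sum to more than 1", call. = FALSE)
  }
  if (any(branches$energy_mev < 0)) stop("alpha energies must be >= 0", call. = FALSE)
  structure(
    list(name = name, half_life_h = half_life_h,
         branches = branches[, c("fraction", "energy_mev")]),
    class = "decay_scheme"
  )
}

#' @export
print.decay_scheme <- function(x, ...) {
  cat(sprintf("<decay_scheme> %s  t1/2 = %g h\n", x$name, x$half_life_h))
  print(x$branches)
  invisible(x)
}

#' Built-in decay scheme for astatine-211
#'
#' 211At decays by two effective alpha branches: 41.8% by direct alpha
#' emission (5.867 MeV) and 58.2% by electron capture to 211Po, whose 0.52 s
#' half-life is negligible at the hour scale of biodistribution sampling, so
#' its 7.450 MeV alpha is treated as emitted in place at the moment of the
#' parent decay. Constants are standard nuclear data. Electron-capture
#' photon/electron dose and the long-lived 207Bi granddaughter are excluded:
#' dosimetry here is alpha-only self-dose.
#'
#' @return A [decay_scheme()] for 211At.
#' @export
at211_scheme <- function() {
  decay_scheme(
    "At-211", 7.214,
    tibble::tibble(fraction = c(0.418, 0.582), energy_mev = c(5.867, 7.450))
  )
}

#' Physical decay factor
#'
#' Fraction of a radionuclide's activity remaining after `t_h` hours:
#' `exp(-ln(2) * t / half_life)`.
#'
#' @param t_h Elapsed time in hours, non-negative (vectorised).
#' @param half_life_h Half-life in hours, positive.
#' @return Numeric in (0, 1], same length as `t_h`.
#' @examples
#' decay_factor(7.214, 7.214)  # 0.5 by definition
#' @export
decay_factor <- function(t_h, half_life_h) {
  if (!is.numeric(half_life_h) || length(half_life_h) != 1 || half_life_h <= 0) {
    stop("`half_life_h` must be a single positive number", call. = FALSE)
  }
  if (any(t_h < 0)) stop("`t_h` must be non-negative", call. = FALSE)
  exp(-log(2) * t_h / half_life_h)
}

#' Branch-weighted mean alpha energy per decay
#'
#' Sum over branches of fraction times alpha energy, returned in joules
#' (1 MeV = 1.602176634e-13 J). This is the energy term of the local-deposition
#' MIRD dose formula for alpha emitters.
#'
#' @param scheme A [decay_scheme()].
#' @return Mean alpha energy per decay, in joules.
#' @export
mean_alpha_energy <- function(scheme) {
  stopifnot(inherits(scheme, "decay_scheme"))
  mev <- sum(scheme$branches$fraction * scheme$branches$energy_mev)
  mev * 1.602176634e-13
}

#' Decay-correct or uncorrect an activity-like quantity
#'
#' Biodistribution tables are conventionally decay-corrected to injection
#' time; physical dosimetry needs the uncorrected (physical) activity.
#' `direction = "uncorrect"` multiplies by the decay factor (corrected ->
#' physical); `direction = "correct"` divides (physical -> corrected). The
#' two are exact inverses.
#'
#' @param x Activity-like quantity (vectorised).
#' @param t_h Elapsed time in hours (scalar or same length as `x`).
#' @param scheme A [decay_scheme()].
#' @param direction `"correct"` or `"uncorrect"`.
#' @return `x` rescaled by the decay factor.
#' @export
apply_decay <- function(x, t_h, scheme, direction = c("uncorrect", "correct")) {
  direction <- match.arg(direction)
  f <- decay_factor(t_h, scheme$half_life_h)
  if (direction == "uncorrect") x * f else x / f
}

#' Read a decay scheme from a YAML config file
#'
#' The file holds `name`, `half_life_h` and a `branches` list of
#' `{fraction, energy_mev}` entries, letting users swap in other
#' alpha emitters or alternative 211At constants.
#'
#' @param path Path to a YAML file.
#' @return A [decay_scheme()].
#' @export
read_decay_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  br <- dplyr::bind_rows(lapply(cfg$branches, tibble::as_tibble))
  decay_scheme(cfg$name, cfg$half_life_h, br)
}
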