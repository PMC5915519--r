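#' Construct a biodistribution time-activity table
#'
#' The central container for organ uptake time-courses: one row per organ and
#' sampling time, holding the group mean and SD of the uptake together with
#' the per-organ reporting unit. Most organs are reported as percent injected
#' dose per gram (`"pct_id_per_g"`); whole-organ rows such as thyroid use
#' percent injected dose (`"pct_id_per_organ"`). Whether values are
#' decay-corrected to injection time is a table-level flag (the near-universal
#' convention for published biodistributions is corrected).
#'
#' @param data A data frame with columns `organ`, `time_h`, `mean`, `sd`,
#'   `n`, `unit`.
#' @param decay_corrected Logical flag: are uptake values corrected for
#'   physical decay back to injection time?
#' @return A tibble of class `biodist_table` with attribute `decay_corrected`.
#' @export
biodist_table <- function(data, decay_corrected = TRUE) {
  data <- tibble::as_tibble(data)
  needed <- c("organ", "time_h", "mean", "sd", "n", "unit")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[, needed]
  problems <- character()
  bad <- which(!is.finite(data$mean) | data$mean < 0)
  if (length(bad) > 0) {
    problems <- c(problems, paste0(
      "negative or missing mean at ", paste0(data$organ[bad], "@", data$time_h[bad], "h",
                                             collapse = ", ")))
  }
  bad <- which(!is.finite(data$sd) | data$sd < 0)
  if (length(bad) > 0) {
    problems <- c(problems, paste0(
      "negative or missing sd at ", paste0(data$organ[bad], "@", data$time_h[bad], "h",
                                           collapse = ", ")))
  }
  if (any(data$time_h <= 0)) problems <- c(problems, "sampling times must be > 0 h")
  if (!all(data$unit %in% c("pct_id_per_g", "pct_id_per_organ"))) {
    problems <- c(problems, "unit must be 'pct_id_per_g' or 'pct_id_per_organ'")
  }
  nondecr <- data |>
    dplyr::group_by(.data$organ) |>
    dplyr::summarise(ok = !is.unsorted(.data$time_h, strictly = TRUE), .groups = "drop")
  if (any(!nondecr$ok)) {
    problems <- c(problems, paste0("times not strictly increasing for: ",
                                   paste(nondecr$organ[!nondecr$ok], collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop("invalid biodistribution table:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(data,
            decay_corrected = isTRUE(decay_corrected),
            class = c("biodist_table", class(data)))
}

#' Is a biodistribution table decay-corrected?
#'
#' @param table A [biodist_table()].
#' @return Logical flag.
#' @export
is_decay_corrected <- function(table) {
  isTRUE(attr(table, "decay_corrected"))
}

#' Read a biodistribution CSV
#'
#' Expects one row per organ in a wide layout: columns `organ`, `unit`, then
#' paired `mean_<t>h` / `sd_<t>h` columns (e.g. `mean_3h`, `sd_3h`), or
#' alternatively single `<t>h` columns holding "mean ± sd" cells. Lines
#' starting with `#` are metadata comments; `# decay_corrected: true|false`
#' and `# n_per_timepoint: <int>` are honoured (defaults: corrected, n = NA).
#'
#' @param path Path to the CSV file.
#' @return A validated [biodist_table()] in long format.
#' @examples
#' path <- system.file("extdata", "table1_biodistribution.csv", package = "alphadose")
#' bd <- read_biodistribution(path)
#' dplyr::filter(bd, organ == "PC12 tumor")
#' @export
read_biodistribution <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 50L, warn = FALSE)
  header <- header[startsWith(header, "#")]
  meta_flag <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), header, value = TRUE)
    if (length(hit) == 0) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1]))
  }
  decay_corrected <- tolower(meta_flag("decay_corrected", "true")) %in% c("true", "yes", "1")
  n_default <- suppressWarnings(as.integer(meta_flag("n_per_timepoint", NA)))

  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0 || !"organ" %in% names(df)) {
    stop("invalid biodistribution CSV: no data rows or no `organ` column", call. = FALSE)
  }
  if (!"unit" %in% names(df)) {
    stop("invalid biodistribution CSV: every organ needs a `unit` flag column", call. = FALSE)
  }

  mean_cols <- grep("^mean_[0-9.]+h$", names(df), value = TRUE)
  pm_cols <- grep("^[0-9.]+h$", names(df), value = TRUE)
  if (length(mean_cols) > 0) {
    long <- df |>
      tidyr::pivot_longer(dplyr::matches("^(mean|sd)_[0-9.]+h$"),
                          names_to = c(".value", "time_h"),
                          names_pattern = "^(mean|sd)_([0-9.]+)h$") |>
      dplyr::mutate(time_h = as.numeric(.data$time_h))
  } else if (length(pm_cols) > 0) {
    long <- df |>
      tidyr::pivot_longer(dplyr::all_of(pm_cols),
                          names_to = "time_h", values_to = "cell") |>
      dplyr::mutate(time_h = as.numeric(sub("h$", "", .data$time_h))) |>
      tidyr::separate_wider_regex(
        "cell", c(mean = "[0-9.eE+-]+", "\\s*(?:±|\\+/-)\\s*", sd = "[0-9.eE+-]+")) |>
      dplyr::mutate(mean = as.numeric(.data$mean), sd = as.numeric(.data$sd))
  } else {
    stop("no time-point columns found (expect `mean_<t>h`/`sd_<t>h` pairs or `<t>h` cells)",
         call. = FALSE)
  }
  if (!"sd" %in% names(long)) long$sd <- 0
  if (!"n" %in% names(long)) long$n <- n_default
  long <- dplyr::arrange(long, .data$organ, .data$time_h)
  biodist_table(long, decay_corrected = decay_corrected)
}

#' Write a biodistribution table as CSV
#'
#' Writes the wide mean/sd-pair layout read back by [read_biodistribution()],
#' with metadata comment lines for the decay-correction flag and group size.
#'
#' @param table A [biodist_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biodistribution <- function(table, path) {
  stopifnot(inherits(table, "biodist_table"))
  wide <- table |>
    tidyr::pivot_wider(id_cols = c("organ", "unit"),
                       names_from = "time_h", values_from = c("mean", "sd"),
                       names_glue = "{.value}_{time_h}h")
  times <- sort(unique(table$time_h))
  ord <- c("organ", "unit",
           as.vector(rbind(paste0("mean_", times, "h"), paste0("sd_", times, "h"))))
  wide <- wide[, ord]
  n <- unique(stats::na.omit(table$n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# decay_corrected: %s", tolower(is_decay_corrected(table))),
    if (length(n) == 1) sprintf("# n_per_timepoint: %d", as.integer(n))
  ), con)
  utils::write.csv(wide, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert an organ row to physical activity concentration
#'
#' Converts decay-corrected percent-injected-dose-per-gram uptake into the
#' physical (non-corrected) fraction of injected activity per gram, the
#' quantity whose time integral feeds the MIRD dose formula:
#' `a(t) = mean(t)/100 * decay_factor(t)` when the table is decay-corrected,
#' or `mean(t)/100` unchanged when it already holds physical values.
#'
#' @param table A [biodist_table()].
#' @param organ Organ name, must be present and reported per gram
#'   (whole-organ rows need a mass; see [organ_dose_table()]).
#' @param scheme A [decay_scheme()].
#' @return A tibble of class `activity_curve` with columns `organ`, `time_h`,
#'   `a_per_g` (fraction of injected activity per gram, physical).
#' @examples
#' bd <- read_biodistribution(
#'   system.file("extdata", "table1_biodistribution.csv", package = "alphadose"))
#' to_physical_concentration(bd, "PC12 tumor", at211_scheme())
#' @export
to_physical_concentration <- function(table, organ, scheme) {
  stopifnot(inherits(table, "biodist_table"), inherits(scheme, "decay_scheme"))
  row <- dplyr::filter(table, .data$organ == !!organ)
  if (nrow(row) == 0) stop("unknown organ: ", organ, call. = FALSE)
  if (any(row$unit != "pct_id_per_g")) {
    stop("organ '", organ, "' is reported per organ, not per gram; ",
         "supply a mass via organ_dose_table()", call. = FALSE)
  }
  a <- row$mean / 100
  if (is_decay_corrected(table)) a <- a * decay_factor(row$time_h, scheme$half_life_h)
  structure(
    tibble::tibble(organ = organ, time_h = row$time_h, a_per_g = a),
    class = c("activity_curve", "tbl_df", "tbl", "data.frame")
  )
}
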