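# Shared fixtures built in code.

table1_path <- function() {
  system.file("extdata", "table1_biodistribution.csv", package = "alphadose")
}

table2_reference <- function() {
  readr::read_csv(system.file("extdata", "table2_absorbed_dose.csv",
                              package = "alphadose"),
                  comment = "#", show_col_types = FALSE, progress = FALSE)
}

# Event table shorthand: status from +/- sign convention (negative = censored)
make_events <- function(days) {
  tibble::tibble(day = abs(days),
                 status = ifelse(days < 0, "censored", "event"))
}

# One-animal longitudinal record with equal caliper axes so that
# volume = day-indexed `volumes` exactly: l = w = (2V)^(1/3).
make_animal <- function(id, group, days, volumes, weights) {
  l <- (2 * volumes)^(1 / 3)
  tibble::tibble(animal_id = id, group_mbq = group, day = days,
                 length_mm = l, width_mm = l, weight_g = weights)
}

# A clean biodistribution table from explicit values (decay-corrected %ID/g).
make_biodist <- function(organ, times, means, sds = 0 * means, n = 5L) {
  biodist_table(tibble::tibble(organ = organ, time_h = times, mean = means,
                               sd = sds, n = n, unit = "pct_id_per_g"))
}
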