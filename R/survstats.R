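#' Kaplan-Meier product-limit estimator
#'
#' From-scratch product-limit estimate of the survival function from
#' possibly right-censored event times: at each distinct event time t_i with
#' d_i events among n_i at risk, the survival probability multiplies by
#' (1 - d_i/n_i). Subjects censored at t remain at risk for events at t
#' (events processed before censorings at tied times, the standard
#' convention). Greenwood standard errors are included.
#'
#' @param events A data frame with columns `day` (time >= 0) and `status`
#'   (`"event"` or `"censored"`), e.g. from [apply_endpoints()].
#' @return A tibble of class `km_fit` with one row per distinct observed
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`, `std_err`.
#' @examples
#' ev <- tibble::tibble(day = c(2, 4, 5, 6, 8),
#'                      status = c("event", "event", "censored", "censored", "censored"))
#' kaplan_meier(ev)
#' @export
kaplan_meier <- function(events) {
  if (nrow(events) == 0) stop("no subjects", call. = FALSE)
  if (!all(c("day", "status") %in% names(events))) {
    stop("`events` needs columns `day` and `status`", call. = FALSE)
  }
  if (any(events$day < 0)) stop("times must be >= 0", call. = FALSE)
  tab <- events |>
    dplyr::group_by(time = .data$day) |>
    dplyr::summarise(n_event = sum(.data$status == "event"),
                     n_censor = sum(.data$status == "censored"),
                     .groups = "drop") |>
    dplyr::arrange(.data$time)
  n <- nrow(events)
  at_risk <- n - cumsum(dplyr::lag(tab$n_event + tab$n_censor, default = 0))
  surv <- cumprod(1 - tab$n_event / at_risk)
  # Greenwood: var(S) = S^2 * sum d_i / (n_i (n_i - d_i)); 0/0 -> 0
  gw_term <- ifelse(tab$n_event > 0 & at_risk > tab$n_event,
                    tab$n_event / (at_risk * (at_risk - tab$n_event)),
                    ifelse(tab$n_event == 0, 0, NA_real_))
  std_err <- surv * sqrt(cumsum(gw_term))
  structure(
    tibble::tibble(time = tab$time, n_risk = at_risk, n_event = tab$n_event,
                   n_censor = tab$n_censor, survival = surv, std_err = std_err),
    n_subjects = n,
    class = c("km_fit", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname kaplan_meier
#' @param x A `km_fit`.
#' @param ... Unused.
#' @export
glance.km_fit <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n_subjects"),
    n_events = sum(x$n_event),
    n_censored = sum(x$n_censor),
    median_time = {
      below <- x$time[x$survival <= 0.5]
      if (length(below) == 0) NA_real_ else min(below)
    }
  )
}

#' @rdname kaplan_meier
#' @export
tidy.km_fit <- function(x, ...) tibble::as_tibble(x)

#' @rdname kaplan_meier
#' @export
autoplot.km_fit <- function(x, ...) {
  dat <- tibble::tibble(time = c(0, x$time), survival = c(1, x$survival))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability")
}

#' Two-group log-rank test
#'
#' From-scratch log-rank comparison of two survival curves. At each distinct
#' event time the observed number of events in group A is compared with its
#' hypergeometric expectation given the at-risk counts; the statistic is
#' `(sum O - sum E)^2 / sum V`, referred to a chi-square distribution with
#' 1 degree of freedom.
#'
#' @param group_a,group_b Data frames with columns `day` and `status` as in
#'   [kaplan_meier()].
#' @return A list of class `logrank_test`: `chi_square`, `df`, `p_value`,
#'   `observed` and `expected` events in group A. When neither group has any
#'   event the statistic is undefined and `chi_square`/`p_value` are `NA`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  time <- c(group_a$day, group_b$day)
  event <- c(group_a$status, group_b$status) == "event"
  grp <- rep(c(1L, 2L), c(nrow(group_a), nrow(group_b)))
  res <- logrank_oe(time, event, grp)
  if (res$sum_v == 0) {
    out <- list(chi_square = NA_real_, df = 1L, p_value = NA_real_,
                observed = res$obs, expected = res$exp)
  } else {
    chisq <- (res$obs - res$exp)^2 / res$sum_v
    out <- list(chi_square = chisq, df = 1L,
                p_value = stats::pchisq(chisq, 1, lower.tail = FALSE),
                observed = res$obs, expected = res$exp)
  }
  structure(out, class = "logrank_test")
}

# O, E and hypergeometric variance summed over distinct event times for
# group 1; vectorised so the permutation oracle in the tests stays cheap.
logrank_oe <- function(time, event, grp) {
  ev_times <- sort(unique(time[event]))
  if (length(ev_times) == 0) return(list(obs = 0, exp = 0, sum_v = 0))
  obs <- exp_ <- sum_v <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d <- sum(event & time == tt)
    d1 <- sum(event & time == tt & grp == 1L)
    obs <- obs + d1
    exp_ <- exp_ + d * n1 / n
    if (n > 1) sum_v <- sum_v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(obs = obs, exp = exp_, sum_v = sum_v)
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  cat(sprintf("  group A events: observed %.3g, expected %.3g\n",
              x$observed, x$expected))
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_test`.
#' @param ... Unused.
#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$chi_square, df = x$df, p.value = x$p_value)
}

#' Dunnett-style many-to-one comparisons
#'
#' Compares each treatment group with the shared control using pooled-variance
#' t statistics, with family-wise adjustment against the null distribution of
#' the maximum absolute statistic. Because all comparisons share the control
#' mean and the pooled variance, the statistics are correlated; the adjusted
#' p-value for comparison i is `P(max_j |T_j| >= |t_i|)` under equal means,
#' evaluated by seeded Monte-Carlo sampling of that joint null rather than
#' tabulated quantiles.
#'
#' @param data A data frame with one observation per row.
#' @param value Column holding the measured value (tidy-eval).
#' @param group Column holding the group label (tidy-eval).
#' @param control Label of the control group.
#' @param mc_draws Monte-Carlo draws for the max-|t| null (default 100000).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A tibble with one row per treatment group: `comparison`,
#'   `estimate` (treatment minus control mean), `statistic`, `df`,
#'   `p_adjusted`.
#' @examples
#' df <- data.frame(g = rep(c("ctl", "a", "b"), each = 5),
#'                  y = c(rnorm(5), rnorm(5, 1), rnorm(5, 2)))
#' dunnett_many_to_one(df, y, g, control = "ctl", mc_draws = 20000, seed = 1)
#' @export
dunnett_many_to_one <- function(data, value, group, control,
                                mc_draws = 1e5, seed = NULL) {
  value <- rlang::eval_tidy(rlang::enquo(value), data)
  group <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  if (!control %in% group) stop("control group '", control, "' not found", call. = FALSE)
  groups <- c(control, setdiff(unique(group), control))
  xs <- lapply(groups, function(g) value[group == g])
  ns <- vapply(xs, length, 1L)
  if (any(ns < 2)) stop("every group needs >= 2 observations", call. = FALSE)
  k <- length(groups) - 1L
  nu <- sum(ns) - length(groups)
  s2 <- sum(vapply(xs, function(x) sum((x - mean(x))^2), 1)) / nu
  if (s2 <= 0) stop("pooled variance is zero; statistics undefined", call. = FALSE)
  means <- vapply(xs, mean, 1)
  se <- sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  tstat <- (means[-1] - means[1]) / se

  if (!is.null(seed)) {
    rs <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  # Null joint draw: group means Z_j/sqrt(n_j), pooled SD from chi-square(nu)
  z <- matrix(stats::rnorm(mc_draws * (k + 1)), mc_draws, k + 1)
  z <- sweep(z, 2, sqrt(ns), "/")
  s_mc <- sqrt(stats::rchisq(mc_draws, nu) / nu)
  tmax <- do.call(pmax, lapply(seq_len(k), function(j) {
    abs(z[, j + 1] - z[, 1]) / (s_mc * sqrt(1 / ns[j + 1] + 1 / ns[1]))
  }))
  p_adj <- vapply(abs(tstat), function(tt) mean(tmax >= tt), 1)

  tibble::tibble(comparison = paste(groups[-1], "-", control),
                 estimate = means[-1] - means[1],
                 statistic = tstat, df = nu, p_adjusted = p_adj)
}
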