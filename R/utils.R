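#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @importFrom tibble tibble
NULL

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Lognormal draws with mean `m` and coefficient of variation `cv`
# (cv = 0 degenerates to the mean).
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, length.out = max(n, length(m))))
  sdlog <- sqrt(log(1 + cv^2))
  m * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
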