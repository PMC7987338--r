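#' Siler bathtub mortality parameters
#'
#' The Siler hazard is the sum of a decaying infant-mortality term, a
#' constant term, and an exponentially increasing senescent term:
#' \deqn{h(x) = a_0 e^{-a_1 x} + c + b_0 e^{b_1 x}.}
#' All five parameters are non-negative; `a1`, `b1` are rates (1/years) and
#' `a0`, `c`, `b0` are hazards (1/years). The defaults give a plausible
#' great-ape schedule: moderate infant mortality decaying over the first
#' years, a low background hazard, and senescence from the thirties onward.
#'
#' @param a0,a1 Infant-mortality level and decay rate.
#' @param c Age-independent hazard.
#' @param b0,b1 Senescent-mortality level and rate.
#' @return Object of class `siler_params` (named numeric vector).
#' @export
siler_params <- function(a0 = 0.1, a1 = 1.2, c = 0.01, b0 = 0.002, b1 = 0.12) {
  p <- c(a0 = a0, a1 = a1, c = c, b0 = b0, b1 = b1)
  check_that(all(is.finite(p)) && all(p >= 0),
             "Siler parameters must be finite and non-negative")
  structure(p, class = "siler_params")
}

#' Siler hazard, cumulative hazard, and survival
#'
#' `siler_hazard()` evaluates the hazard at `age`; `siler_cumhaz()` the
#' closed-form integral of the three terms; `siler_survival()` the
#' conditional survival \eqn{S(exit | entry) = \exp(-(H(exit) - H(entry)))}
#' used for left-truncated records.
#'
#' @param params A [siler_params()] object (or compatible named vector).
#' @param age,entry,exit Ages in years (vectors recycle).
#' @return Numeric vector.
#' @export
siler_hazard <- function(params, age) {
  check_that(all(age >= 0), "age must be non-negative")
  params[["a0"]] * exp(-params[["a1"]] * age) + params[["c"]] +
    params[["b0"]] * exp(params[["b1"]] * age)
}

#' @rdname siler_hazard
#' @export
siler_cumhaz <- function(params, age) {
  check_that(all(age >= 0), "age must be non-negative")
  a0 <- params[["a0"]]; a1 <- params[["a1"]]
  b0 <- params[["b0"]]; b1 <- params[["b1"]]
  infant <- if (a1 > 0) a0 / a1 * (1 - exp(-a1 * age)) else a0 * age
  senesc <- if (b1 > 0) b0 / b1 * (exp(b1 * age) - 1) else b0 * age
  infant + params[["c"]] * age + senesc
}

#' @rdname siler_hazard
#' @export
siler_survival <- function(params, entry, exit) {
  check_that(all(exit >= entry), "exit must be >= entry")
  exp(-(siler_cumhaz(params, exit) - siler_cumhaz(params, entry)))
}

#' Draw lifespans from a Siler law
#'
#' Inverse-CDF sampling via root finding on the closed-form cumulative
#' hazard, conditional on survival to `entry` (left truncation). A
#' log-hazard-ratio shifts the whole hazard proportionally, which is how the
#' generator injects orphan-class effects on survival.
#'
#' @param n Number of draws.
#' @param params [siler_params()].
#' @param entry Entry age(s), recycled to length `n`.
#' @param log_hr Proportional log-hazard-ratio applied to the hazard.
#' @param seed Optional integer seed.
#' @return Numeric vector of ages at death (all `> entry`).
#' @export
simulate_lifespans <- function(n, params = siler_params(), entry = 0,
                               log_hr = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  entry <- rep_len(entry, n)
  hr <- exp(log_hr)
  u <- stats::runif(n)
  target <- siler_cumhaz(params, entry) - log(u) / hr
  vapply(seq_len(n), function(i) {
    f <- function(t) siler_cumhaz(params, t) - target[i]
    hi <- max(entry[i] + 1, 10)
    while (f(hi) < 0 && hi < 1e4) hi <- hi * 2
    if (f(hi) < 0) return(hi)  # hazard effectively zero; cap
    stats::uniroot(f, c(entry[i], hi), tol = 1e-10)$root
  }, numeric(1))
}
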