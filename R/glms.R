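#' Binomial GLM with Wald inference
#'
#' Logistic regression by iteratively reweighted least squares, for binary
#' outcomes or grouped successes/totals, with Wald standard errors from the
#' observed information and normal-based two-sided p-values. Coefficients
#' whose magnitude diverges are flagged as complete separation with a
#' warning.
#'
#' @param formula Model formula; for grouped data use
#'   `cbind(successes, failures)` on the left-hand side.
#' @param data Data.frame.
#' @return Object of class `sb_glm`: `coefficients`, `se`, `z`, `p`
#'   (named vectors), `family`, `n` (observation/group count),
#'   `separation` flag, and the underlying [stats::glm()] fit.
#' @export
fit_binomial_glm <- function(formula, data) {
  fit <- stats::glm(formula, data = data, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  sb_glm(fit, "binomial-logit")
}

# internal: wrap a glm/lm fit into the package's coefficient container
sb_glm <- function(fit, family) {
  s <- summary(fit)$coefficients
  est <- s[, 1]; se <- s[, 2]; z <- s[, 3]
  p <- if (family == "binomial-logit") 2 * stats::pnorm(-abs(z)) else s[, 4]
  sep <- family == "binomial-logit" && any(abs(est) > 15 | se > 100)
  if (sep) {
    warning("complete separation suspected: diverging coefficient capped in report")
    est <- pmin(pmax(est, -20), 20)
  }
  structure(list(coefficients = est, se = se, z = z, p = p, family = family,
                 n = stats::nobs(fit), separation = sep, model = fit),
            class = "sb_glm")
}

#' @export
print.sb_glm <- function(x, ...) {
  cat(sprintf("GLM (%s), n = %d%s\n", x$family, x$n,
              if (x$separation) " [separation flagged]" else ""))
  print(data.frame(est = x$coefficients, se = x$se, z = x$z, p = x$p),
        digits = 3)
  invisible(x)
}

#' Gaussian GLM for age at first birth
#'
#' Age at first birth is strongly right-skewed; the response is
#' `sqrt(age_first_birth - 8)` (8 years being the earliest recorded age at
#' first birth), modelled on orphan class (juvenile and subadult merged)
#' and whether the female dispersed before first birth.
#'
#' @param data Data.frame with `age_first_birth`, `class` (factor:
#'   non_orphan / infant / juv_subadult), `dispersed` (0/1).
#' @return `sb_glm` (Gaussian; t-based p-values).
#' @export
fit_age_first_birth <- function(data) {
  check_that(all(data$age_first_birth > 8),
             "sqrt(age - 8) transform requires ages > 8")
  data$resp <- sqrt(data$age_first_birth - 8)
  fit <- stats::glm(resp ~ class + dispersed, data = data,
                    family = stats::gaussian())
  sb_glm(fit, "gaussian-identity")
}

#' Binomial GLM for first-offspring infant survival
#'
#' Whether a female's first offspring survived infancy (to 4 years),
#' modelled on the mother's age at first birth, dispersal before first
#' birth, and her own orphan class (juvenile/subadult merged).
#'
#' @param data Data.frame with `survived` (0/1), `age_first_birth`,
#'   `dispersed` (0/1), `class`.
#' @return `sb_glm`.
#' @export
fit_first_offspring_survival <- function(data) {
  fit_binomial_glm(survived ~ age_first_birth + dispersed + class, data)
}

#' Dominance attainment proportions by orphan class
#'
#' Among males that survived and remained in the study population to at
#' least 23 years (the oldest observed age of first dominance), the
#' proportion per orphan class that held dominant-male status of a stable
#' group for at least six consecutive months. Two short tenures do not sum:
#' the six months must be consecutive. No statistical test is attached;
#' with a handful of orphaned males per class these are descriptive
#' proportions only.
#'
#' @param males Data.frame with `id`, `class` (orphan class), and
#'   `present_to_age` (age in years to which the male survived and remained
#'   in the population).
#' @param tenures Data.frame with `id`, `start`, `end` (Dates) of dominance
#'   tenure intervals.
#' @param min_age Survivorship cut-off in years (default 23).
#' @param min_days Minimum consecutive tenure length (default 182.5 days,
#'   six months).
#' @return Data.frame `class`, `n`, `n_dominant`, `proportion`.
#' @export
dominance_attainment_summary <- function(males, tenures, min_age = 23,
                                         min_days = 182.5) {
  eligible <- males[males$present_to_age >= min_age, ]
  score <- vapply(eligible$id, function(i) {
    tn <- tenures[tenures$id == i, , drop = FALSE]
    if (nrow(tn) == 0) return(0L)
    len <- as.numeric(as.Date(tn$end) - as.Date(tn$start))
    as.integer(any(len >= min_days))
  }, integer(1))
  agg <- stats::aggregate(score, by = list(class = eligible$class),
                          FUN = function(v) c(n = length(v), d = sum(v)))
  data.frame(class = agg$class,
             n = agg$x[, "n"], n_dominant = agg$x[, "d"],
             proportion = agg$x[, "d"] / agg$x[, "n"],
             stringsAsFactors = FALSE)
}

#' Published natal-dispersal counts by orphan class
#'
#' Class-level dispersal summaries from the Karisoke long-term mountain
#' gorilla records, reconstructed as grouped counts from the published
#' class percentages and sample sizes: among females, 37.5% of 32
#' non-orphans, 54.5% of 11 infant orphans, and 75.0% of 8
#' juvenile/subadult orphans dispersed before their first birth (12/32,
#' 6/11, 6/8); among males reaching 16 years, 37.5% of 40 non-orphans and
#' 84.6% of 13 juvenile/subadult orphans dispersed before 16 (15/40,
#' 11/13). Only three males orphaned as infants reached 16 (none
#' dispersed), too few to model, so the male design carries a single
#' juvenile/subadult dummy.
#'
#' @return List with data.frames `female` and `male`, each with `class`,
#'   `dispersed`, `total`.
#' @export
gorilla_dispersal_counts <- function() {
  list(
    female = data.frame(
      class = factor(c("non_orphan", "infant", "juv_subadult"),
                     levels = c("non_orphan", "infant", "juv_subadult")),
      dispersed = c(12L, 6L, 6L), total = c(32L, 11L, 8L)),
    male = data.frame(
      class = factor(c("non_orphan", "juv_subadult"),
                     levels = c("non_orphan", "juv_subadult")),
      dispersed = c(15L, 11L), total = c(40L, 13L)))
}

#' Dispersal GLMs on grouped class counts
#'
#' Convenience wrapper fitting the female and male natal-dispersal
#' logistic models on grouped counts (see [gorilla_dispersal_counts()] for
#' the packaged reference counts).
#'
#' @param counts Data.frame with `class`, `dispersed`, `total`.
#' @return `sb_glm`.
#' @export
fit_dispersal_glm <- function(counts) {
  counts$stayed <- counts$total - counts$dispersed
  fit_binomial_glm(cbind(dispersed, stayed) ~ class, counts)
}
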