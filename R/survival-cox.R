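#' Left-truncated survival records from a roster
#'
#' Builds per-individual survival records for the age range from 2 years
#' on: individuals dying before age 2 are excluded, everyone enters the
#' risk set at age 2, exits at death or censoring (study end or permanent
#' disappearance), and carries the age at maternal loss (NA for
#' non-orphans) from which the time-varying orphan-class covariate is
#' derived.
#'
#' @param roster Roster data.frame (`id`, `sex`, `birth_date`,
#'   `death_date` with NA = alive/censored).
#' @param orphan_table Orphan table (`id`, `age_at_loss`); individuals
#'   absent from it are non-orphans.
#' @param study_end Censoring date.
#' @return Data.frame with `id`, `sex`, `entry`, `exit`, `event`,
#'   `loss_age`, `class` (four-level orphan class).
#' @export
build_survival_records <- function(roster, orphan_table, study_end) {
  study_end <- as.Date(study_end)
  exit_date <- roster$death_date
  event <- !is.na(exit_date) & exit_date <= study_end
  exit_date[!event] <- study_end
  exit <- years_between(roster$birth_date, exit_date)
  keep <- exit > 2
  r <- roster[keep, ]
  exit <- exit[keep]; event <- event[keep]
  loss_age <- orphan_table$age_at_loss[match(r$id, orphan_table$id)]
  out <- data.frame(id = r$id, sex = r$sex, entry = 2, exit = exit,
                    event = as.integer(event), loss_age = loss_age,
                    class = orphan_class(loss_age),
                    stringsAsFactors = FALSE)
  check_that(all(out$exit > out$entry), "exit before entry")
  rownames(out) <- NULL
  out
}

# internal: episode-split records at the age of maternal loss so the orphan
# class enters the Cox model as a time-varying covariate
episode_split <- function(records, merge_juv_subadult = FALSE) {
  cls <- as.character(orphan_class(records$loss_age, merge_juv_subadult))
  pre <- post <- NULL
  switches <- !is.na(records$loss_age) & records$loss_age > records$entry &
    records$loss_age < records$exit
  # pre-loss episodes (non-orphan state)
  pre <- data.frame(id = records$id,
                    start = records$entry,
                    stop = ifelse(switches, records$loss_age, records$exit),
                    event = ifelse(switches, 0L, records$event),
                    class = ifelse(switches, "non_orphan",
                                   ifelse(is.na(records$loss_age) |
                                            records$loss_age >= records$exit,
                                          "non_orphan", cls)),
                    stringsAsFactors = FALSE)
  # individuals orphaned at or before entry carry their class from entry
  pre$class[!is.na(records$loss_age) & records$loss_age <= records$entry] <-
    cls[!is.na(records$loss_age) & records$loss_age <= records$entry]
  post <- data.frame(id = records$id[switches],
                     start = records$loss_age[switches],
                     stop = records$exit[switches],
                     event = records$event[switches],
                     class = cls[switches], stringsAsFactors = FALSE)
  ep <- rbind(pre, post)
  lev <- if (merge_juv_subadult) c("non_orphan", "infant", "juv_subadult")
         else c("non_orphan", "infant", "juvenile", "subadult")
  ep$class <- factor(ep$class, levels = lev)
  ep[order(ep$id, ep$start), ]
}

#' Cox proportional hazards with a time-varying orphan-class covariate
#'
#' Partial-likelihood estimation (Efron tie handling) of the log-hazard of
#' each orphan class relative to non-orphans, with each orphan's record
#' episode-split at the age of maternal loss so the class switches on at
#' loss. Coefficients with very large magnitude are flagged as monotone
#' likelihood (complete separation).
#'
#' @param records [build_survival_records()] output (typically one sex).
#' @param class_coding `"four"` (infant/juvenile/subadult) or `"merged"`
#'   (infant/juv_subadult).
#' @return List of class `cox_fit`: `coefficients` (term, est, se, z, p),
#'   `n`, `n_events`, `separation` flag, and the underlying
#'   [survival::coxph()] object.
#' @export
fit_cox_ph <- function(records, class_coding = c("four", "merged")) {
  class_coding <- match.arg(class_coding)
  check_that(sum(records$event) > 0, "no events in records")
  ep <- episode_split(records, merge_juv_subadult = class_coding == "merged")
  fit <- survival::coxph(
    survival::Surv(start, stop, event) ~ class, data = ep,
    ties = "efron",
    control = survival::coxph.control(eps = 1e-11, toler.chol = 1e-13,
                                      iter.max = 100))
  s <- summary(fit)$coefficients
  co <- data.frame(term = rownames(s), est = s[, "coef"],
                   se = s[, "se(coef)"], z = s[, "z"],
                   p = s[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  rownames(co) <- NULL
  sep <- any(abs(co$est) > 10, na.rm = TRUE)
  if (sep) warning("monotone partial likelihood suspected (|coef| > 10)")
  structure(list(coefficients = co, n = nrow(records),
                 n_events = sum(records$event), separation = sep,
                 model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH, time-varying orphan class (n = %d, events = %d)\n",
              x$n, x$n_events))
  print(x$coefficients, digits = 3)
  invisible(x)
}
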