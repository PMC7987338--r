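#' Derive a reproducible sub-stream seed
#'
#' All generators in the package consume one global integer seed; independent
#' sub-streams (per module, per entity) are derived by stable hashing of a
#' character key so that adding one simulation stage never perturbs another.
#'
#' @param seed Integer master seed.
#' @param key Character scalar naming the sub-stream.
#' @return An integer in `[0, 2^31 - 2]` suitable for `set.seed()`.
#' @export
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key),
            length(key) == 1L)
  cp <- utf8ToInt(key)
  h <- 0
  for (v in cp) h <- (h * 131 + v) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 69069 + h) %% 2147483629)
}

# internal: decimal years between two Dates (365.25-day years)
years_between <- function(from, to) {
  as.numeric(difftime(as.Date(to), as.Date(from), units = "days")) / 365.25
}

# internal: assertion helper with a terse message
check_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Age class at maternal loss
#'
#' Bins age at maternal loss into the orphan classes used throughout:
#' infant `[2, 4)`, juvenile `[4, 6)`, subadult `[6, 8)`. Ages outside
#' `[2, 8)` return `"non_orphan"` (losses outside the immature window are
#' not treated as orphaning events).
#'
#' @param age_at_loss Numeric vector of ages in years (NA = mother survived).
#' @param merge_juv_subadult Merge juvenile and subadult into one class.
#' @return Factor with reference level `"non_orphan"`.
#' @export
orphan_class <- function(age_at_loss, merge_juv_subadult = FALSE) {
  cls <- rep("non_orphan", length(age_at_loss))
  ok <- !is.na(age_at_loss)
  cls[ok & age_at_loss >= 2 & age_at_loss < 4] <- "infant"
  cls[ok & age_at_loss >= 4 & age_at_loss < 6] <- "juvenile"
  cls[ok & age_at_loss >= 6 & age_at_loss < 8] <- "subadult"
  if (merge_juv_subadult) {
    cls[cls %in% c("juvenile", "subadult")] <- "juv_subadult"
    levels <- c("non_orphan", "infant", "juv_subadult")
  } else {
    levels <- c("non_orphan", "infant", "juvenile", "subadult")
  }
  factor(cls, levels = levels)
}

#' Age-sex class of a group member
#'
#' Field convention: infants up to 4 years, juveniles 4-6, subadults 6-8
#' (split by sex), females adult from 8, males blackback 8-12 then adult,
#' with adult males split into the single dominant male versus subordinates.
#'
#' @param age Numeric age in years.
#' @param sex `"F"` or `"M"`.
#' @param dominant Logical; is this the group's dominant male?
#' @return Factor with reference level `"dominant_male"`.
#' @export
age_sex_class <- function(age, sex, dominant = FALSE) {
  n <- max(length(age), length(sex), length(dominant))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  dominant <- rep_len(dominant, n)
  cls <- character(n)
  cls[age < 4] <- "infant"
  cls[age >= 4 & age < 6] <- "juvenile"
  cls[age >= 6 & age < 8] <- ifelse(sex[age >= 6 & age < 8] == "M",
                                    "subadult_male", "subadult_female")
  cls[age >= 8 & sex == "F"] <- "adult_female"
  cls[age >= 8 & age < 12 & sex == "M"] <- "blackback"
  adult_m <- age >= 12 & sex == "M"
  cls[adult_m] <- ifelse(dominant[adult_m], "dominant_male", "subordinate_male")
  factor(cls, levels = c("dominant_male", "subordinate_male", "adult_female",
                         "blackback", "subadult_male", "subadult_female",
                         "juvenile", "infant"))
}
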