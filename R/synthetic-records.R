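#' Simulate node-level change records at the study's scale
#'
#' Generates the per-individual change-in-network-position table that the
#' permutation machinery consumes, directly at the level of the fitted
#' model: an incident random intercept, mild age and regression-to-the-mean
#' (deviance) effects, a weak smooth sampling-effort effect, an additive
#' orphan effect, and Gaussian residual noise. Defaults reproduce the
#' study's sampling frame: 19 maternal-loss incidents, 28 orphans, 108
#' non-orphan immatures, roughly 290 focal scans per individual over the
#' two 183-day windows, and noise scaled so the orphan coefficient's
#' standard error is near 0.03 on the SRI-change scale.
#'
#' @param n_incidents,n_orphans,n_non_orphans Sampling frame sizes.
#' @param orphan_effect Additive effect of orphan status on the metric
#'   change (0 = null generator).
#' @param sd_incident,sd_resid Incident random-intercept and residual SDs.
#' @param seed Integer seed.
#' @return Data.frame with columns `incident`, `node`, `orphan` (logical),
#'   `age`, `deviance`, `total_scans`, `delta`.
#' @export
simulate_change_records <- function(n_incidents = 19, n_orphans = 28,
                                    n_non_orphans = 108, orphan_effect = 0,
                                    sd_incident = 0.05, sd_resid = 0.15,
                                    seed = 1L) {
  check_that(n_incidents >= 2 && n_orphans >= n_incidents &&
               n_non_orphans >= n_incidents,
             "each incident needs at least one orphan and one non-orphan")
  set.seed(substream_seed(seed, "change_records"))
  # every incident gets >= 1 of each; remainder allocated at random
  inc_orph <- rep(1L, n_incidents)
  extra <- stats::rmultinom(1, n_orphans - n_incidents,
                            rep(1, n_incidents))[, 1]
  inc_orph <- inc_orph + extra
  inc_non <- rep(1L, n_incidents)
  extra <- stats::rmultinom(1, n_non_orphans - n_incidents,
                            rep(1, n_incidents))[, 1]
  inc_non <- inc_non + extra
  inc_id <- sprintf("I%02d", seq_len(n_incidents))
  incident <- rep(inc_id, inc_orph + inc_non)
  orphan <- unlist(lapply(seq_len(n_incidents), function(i)
    c(rep(TRUE, inc_orph[i]), rep(FALSE, inc_non[i]))))
  n <- length(orphan)
  age <- stats::runif(n, 2, 8)
  deviance <- stats::rnorm(n, 0, 0.15)
  total_scans <- pmax(26L, round(stats::rnorm(n, 290, 90)))
  b_inc <- stats::rnorm(n_incidents, 0, sd_incident)
  delta <- b_inc[match(incident, inc_id)] -
    0.005 * (age - 5) - 0.3 * deviance +
    0.0001 * (total_scans - 290) +
    orphan_effect * orphan +
    stats::rnorm(n, 0, sd_resid)
  data.frame(incident = incident,
             node = sprintf("N%03d", seq_len(n)),
             orphan = orphan, age = age, deviance = deviance,
             total_scans = total_scans, delta = delta,
             stringsAsFactors = FALSE)
}

#' Simulate dyadic relationship-change records
#'
#' Generates the immature-by-partner table of SRI changes that the dyadic
#' models consume, with known additive effects so that coefficient recovery
#' can be verified. Each immature contributes one record per group member;
#' partner age-sex classes are drawn with frequencies typical of a gorilla
#' group (one dominant male, few subordinate males, many adult females and
#' immatures). Orphans receive `class_effects` (by partner class),
#' `age_mate_effect`, and `sibling_effects` additively on the SRI change;
#' non-orphans are unaffected.
#'
#' @param n_orphans,n_non_orphans Number of immatures of each status.
#' @param n_incidents Number of maternal-loss incidents (groups).
#' @param partners_per Mean number of partners per immature.
#' @param class_effects Named numeric: additive orphan effect per partner
#'   age-sex class (default all zero).
#' @param age_mate_effect,sibling_effect Additive orphan effects for
#'   age-mates and maternal siblings.
#' @param paternity_effect Additive orphan effect for genetic fathers
#'   (adult-male partners only).
#' @param sd_immature,sd_partner,sd_resid Random-effect and residual SDs.
#' @param seed Integer seed.
#' @return Data.frame matching [build_dyad_table()]'s columns.
#' @export
simulate_dyad_records <- function(n_orphans = 31, n_non_orphans = 51,
                                  n_incidents = 19, partners_per = 24,
                                  class_effects = numeric(0),
                                  age_mate_effect = 0, sibling_effect = 0,
                                  paternity_effect = 0,
                                  sd_immature = 0.01, sd_partner = 0.01,
                                  sd_resid = 0.05, seed = 1L) {
  set.seed(substream_seed(seed, "dyad_records"))
  classes <- c("dominant_male", "subordinate_male", "adult_female",
               "blackback", "subadult_male", "subadult_female",
               "juvenile", "infant")
  class_w <- c(1, 1.5, 6, 1, 1.5, 1.5, 3, 3)
  imm_inc <- sort(rep_len(seq_len(n_incidents), n_orphans + n_non_orphans))
  n_imm <- n_orphans + n_non_orphans
  orphan <- rep(c(TRUE, FALSE), c(n_orphans, n_non_orphans))[
    sample(n_imm)]
  imm_id <- sprintf("IM%03d", seq_len(n_imm))
  b_imm <- stats::rnorm(n_imm, 0, sd_immature)
  rows <- vector("list", n_imm)
  for (i in seq_len(n_imm)) {
    np <- max(4, stats::rpois(1, partners_per))
    pcls <- sample(classes, np, replace = TRUE, prob = class_w)
    # exactly one dominant male per group: force first partner
    pcls[1] <- "dominant_male"
    partner <- sprintf("G%02d_%s%02d", imm_inc[i],
                       toupper(substr(pcls, 1, 2)), seq_len(np))
    partner[1] <- sprintf("G%02d_DOM", imm_inc[i])
    age <- stats::runif(1, 2, 8)
    page <- stats::runif(np, 0, 35)
    page[pcls == "infant"] <- stats::runif(sum(pcls == "infant"), 0, 4)
    page[pcls == "juvenile"] <- stats::runif(sum(pcls == "juvenile"), 4, 6)
    age_mate <- abs(page - age) < 2
    sibling <- stats::runif(np) < 0.12
    father <- pcls %in% c("dominant_male", "subordinate_male") &
      stats::runif(np) < ifelse(pcls == "dominant_male", 0.5, 0.1)
    mean_scans <- pmax(13, round(stats::rnorm(np, 145, 45)))
    eff <- rep(0, np)
    if (orphan[i]) {
      hit <- pcls %in% names(class_effects)
      eff[hit] <- eff[hit] + unlist(class_effects[pcls[hit]])
      eff <- eff + age_mate_effect * age_mate + sibling_effect * sibling +
        paternity_effect * father
    }
    delta <- b_imm[i] + stats::rnorm(np, 0, sd_partner) + eff -
      0.002 * (age - 5) + stats::rnorm(np, 0, sd_resid)
    rows[[i]] <- data.frame(
      incident = sprintf("I%02d", imm_inc[i]),
      group = sprintf("G%02d", imm_inc[i]),
      immature = imm_id[i], partner = partner, orphan = orphan[i],
      immature_age = age, immature_sex = sample(c("F", "M"), 1),
      partner_class = pcls, age_mate = age_mate, sibling = sibling,
      father = father, mean_scans = mean_scans, delta_sri = delta,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$partner_class <- factor(out$partner_class, levels = classes)
  rownames(out) <- NULL
  out
}
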