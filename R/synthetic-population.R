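#' Orphan-effect configuration for the synthetic generator
#'
#' Additive changes applied to latent per-scan association probabilities of
#' an orphan's dyads after maternal loss. Effects are additive on the
#' probability scale so that they map one-to-one onto expected SRI changes.
#' An all-zero configuration is the null model.
#'
#' @param boost_by_class Named numeric: additive probability change per
#'   partner age-sex class (levels of [age_sex_class()]); unnamed classes
#'   default to 0.
#' @param age_mate_boost Additive change for partners within 2 years of age.
#' @param sibling_boost_by_class Named numeric: extra additive change for
#'   maternal siblings, by the sibling's age-sex class.
#' @return Object of class `orphan_effects`.
#' @export
orphan_effects <- function(boost_by_class = numeric(0), age_mate_boost = 0,
                           sibling_boost_by_class = numeric(0)) {
  check_that(is.numeric(age_mate_boost) && length(age_mate_boost) == 1L,
             "age_mate_boost must be a single number")
  structure(list(boost_by_class = boost_by_class,
                 age_mate_boost = age_mate_boost,
                 sibling_boost_by_class = sibling_boost_by_class),
            class = "orphan_effects")
}

#' Synthetic population configuration
#'
#' Parameters of [simulate_population()]. Defaults emulate the scale of a
#' long-term mountain gorilla monitoring programme: several habituated
#' groups of 18-30 animals, an even sex ratio, a Siler lifespan law, and one
#' maternal-loss incident per group leaving orphans aged 2-8.
#'
#' @param n_groups Number of social groups (each contributes one incident).
#' @param group_size_range Length-2 integer range of group sizes (min 3).
#' @param sex_ratio Probability an individual is female.
#' @param siler [siler_params()] governing lifespans.
#' @param orphan_effects [orphan_effects()] applied to post-loss networks.
#' @param orphan_hazard_log_hr Named or scalar log-hazard-ratio applied to
#'   orphans' post-loss mortality (0 = no survival effect).
#' @param dispersal_logit Named numeric: `intercept` plus per-orphan-class
#'   log-odds offsets for natal dispersal (classes merged as
#'   infant / juv_subadult).
#' @param mother_transfer If `TRUE` mothers permanently transfer out rather
#'   than die; network consequences are identical, the mother is censored
#'   rather than dead in the demographic table.
#' @param study_start,study_years Monitoring window (ISO date, years).
#' @param seed Master integer seed; fixes the full output stream.
#' @return Object of class `population_config`.
#' @export
population_config <- function(n_groups = 7,
                              group_size_range = c(18, 30),
                              sex_ratio = 0.5,
                              siler = siler_params(),
                              orphan_effects = socbuffer::orphan_effects(),
                              orphan_hazard_log_hr = 0,
                              dispersal_logit = c(intercept = log(0.6),
                                                  infant = 0,
                                                  juv_subadult = 0),
                              mother_transfer = FALSE,
                              study_start = "2005-01-01",
                              study_years = 6,
                              seed = 1L) {
  check_that(length(group_size_range) == 2L &&
               group_size_range[1] >= 3 &&
               group_size_range[2] >= group_size_range[1],
             "group sizes must be >= 3 (no non-orphan immatures possible below that)")
  check_that(sex_ratio >= 0 && sex_ratio <= 1, "sex_ratio must be in [0,1]")
  check_that(n_groups >= 1, "need at least one group")
  check_that(inherits(siler, "siler_params"), "siler must be siler_params()")
  structure(list(n_groups = n_groups, group_size_range = group_size_range,
                 sex_ratio = sex_ratio, siler = siler,
                 orphan_effects = orphan_effects,
                 orphan_hazard_log_hr = orphan_hazard_log_hr,
                 dispersal_logit = dispersal_logit,
                 mother_transfer = mother_transfer,
                 study_start = as.Date(study_start),
                 study_years = study_years, seed = seed),
            class = "population_config")
}

#' Simulate a monitored population with maternal-loss incidents
#'
#' Generates a roster of individuals in `n_groups` groups, each with one
#' dominant adult male, subordinate males, adult females, and immatures with
#' known mothers; one maternal-loss incident per group (death or permanent
#' transfer of a mother with at least one offspring aged 2-8 and at least
#' one unrelated immature aged 2-8 in the group); Siler-distributed ages at
#' death with an optional proportional hazard effect on orphans after loss;
#' and per-individual paternity labels (the dominant male with probability
#' 0.67 among known paternities, unknown otherwise).
#'
#' @param config A [population_config()].
#' @return List with elements `roster` (data.frame: id, group, sex,
#'   birth_date, death_date (NA = alive at study end), mother_id, father_id,
#'   dominant), `incidents` (data.frame: incident, group, date, mother),
#'   `orphans` (data.frame: incident, id, age_at_loss, class), and
#'   `study_end` (Date).
#' @export
simulate_population <- function(config) {
  check_that(inherits(config, "population_config"), "need a population_config")
  set.seed(substream_seed(config$seed, "population"))
  start <- config$study_start
  study_end <- start + round(config$study_years * 365.25)
  rosters <- list(); incidents <- list(); orphan_rows <- list()
  for (g in seq_len(config$n_groups)) {
    size <- sample(seq(config$group_size_range[1], config$group_size_range[2]), 1)
    gid <- sprintf("G%02d", g)
    # composition: ~15% adult males (first dominant), ~35% adult females,
    # remainder immatures aged 0-8 at the incident date
    n_am <- max(1, round(size * 0.15))
    n_af <- max(2, round(size * 0.35))
    n_im <- max(3, size - n_am - n_af)
    # incident midway through the study so both 183-day windows are covered
    inc_date <- start + round(365.25 * stats::runif(1, 1.2, config$study_years - 1.2))
    # ages at incident date; ensure >=2 immatures in [2.2, 7.8] so an orphan
    # and a non-orphan immature both exist
    age_im <- stats::runif(n_im, 0.5, 7.9)
    age_im[1] <- stats::runif(1, 2.2, 3.9)   # guaranteed orphan-age offspring
    age_im[2] <- stats::runif(1, 2.2, 7.8)   # guaranteed non-orphan immature
    age_af <- stats::runif(n_af, 12, 30)
    age_am <- stats::runif(n_am, 13, 28)
    id <- c(sprintf("%s_AM%02d", gid, seq_len(n_am)),
            sprintf("%s_AF%02d", gid, seq_len(n_af)),
            sprintf("%s_IM%02d", gid, seq_len(n_im)))
    sex <- c(rep("M", n_am), rep("F", n_af),
             ifelse(stats::runif(n_im) < config$sex_ratio, "F", "M"))
    age_at_inc <- c(age_am, age_af, age_im)
    birth <- inc_date - round(age_at_inc * 365.25)
    dominant <- c(TRUE, rep(FALSE, n_am - 1), rep(FALSE, n_af + n_im))
    af_ids <- id[(n_am + 1):(n_am + n_af)]
    # mother of immature 1 is the dying mother; immature 2 gets a different one
    dying_mother <- af_ids[1]
    mother_id <- c(rep("unknown", n_am + n_af),
                   sample(af_ids, n_im, replace = TRUE))
    mother_id[n_am + n_af + 1] <- dying_mother
    if (length(af_ids) > 1) {
      mother_id[n_am + n_af + 2] <- sample(af_ids[-1], 1)
    }
    # paternity: known with p ~ 0.6; known fathers are the dominant male with
    # p = 0.67, else a random subordinate (or dominant if none)
    father_id <- rep("unknown", length(id))
    imm_idx <- (n_am + n_af + 1):length(id)
    known <- stats::runif(n_im) < 0.6
    dom_id <- id[1]
    sub_ids <- if (n_am > 1) id[2:n_am] else dom_id
    father_id[imm_idx] <- ifelse(known,
      ifelse(stats::runif(n_im) < 0.67, dom_id,
             sample(sub_ids, n_im, replace = TRUE)),
      "unknown")
    # lifespans: everyone alive at incident date by construction; draw death
    # age conditional on age at incident
    death_age <- simulate_lifespans(length(id), config$siler,
                                    entry = pmax(age_at_inc, 1e-6))
    # orphans of the dying mother, aged 2-8 at the incident
    is_orphan <- mother_id == dying_mother &
      age_at_inc >= 2 & age_at_inc < 8
    # optional post-loss hazard effect on orphans
    if (any(is_orphan) && any(config$orphan_hazard_log_hr != 0)) {
      idx <- which(is_orphan)
      death_age[idx] <- simulate_lifespans(length(idx), config$siler,
                                           entry = age_at_inc[idx],
                                           log_hr = config$orphan_hazard_log_hr[1])
    }
    death_date <- birth + round(death_age * 365.25)
    # the chosen mother dies (or transfers) at the incident date
    mi <- match(dying_mother, id)
    death_date[mi] <- inc_date
    died <- death_date <= study_end
    if (config$mother_transfer) died[mi] <- FALSE  # censored, not dead
    roster <- data.frame(
      id = id, group = gid, sex = sex,
      birth_date = birth,
      death_date = as.Date(ifelse(died, death_date, NA), origin = "1970-01-01"),
      mother_id = mother_id, father_id = father_id,
      dominant = dominant, stringsAsFactors = FALSE)
    rosters[[g]] <- roster
    inc_id <- sprintf("I%02d", g)
    incidents[[g]] <- data.frame(incident = inc_id, group = gid,
                                 date = inc_date, mother = dying_mother,
                                 stringsAsFactors = FALSE)
    if (any(is_orphan)) {
      orphan_rows[[g]] <- data.frame(
        incident = inc_id, id = id[is_orphan],
        age_at_loss = age_at_inc[is_orphan],
        class = as.character(orphan_class(age_at_inc[is_orphan])),
        stringsAsFactors = FALSE)
    }
  }
  list(roster = do.call(rbind, rosters),
       incidents = do.call(rbind, incidents),
       orphans = do.call(rbind, orphan_rows),
       study_end = study_end)
}

#' Simulate binary dispersal outcomes
#'
#' Bernoulli natal-dispersal outcomes with log-odds = intercept +
#' orphan-class offset. Offsets are capped at +/- 20 so that extreme
#' configurations degrade gracefully to probability 0/1.
#'
#' @param classes Factor/character of orphan classes (`non_orphan`,
#'   `infant`, `juv_subadult`).
#' @param logit_params Named numeric with `intercept` and per-class offsets
#'   (missing class names mean offset 0).
#' @param seed Integer seed.
#' @return Data.frame with `class`, `p`, `dispersed` (0/1).
#' @export
simulate_dispersal <- function(classes, logit_params, seed = 1L) {
  check_that("intercept" %in% names(logit_params),
             "logit_params must contain 'intercept'")
  set.seed(substream_seed(seed, "dispersal"))
  classes <- as.character(classes)
  off <- vapply(classes, function(cl) {
    if (cl %in% names(logit_params)) logit_params[[cl]] else 0
  }, numeric(1))
  eta <- pmin(pmax(logit_params[["intercept"]] + off, -20), 20)
  p <- stats::plogis(eta)
  data.frame(class = classes, p = p,
             dispersed = as.integer(stats::runif(length(p)) < p),
             stringsAsFactors = FALSE)
}
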