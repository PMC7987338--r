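# File schemata and the end-to-end driver.
#
# All tables are UTF-8 CSV with a header row; dates are ISO-8601; partner
# sets in scan files are ';'-separated id lists; ages are decimal years
# (365.25-day years).

#' Read and validate a demographic roster CSV
#'
#' Columns: `id`, `group`, `sex` (F/M), `birth_date`, `death_date` (empty =
#' alive/censored), `mother_id` (`unknown` allowed), `father_id`,
#' `dominant` (TRUE/FALSE). Validation errors name the offending row.
#'
#' @param path CSV path.
#' @return Roster data.frame with Date columns.
#' @export
read_demography <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("id", "group", "sex", "birth_date", "death_date", "mother_id",
            "father_id", "dominant")
  missing <- setdiff(need, names(r))
  check_that(length(missing) == 0,
             paste("missing roster columns:", paste(missing, collapse = ", ")))
  parse_date <- function(x, col) {
    out <- as.Date(x, format = "%Y-%m-%d")
    bad <- which(!is.na(x) & nzchar(x) & is.na(out))
    check_that(length(bad) == 0,
               sprintf("malformed date in column '%s', row %d: '%s'",
                       col, bad[1], x[bad[1]]))
    out
  }
  r$birth_date <- parse_date(r$birth_date, "birth_date")
  r$death_date <- parse_date(r$death_date, "death_date")
  r$dominant <- as.logical(r$dominant)
  bad_sex <- which(!r$sex %in% c("F", "M"))
  check_that(length(bad_sex) == 0,
             sprintf("invalid sex in row %d: '%s'", bad_sex[1], r$sex[bad_sex[1]]))
  known <- c(r$id, "unknown")
  bad_mom <- which(!r$mother_id %in% known)
  check_that(length(bad_mom) == 0,
             sprintf("unknown mother_id in row %d: '%s'",
                     bad_mom[1], r$mother_id[bad_mom[1]]))
  r
}

#' @rdname read_demography
#' @param roster Roster data.frame.
#' @export
write_roster <- function(roster, path) {
  out <- roster
  out$birth_date <- format(out$birth_date, "%Y-%m-%d")
  out$death_date <- ifelse(is.na(roster$death_date), "",
                           format(roster$death_date, "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a focal-scan CSV
#'
#' Columns: `date`, `group`, `focal`, `proximity_partners`,
#' `contact_partners` (each a `;`-separated id list, empty allowed). Rows
#' whose contact set is not a subset of the proximity set, or whose focal
#' appears in a partner set, are rejected with the row number.
#'
#' @param path CSV path.
#' @return Scan data.frame with list columns.
#' @export
read_scans <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("date", "group", "focal", "proximity_partners", "contact_partners")
  missing <- setdiff(need, names(s))
  check_that(length(missing) == 0,
             paste("missing scan columns:", paste(missing, collapse = ", ")))
  date <- as.Date(s$date, format = "%Y-%m-%d")
  bad <- which(is.na(date))
  check_that(length(bad) == 0,
             sprintf("malformed date in row %d: '%s'", bad[1], s$date[bad[1]]))
  split_ids <- function(x) {
    lapply(strsplit(x, ";", fixed = TRUE),
           function(v) v[nzchar(v)])
  }
  prox <- split_ids(s$proximity_partners)
  cont <- split_ids(s$contact_partners)
  for (i in seq_along(prox)) {
    check_that(!s$focal[i] %in% c(prox[[i]], cont[[i]]),
               sprintf("row %d: focal '%s' appears in its own partner set",
                       i, s$focal[i]))
    check_that(all(cont[[i]] %in% prox[[i]]),
               sprintf("row %d: contact partners not a subset of proximity partners", i))
  }
  data.frame(date = date, group = s$group, focal = s$focal,
             proximity_partners = I(prox), contact_partners = I(cont),
             stringsAsFactors = FALSE)
}

#' @rdname read_scans
#' @param scans Scan data.frame (list columns).
#' @export
write_scans <- function(scans, path) {
  join <- function(col) vapply(col, paste, character(1), collapse = ";")
  out <- data.frame(date = format(scans$date, "%Y-%m-%d"),
                    group = scans$group, focal = scans$focal,
                    proximity_partners = join(scans$proximity_partners),
                    contact_partners = join(scans$contact_partners),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles every tunable of the pipeline with its default; the
#' configuration is serialized (YAML) into every output directory for
#' provenance.
#'
#' @param seed Master seed.
#' @param window_days Pre/post window length (183 = six months).
#' @param min_scans Focal-scan inclusion threshold (strictly more than
#'   this in both windows).
#' @param n_sets,thin Permutation settings.
#' @param mcmc_chains,mcmc_iter MCMC settings for the Siler fits.
#' @param population A [population_config()] for simulated runs.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, window_days = 183, min_scans = 12,
                       n_sets = 1000, thin = 200, mcmc_chains = 2,
                       mcmc_iter = 4000,
                       population = population_config(seed = seed)) {
  structure(list(seed = seed, window_days = window_days,
                 min_scans = min_scans, n_sets = n_sets, thin = thin,
                 mcmc_chains = mcmc_chains, mcmc_iter = mcmc_iter,
                 population = population),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  ser <- unclass(config)
  ser$population <- lapply(unclass(ser$population), function(x) {
    if (inherits(x, "Date")) format(x, "%Y-%m-%d")
    else if (inherits(x, "orphan_effects") || inherits(x, "siler_params"))
      as.list(unclass(x))
    else x
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Full simulated-study run
#'
#' Chains the whole pipeline on synthetic data: population and incidents,
#' latent associations, pre/post focal scans, paired SRI networks, change
#' in network position with the node-label permutation test, dyadic
#' relationship-change models, Cox and Bayesian Siler survival models with
#' DIC comparison, and the dispersal GLMs. With identical configuration
#' and seed the outputs are byte-identical across runs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, result tables are
#'   written as CSV (plus the config as YAML) and paths returned.
#' @param verbose Log progress to stderr.
#' @return List of results (`networks`, `change_records`,
#'   `permutation`, `dyads`, `dyadic_fit`, `cox`, `siler`, `dic`,
#'   `dispersal`).
#' @export
full_run <- function(config = run_config(), out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message("[socbuffer] ", ...)
  say("simulating population")
  pop <- simulate_population(config$population)
  eff <- config$population$orphan_effects
  say("simulating focal scans")
  paired <- list()
  for (k in seq_len(nrow(pop$incidents))) {
    inc <- pop$incidents[k, ]
    orp <- pop$orphans[pop$orphans$incident == inc$incident, ]
    grp <- pop$roster[pop$roster$group == inc$group, ]
    lat_pre <- latent_associations(grp, seed = substream_seed(config$seed, inc$incident))
    lat_post <- suppressWarnings(
      apply_maternal_loss(lat_pre, grp, inc, orp, eff))
    pre_scans <- simulate_focal_scans(
      grp, lat_pre, c(inc$date - config$window_days, inc$date - 1),
      seed = substream_seed(config$seed, paste0(inc$incident, "_pre")))
    post_scans <- simulate_focal_scans(
      grp, lat_post, c(inc$date, inc$date + config$window_days - 1),
      seed = substream_seed(config$seed, paste0(inc$incident, "_post")))
    scans <- rbind(pre_scans, post_scans)
    paired[[inc$incident]] <- tryCatch(
      build_paired_networks(scans, inc, orp$id, "proximity",
                            min_scans = config$min_scans,
                            window_days = config$window_days),
      inadequate_data = function(e) {
        say("incident ", inc$incident, " dropped: ", conditionMessage(e))
        NULL
      })
  }
  paired <- Filter(Negate(is.null), paired)
  say("assembling change records and permutation test")
  records <- assemble_change_records(paired, pop$roster, pop$incidents,
                                     pop$orphans, "weighted_degree_norm")
  perm <- permutation_test(records, n_sets = config$n_sets,
                           thin = config$thin, seed = config$seed)
  say("dyadic models")
  dyads <- build_dyad_table(paired, pop$roster, pop$incidents, pop$orphans)
  dyfit <- fit_all_immature_model(dyads)
  say("survival models")
  srec <- build_survival_records(pop$roster, pop$orphans, pop$study_end)
  cox <- fit_cox_ph(srec, "merged")
  fits <- list(
    null = fit_siler_bayes(srec, "null", chains = config$mcmc_chains,
                           iter = config$mcmc_iter, seed = config$seed),
    prop_hazards = fit_siler_bayes(srec, "prop_hazards",
                                   chains = config$mcmc_chains,
                                   iter = config$mcmc_iter,
                                   seed = config$seed))
  dic <- compare_dic(fits)
  say("dispersal GLMs")
  cls <- orphan_class(srec$loss_age, merge_juv_subadult = TRUE)
  disp <- simulate_dispersal(cls, config$population$dispersal_logit,
                             seed = config$seed)
  disp_fit <- fit_binomial_glm(dispersed ~ class,
                               data.frame(dispersed = disp$dispersed,
                                          class = cls))
  res <- list(networks = paired, change_records = records,
              permutation = perm, dyads = dyads, dyadic_fit = dyfit,
              cox = cox, siler = fits, dic = dic, dispersal = disp_fit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(out_dir, "config.yaml"))
    utils::write.csv(records, file.path(out_dir, "change_records.csv"),
                     row.names = FALSE)
    utils::write.csv(network_metric_table(paired, pop$orphans),
                     file.path(out_dir, "node_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(dyads, file.path(out_dir, "dyad_records.csv"),
                     row.names = FALSE)
    utils::write.csv(perm$observed$coefficients,
                     file.path(out_dir, "change_model.csv"), row.names = FALSE)
    utils::write.csv(data.frame(observed_t = perm$observed_t,
                                p_null = perm$p_null, n_sets = perm$n_sets),
                     file.path(out_dir, "permutation.csv"), row.names = FALSE)
    utils::write.csv(dyfit$coefficients,
                     file.path(out_dir, "dyadic_model.csv"), row.names = FALSE)
    utils::write.csv(cox$coefficients, file.path(out_dir, "cox.csv"),
                     row.names = FALSE)
    utils::write.csv(dic, file.path(out_dir, "dic.csv"), row.names = FALSE)
    utils::write.csv(data.frame(term = names(disp_fit$coefficients),
                                est = disp_fit$coefficients,
                                se = disp_fit$se),
                     file.path(out_dir, "dispersal_glm.csv"),
                     row.names = FALSE)
  }
  res
}
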