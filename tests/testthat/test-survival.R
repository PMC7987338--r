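test_that("survival records apply truncation, classing, and censoring rules", {
  roster <- data.frame(
    id = c("A", "B", "C", "D"),
    group = "G01", sex = c("F", "F", "M", "M"),
    birth_date = as.Date("2000-01-01"),
    death_date = as.Date("2000-01-01") + round(365.25 * c(1.9, 12, 30, 6)),
    mother_id = "unknown", father_id = "unknown", dominant = FALSE,
    stringsAsFactors = FALSE)
  study_end <- as.Date("2000-01-01") + round(365.25 * 20)
  orphans <- data.frame(incident = "I01", id = "B", age_at_loss = 5.1,
                        class = "juvenile", stringsAsFactors = FALSE)
  rec <- build_survival_records(roster, orphans, study_end)
  # death at 1.9 years: excluded by the age-2 truncation
  expect_false("A" %in% rec$id)
  # orphaned at 5.1, died at 12: event with juvenile class
  b <- rec[rec$id == "B", ]
  expect_equal(b$entry, 2)
  expect_equal(b$exit, 12, tolerance = 0.01)
  expect_equal(b$event, 1L)
  expect_equal(as.character(b$class), "juvenile")
  expect_equal(b$loss_age, 5.1)
  # C outlives the study: censored at study end
  cc <- rec[rec$id == "C", ]
  expect_equal(cc$event, 0L)
  expect_equal(cc$exit, 20, tolerance = 0.01)
})

test_that("episode splitting switches the orphan class on at the loss age", {
  rec <- data.frame(id = c("A", "B"), sex = "F", entry = 2,
                    exit = c(12, 9), event = c(1L, 0L),
                    loss_age = c(5.1, NA),
                    class = orphan_class(c(5.1, NA)))
  ep <- socbuffer:::episode_split(rec)
  a <- ep[ep$id == "A", ]
  expect_equal(nrow(a), 2)
  expect_equal(a$stop[1], 5.1)
  expect_equal(as.character(a$class), c("non_orphan", "juvenile"))
  expect_equal(a$event, c(0L, 1L))
  b <- ep[ep$id == "B", ]
  expect_equal(nrow(b), 1)
  expect_equal(as.character(b$class), "non_orphan")
})

test_that("two identical lifespans distributions give a near-zero class effect", {
  rec <- make_surv_records(600, seed = 51, log_hr = 0)
  fit <- fit_cox_ph(rec, "merged")
  expect_true(all(abs(fit$coefficients$est) < 2.5 * fit$coefficients$se))
})

test_that("Cox estimates match brute-force partial likelihood maximization", {
  set.seed(53)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    # tie-free exit ages; some orphaned at exactly age 2 (class fixed from
    # entry), some mid-interval switches
    loss_age <- ifelse(runif(n) < 0.5, 2, NA)
    exit <- sort(2 + rexp(n, 0.2) + seq_len(n) * 1e-4)
    event <- as.integer(runif(n) < 0.8)
    if (sum(event[!is.na(loss_age)]) == 0 || sum(event[is.na(loss_age)]) == 0)
      next  # monotone likelihood; estimate unbounded
    rec <- data.frame(id = as.character(seq_len(n)), sex = "F", entry = 2,
                      exit = exit, event = event, loss_age = loss_age,
                      class = orphan_class(loss_age, merge_juv_subadult = TRUE))
    fit <- tryCatch(fit_cox_ph(rec, "merged"), warning = function(w) NULL)
    if (is.null(fit) || fit$separation) next
    ep <- socbuffer:::episode_split(rec, merge_juv_subadult = TRUE)
    oracle <- stats::optimize(function(b) -oracle_partial_loglik(b, ep),
                              c(-10, 10), tol = 1e-10)$minimum
    if (abs(oracle) > 9) next
    expect_equal(fit$coefficients$est[1], oracle, tolerance = 1e-6)
  }
})

test_that("a twofold orphan hazard is recovered by the time-varying Cox model", {
  # simulate from the time-varying model itself: baseline hazard up to the
  # loss age, twofold hazard afterwards for those still alive at loss
  set.seed(57)
  n <- 400
  p <- siler_params()
  loss_age <- ifelse(runif(n) < 0.4, runif(n, 2, 8), NA)
  death <- simulate_lifespans(n, p, entry = 2)
  sw <- !is.na(loss_age) & death > loss_age
  death[sw] <- simulate_lifespans(sum(sw), p, entry = loss_age[sw],
                                  log_hr = log(2))
  cens <- 45
  rec <- data.frame(id = sprintf("S%03d", 1:n), sex = "F", entry = 2,
                    exit = pmin(death, cens),
                    event = as.integer(death <= cens), loss_age = loss_age,
                    class = orphan_class(loss_age, merge_juv_subadult = TRUE))
  fit <- fit_cox_ph(rec, "merged")
  est <- fit$coefficients$est
  expect_equal(unname(est[1]), log(2), tolerance = 0.25 / log(2))
  expect_equal(unname(est[2]), log(2), tolerance = 0.25 / log(2))
})

test_that("no events is an error and separation is flagged", {
  rec <- make_surv_records(50, seed = 59)
  rec$event <- 0L
  expect_error(fit_cox_ph(rec), "no events")
})

test_that("variant (b) with zero effects reproduces the null likelihood", {
  rec <- make_surv_records(120, seed = 61)
  theta <- log(unclass(siler_params()))
  l_null <- socbuffer:::siler_loglik(theta, rec, "null", character(0))
  l_prop <- socbuffer:::siler_loglik(c(theta, 0, 0), rec, "prop_hazards",
                                     c("infant", "juv_subadult"))
  expect_equal(l_null, l_prop, tolerance = 1e-10)
})

test_that("DIC satisfies its defining identity on a fitted model", {
  rec <- make_surv_records(80, seed = 63)
  fit <- suppressWarnings(fit_siler_bayes(rec, "null", chains = 2,
                                          iter = 1500, seed = 3))
  # recompute deviance terms directly from the posterior draws
  recs <- rec
  sw <- !is.na(recs$loss_age) & recs$loss_age > recs$entry
  recs$entry[sw] <- recs$loss_age[sw]
  recs <- recs[recs$exit > recs$entry, ]
  dev <- -2 * apply(fit$samples, 1, socbuffer:::siler_loglik,
                    records = recs, variant = "null", classes = character(0))
  dev_at_mean <- -2 * socbuffer:::siler_loglik(colMeans(fit$samples), recs,
                                               "null", character(0))
  pd <- mean(dev) - dev_at_mean
  expect_equal(fit$pd, pd, tolerance = 1e-8)
  expect_equal(fit$dic, mean(dev) + pd, tolerance = 1e-8)
})

test_that("DIC deltas use unrounded differences and are order-invariant", {
  mk_fit <- function(dic, variant) structure(
    list(dic = dic, pd = 2, variant = variant, n = 100, converged = TRUE),
    class = "siler_fit")
  fits <- list(null = mk_fit(371.455, "null"),
               prop_hazards = mk_fit(374.16, "prop_hazards"),
               all_params = mk_fit(377.04, "all_params"))
  cmp <- compare_dic(fits)
  expect_equal(cmp$delta_dic, c(0, 374.16 - 371.455, 377.04 - 371.455))
  cmp2 <- compare_dic(rev(fits))
  expect_equal(sort(cmp2$delta_dic), sort(cmp$delta_dic))
  expect_error(compare_dic(fits[1]), "at least two")
  bad <- fits; bad$prop_hazards$n <- 99
  expect_error(compare_dic(bad), "identical record sets")
})
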