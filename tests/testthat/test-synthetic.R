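test_that("population generation is deterministic under a fixed seed", {
  cfg <- population_config(n_groups = 2, group_size_range = c(10, 14), seed = 5)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1, p2)
  p3 <- simulate_population(population_config(n_groups = 2,
                                              group_size_range = c(10, 14),
                                              seed = 6))
  expect_false(identical(p1$roster, p3$roster))
})

test_that("roster mothers are in-roster or unknown and orphans are binned by age", {
  pop <- simulate_population(population_config(n_groups = 3, seed = 2))
  expect_true(all(pop$roster$mother_id %in% c(pop$roster$id, "unknown")))
  expect_true(all(pop$orphans$age_at_loss >= 2 & pop$orphans$age_at_loss < 8))
  expect_identical(pop$orphans$class,
                   as.character(orphan_class(pop$orphans$age_at_loss)))
})

test_that("orphan classes follow the [2,4), [4,6), [6,8) bins", {
  expect_equal(as.character(orphan_class(3.0)), "infant")
  expect_equal(as.character(orphan_class(6.0)), "subadult")
  expect_equal(as.character(orphan_class(c(2, 4, 5.99, 8, NA))),
               c("infant", "juvenile", "juvenile", "non_orphan", "non_orphan"))
  expect_equal(as.character(orphan_class(5, merge_juv_subadult = TRUE)),
               "juv_subadult")
})

test_that("undersized groups are rejected", {
  expect_error(population_config(group_size_range = c(2, 5)), ">= 3")
})

test_that("null hazard effect leaves orphan and non-orphan lifespans exchangeable", {
  p <- siler_params()
  a <- simulate_lifespans(2000, p, entry = 2, log_hr = 0, seed = 31)
  b <- simulate_lifespans(2000, p, entry = 2, log_hr = 0, seed = 32)
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})

test_that("focal scans cycle through the group and respect latent probabilities", {
  roster <- data.frame(id = c("A", "B", "C"), group = "G01",
                       sex = c("F", "F", "M"),
                       birth_date = as.Date("2000-01-01"),
                       death_date = as.Date(NA),
                       mother_id = "unknown", father_id = "unknown",
                       dominant = c(FALSE, FALSE, TRUE),
                       stringsAsFactors = FALSE)
  latent <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                       group = "G01",
                       p_proximity = c(1, 0.4, 0.4),
                       p_contact = c(0.5, 0, 0))
  scans <- simulate_focal_scans(roster, latent,
                                window = as.Date(c("2015-01-01", "2015-05-10")),
                                scans_per_day = 30, seed = 3)
  # determinism
  scans2 <- simulate_focal_scans(roster, latent,
                                 window = as.Date(c("2015-01-01", "2015-05-10")),
                                 scans_per_day = 30, seed = 3)
  expect_identical(scans, scans2)
  # contact set is always inside the proximity set
  expect_true(all(mapply(function(ct, px) all(ct %in% px),
                         scans$contact_partners, scans$proximity_partners)))
  # certainty dyad: SRI(proximity) = 1
  expect_equal(compute_sri(scans, "A", "B", "proximity"), 1)
  # B-C has zero contact probability everywhere
  expect_equal(compute_sri(scans, "B", "C", "contact"), 0)
  # law of large numbers: empirical SRI near latent p = 0.4
  n_scans <- sum(scans$focal %in% c("A", "C"))
  expect_gt(n_scans, 2000)
  expect_equal(compute_sri(scans, "A", "C", "proximity"), 0.4,
               tolerance = 0.03 / 0.4)
})

test_that("maternal loss removes the mother and boosts orphan dyads additively", {
  pop <- simulate_population(population_config(n_groups = 1, seed = 4))
  inc <- pop$incidents[1, ]
  orp <- pop$orphans[pop$orphans$incident == inc$incident, ]
  grp <- pop$roster[pop$roster$group == inc$group, ]
  lat <- latent_associations(grp, seed = 9)

  # all-zero effects: post equals pre minus the mother's dyads
  post0 <- apply_maternal_loss(lat, grp, inc, orp, orphan_effects())
  pre_minus <- lat[lat$a != inc$mother & lat$b != inc$mother, ]
  expect_equal(post0$p_proximity, pre_minus$p_proximity)
  expect_false(inc$mother %in% c(post0$a, post0$b))

  # additive boost on the dominant-male dyad of each orphan
  eff <- orphan_effects(boost_by_class = list(dominant_male = 0.2))
  post <- apply_maternal_loss(lat, grp, inc, orp, eff)
  dom <- grp$id[grp$dominant]
  o <- orp$id[1]
  pick <- function(d, x, y) which((d$a == x & d$b == y) | (d$a == y & d$b == x))
  expect_equal(post$p_proximity[pick(post, o, dom)],
               pre_minus$p_proximity[pick(pre_minus, o, dom)] + 0.2)
  # non-orphan dyads untouched
  non <- setdiff(grp$id, c(orp$id, inc$mother))
  keep <- post$a %in% non & post$b %in% non
  expect_equal(post$p_proximity[keep],
               pre_minus$p_proximity[pre_minus$a %in% non & pre_minus$b %in% non])

  # boosts above 1 are clipped with a warning
  eff_big <- orphan_effects(boost_by_class = list(dominant_male = 0.95))
  expect_warning(post_big <- apply_maternal_loss(lat, grp, inc, orp, eff_big),
                 "clipped")
  expect_true(all(post_big$p_proximity <= 1 & post_big$p_contact <= post_big$p_proximity))

  # unknown orphan id is an error
  bad <- orp; bad$id[1] <- "NOBODY"
  expect_error(apply_maternal_loss(lat, grp, inc, bad, eff), "unknown orphan")
})

test_that("dispersal outcomes follow the configured log-odds", {
  cls <- rep("non_orphan", 20000)
  d <- simulate_dispersal(cls, c(intercept = log(0.6)), seed = 11)
  expect_equal(unique(d$p), stats::plogis(log(0.6)))
  expect_equal(mean(d$dispersed), 0.375, tolerance = 0.03)
  # extreme offsets are capped at +/- 20: probability pinned at
  # plogis(20) = 1 - 2.061e-9
  d2 <- simulate_dispersal(rep("infant", 5), c(intercept = 0, infant = 1e6),
                           seed = 1)
  expect_true(all(abs(d2$p - 1) < 2.1e-9))
  expect_equal(unique(d2$p), stats::plogis(20))
})

test_that("dispersal offsets are recovered by the binomial GLM at n = 5000", {
  cls <- factor(sample(c("non_orphan", "infant", "juv_subadult"), 5000,
                       replace = TRUE, prob = c(0.6, 0.2, 0.2)),
                levels = c("non_orphan", "infant", "juv_subadult"))
  truth <- c(intercept = -0.5, infant = 0.7, juv_subadult = 1.6)
  d <- simulate_dispersal(cls, truth, seed = 21)
  fit <- fit_binomial_glm(dispersed ~ class,
                          data.frame(dispersed = d$dispersed, class = cls))
  expect_equal(unname(fit$coefficients["classinfant"]), 0.7, tolerance = 0.15)
  expect_equal(unname(fit$coefficients["classjuv_subadult"]), 1.6,
               tolerance = 0.15)
})
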