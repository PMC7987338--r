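test_that("SRI is the association count over the summed focal counts", {
  rows <- c(scans_block("A", "B", 10, 2), scans_block("B", "A", 10, 1))
  scans <- make_scans(rows)
  expect_equal(compute_sri(scans, "A", "B", "proximity"), 3 / 20)
  # asymmetric sampling: 30 + 10 focals, 8 associations
  rows <- c(scans_block("A", "B", 30, 8), scans_block("B", "A", 10, 0))
  expect_equal(compute_sri(make_scans(rows), "A", "B", "proximity"), 0.2)
  # partner present on every scan of either member
  rows <- c(scans_block("A", "B", 7, 7), scans_block("B", "A", 5, 5))
  expect_equal(compute_sri(make_scans(rows), "A", "B", "proximity"), 1)
})

test_that("SRI is symmetric and errors on unsampled dyads", {
  rows <- c(scans_block("A", "B", 12, 5), scans_block("B", "A", 8, 3))
  scans <- make_scans(rows)
  expect_equal(compute_sri(scans, "A", "B", "proximity"),
               compute_sri(scans, "B", "A", "proximity"))
  expect_error(compute_sri(scans, "X", "Y", "proximity"), "unsampled dyad")
})

test_that("adding an association scan never decreases the dyad's SRI", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(5:20, 1); k <- sample(0:n, 1)
    base <- c(scans_block("A", "B", n, k), scans_block("B", "A", 3, 1))
    s0 <- compute_sri(make_scans(base), "A", "B", "proximity")
    plus <- c(base, list(list(date = 0, focal = "A", prox = "B",
                              contact = character(0))))
    s1 <- compute_sri(make_scans(plus), "A", "B", "proximity")
    expect_gte(s1, s0)
  }
})

test_that("paired networks enforce the strict scan filter and drop mothers", {
  mk_inc <- function() data.frame(incident = "I01", group = "G01",
                                  date = as.Date("2015-07-01"),
                                  mother = "MOM", stringsAsFactors = FALSE)
  # A (orphan), B, C well-sampled in both windows; D has exactly 12 pre scans;
  # MOM sampled pre only
  pre_day <- -100; post_day <- 50
  rows <- c(scans_block("A", "B", 20, 10, pre_day),
            scans_block("B", "A", 20, 8, pre_day),
            scans_block("C", "MOM", 20, 5, pre_day),
            scans_block("MOM", "A", 20, 12, pre_day),
            scans_block("D", "A", 12, 3, pre_day),
            scans_block("A", "B", 20, 12, post_day),
            scans_block("B", "C", 20, 4, post_day),
            scans_block("C", "A", 20, 2, post_day),
            scans_block("D", "C", 200, 50, post_day))
  scans <- make_scans(rows, start = as.Date("2015-07-01"))
  pn <- build_paired_networks(scans, mk_inc(), orphans = "A", "proximity",
                              min_scans = 12, window_days = 183)
  # D had only 12 pre scans: excluded by the strict "> 12" rule despite 200 post
  expect_false("D" %in% pn$pre$nodes)
  # the mother is excluded from both periods even though sampled pre
  expect_false("MOM" %in% pn$pre$nodes)
  expect_false("MOM" %in% pn$post$nodes)
  expect_identical(pn$pre$nodes, pn$post$nodes)
  expect_setequal(pn$pre$nodes, c("A", "B", "C"))
  # the orphan's pre-loss SRI with the mother is extracted separately
  expect_equal(unname(pn$mother_sri["A"]), 12 / 40)
  # weights live in [0,1] and are symmetric
  expect_true(all(pn$pre$weights >= 0 & pn$pre$weights <= 1))
  expect_identical(pn$pre$weights, t(pn$pre$weights))

  # no scans in the post window at all -> window uncovered
  pre_only <- make_scans(c(scans_block("A", "B", 20, 3, pre_day),
                           scans_block("B", "A", 20, 3, pre_day)),
                         start = as.Date("2015-07-01"))
  expect_error(build_paired_networks(pre_only, mk_inc(), "A", "proximity"),
               "window uncovered")

  # orphan itself under-sampled -> incident flagged inadequate and dropped
  thin <- make_scans(c(scans_block("A", "B", 5, 1, pre_day),
                       scans_block("B", "C", 30, 3, pre_day),
                       scans_block("C", "B", 30, 3, pre_day),
                       scans_block("A", "B", 30, 1, post_day),
                       scans_block("B", "C", 30, 3, post_day),
                       scans_block("C", "B", 30, 3, post_day)),
                     start = as.Date("2015-07-01"))
  expect_error(build_paired_networks(thin, mk_inc(), "A", "proximity"),
               class = "inadequate_data")
})

test_that("node metrics are max-normalized with closed-form eigenvector values", {
  nodes <- c("L", "M", "R")
  w <- sym_matrix(nodes)
  w["L", "M"] <- w["M", "L"] <- 0.5
  w["M", "R"] <- w["R", "M"] <- 0.5
  net <- make_paired(w, w)$pre
  m <- node_metrics(net)
  expect_equal(m$eigenvector[m$node == "M"], 1)
  expect_equal(m$eigenvector[m$node == "L"], 1 / sqrt(2), tolerance = 1e-10)
  expect_equal(m$binary_degree_norm, c(0.5, 1, 0.5))

  # star with 4 leaves
  nodes <- c("H", paste0("S", 1:4))
  w <- sym_matrix(nodes)
  w["H", paste0("S", 1:4)] <- 0.3
  w[paste0("S", 1:4), "H"] <- 0.3
  m <- node_metrics(make_paired(w, w)$pre)
  expect_equal(m$binary_degree_norm[m$node == "H"], 1)
  expect_equal(m$binary_degree_norm[m$node == "S1"], 0.25)

  # complete network with equal weights: every metric 1 for every node
  nodes <- paste0("N", 1:5)
  w <- sym_matrix(nodes, 0.2); diag(w) <- 0
  m <- node_metrics(make_paired(w, w)$pre)
  expect_true(all(m$binary_degree_norm == 1 & m$weighted_degree_norm == 1))
  expect_true(all(abs(m$eigenvector - 1) < 1e-12))

  # all-zero network: metrics 0 with a warning
  w0 <- sym_matrix(nodes)
  expect_warning(m0 <- node_metrics(make_paired(w0, w0)$pre), "all-zero")
  expect_true(all(m0$eigenvector == 0))
})

test_that("eigenvector centrality agrees with a power-iteration oracle", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    nodes <- paste0("N", seq_len(n))
    w <- matrix(runif(n * n, 0, 0.5), n)
    w <- (w + t(w)) / 2; diag(w) <- 0
    dimnames(w) <- list(nodes, nodes)
    m <- node_metrics(make_paired(w, w)$pre)
    expect_equal(m$eigenvector, power_iteration_ev(w), tolerance = 1e-8)
  }
})

test_that("metric change is post minus pre with a signed immature-mean deviance", {
  nodes <- c("A", "B", "C", "D")
  pre_w <- sym_matrix(nodes)
  pre_w["A", "B"] <- pre_w["B", "A"] <- 0.4
  pre_w["C", "D"] <- pre_w["D", "C"] <- 0.2
  pre_w["A", "C"] <- pre_w["C", "A"] <- 0.1
  post_w <- pre_w
  post_w["A", "B"] <- post_w["B", "A"] <- 0.6
  pn <- make_paired(pre_w, post_w)
  pre_m <- node_metrics(pn$pre); post_m <- node_metrics(pn$post)
  mc <- metric_change(pre_m, post_m, immatures = c("A", "B"))
  # hand computation: weighted degrees pre (0.5, 0.4, 0.3, 0.2)/0.5,
  # post (0.7, 0.6, 0.3, 0.2)/0.7
  expect_equal(mc$delta_weighted_degree_norm[mc$node == "A"], 0)
  expect_equal(mc$delta_weighted_degree_norm[mc$node == "B"],
               0.6 / 0.7 - 0.4 / 0.5)
  expect_equal(mc$deviance_weighted_degree_norm[mc$node == "A"],
               1 - mean(c(1, 0.8)))
  # identical networks: all deltas 0, node at the immature mean has deviance 0
  mc0 <- metric_change(pre_m, pre_m, immatures = nodes)
  expect_true(all(mc0$delta_weighted_degree_norm == 0))
  # mismatched node sets error
  expect_error(metric_change(pre_m[-1, ], post_m), "mismatch")
})

test_that("contact SRI never exceeds proximity SRI on simulated data", {
  pop <- simulate_population(population_config(n_groups = 1,
                                               group_size_range = c(8, 10),
                                               seed = 19))
  grp <- pop$roster
  lat <- latent_associations(grp, seed = 23)
  scans <- simulate_focal_scans(grp, lat,
                                window = as.Date(c("2015-01-01", "2015-02-19")),
                                scans_per_day = 20, seed = 29)
  ids <- unique(scans$focal)
  pairs <- utils::combn(ids, 2)
  for (k in seq_len(ncol(pairs))) {
    expect_lte(compute_sri(scans, pairs[1, k], pairs[2, k], "contact"),
               compute_sri(scans, pairs[1, k], pairs[2, k], "proximity"))
  }
})
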