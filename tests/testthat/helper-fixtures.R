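# Shared fixture builders: everything is generated in code at test time.

# hand-built focal-scan table; each element of `rows` is
# list(date, focal, prox = c(...), contact = c(...))
make_scans <- function(rows, group = "G01", start = as.Date("2015-01-01")) {
  data.frame(
    date = start + vapply(rows, function(r) r$date, numeric(1)),
    group = group,
    focal = vapply(rows, function(r) r$focal, character(1)),
    proximity_partners = I(lapply(rows, function(r) r$prox %||% character(0))),
    contact_partners = I(lapply(rows, function(r) r$contact %||% character(0))),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n scans with `focal`, partner present in the proximity set for the first
# `n_assoc` of them
scans_block <- function(focal, partner, n, n_assoc, day0 = 0, span = 80) {
  lapply(seq_len(n), function(i)
    list(date = day0 + i %% span, focal = focal,
         prox = if (i <= n_assoc) partner else character(0),
         contact = character(0)))
}

# survival records with orphans left-truncated at loss and an optional
# proportional hazard effect after loss
make_surv_records <- function(n, seed, log_hr = 0, p_orphan = 0.3,
                              params = siler_params(), cens = 45,
                              merge = TRUE) {
  set.seed(seed)
  orphan <- stats::runif(n) < p_orphan
  loss_age <- ifelse(orphan, stats::runif(n, 2, 8), NA)
  entry <- ifelse(orphan, loss_age, 2)
  death <- simulate_lifespans(n, params, entry = entry,
                              log_hr = ifelse(orphan, log_hr, 0))
  data.frame(id = sprintf("S%04d", seq_len(n)), sex = "F", entry = entry,
             exit = pmin(death, cens), event = as.integer(death <= cens),
             loss_age = loss_age,
             class = orphan_class(loss_age, merge_juv_subadult = merge),
             stringsAsFactors = FALSE)
}

# wrap a pair of weight matrices into the paired_networks structure
make_paired <- function(pre_w, post_w, incident = "I01",
                        assoc_type = "proximity", focal_counts = NULL) {
  nodes <- rownames(pre_w)
  if (is.null(focal_counts)) focal_counts <- stats::setNames(rep(100L, length(nodes)), nodes)
  mk <- function(w, period) structure(
    list(incident = incident, period = period, assoc_type = assoc_type,
         nodes = nodes, focal_counts = focal_counts, weights = w),
    class = "sri_network")
  structure(list(pre = mk(pre_w, "pre"), post = mk(post_w, "post"),
                 mother_sri = NULL, orphans = character(0)),
            class = "paired_networks")
}

sym_matrix <- function(nodes, fill = 0) {
  matrix(fill, length(nodes), length(nodes), dimnames = list(nodes, nodes))
}

# independent power-iteration oracle for eigenvector centrality
power_iteration_ev <- function(w, iters = 10000, tol = 1e-14) {
  v <- rep(1, nrow(w))
  for (i in seq_len(iters)) {
    v2 <- as.vector(w %*% v)
    if (max(abs(v2)) == 0) return(rep(0, nrow(w)))
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < tol) { v <- v2; break }
    v <- v2
  }
  v / max(v)
}

# independent log partial likelihood (Breslow-free, no ties) over
# counting-process episodes with a single binary covariate
oracle_partial_loglik <- function(beta, ep) {
  x <- as.numeric(ep$class != "non_orphan")
  ll <- 0
  for (i in which(ep$event == 1)) {
    t <- ep$stop[i]
    risk <- ep$start < t & ep$stop >= t
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
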