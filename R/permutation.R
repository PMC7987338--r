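#' Assemble node-level change records across incidents
#'
#' Combines [metric_change()] output across incidents into the table the
#' change model consumes, restricted to immatures aged 2-8 at the incident
#' date. Incidents whose orphans have no non-orphan immature companions are
#' excluded (their labels cannot be permuted).
#'
#' @param paired_list Named list of `paired_networks`, one per incident.
#' @param roster Roster data.frame.
#' @param incidents Incidents data.frame (`incident`, `date`, ...).
#' @param orphan_table Orphan table (`incident`, `id`).
#' @param metric One of `"binary_degree_norm"`, `"weighted_degree_norm"`,
#'   `"eigenvector"`.
#' @return Data.frame with `incident`, `node`, `orphan`, `age`, `deviance`,
#'   `total_scans`, `delta`.
#' @export
assemble_change_records <- function(paired_list, roster, incidents,
                                    orphan_table,
                                    metric = c("weighted_degree_norm",
                                               "binary_degree_norm",
                                               "eigenvector")) {
  metric <- match.arg(metric)
  rows <- list()
  for (inc_id in names(paired_list)) {
    pn <- paired_list[[inc_id]]
    inc <- incidents[incidents$incident == inc_id, ]
    age <- years_between(roster$birth_date[match(pn$pre$nodes, roster$id)],
                         inc$date)
    imm <- pn$pre$nodes[age >= 2 & age < 8]
    if (length(imm) == 0) next
    mc <- metric_change(node_metrics(pn$pre), node_metrics(pn$post), imm)
    mc <- mc[mc$node %in% imm, ]
    is_orphan <- mc$node %in% orphan_table$id[orphan_table$incident == inc_id]
    if (!any(is_orphan) || all(is_orphan)) next  # unpermutable incident
    rows[[inc_id]] <- data.frame(
      incident = inc_id, node = mc$node, orphan = is_orphan,
      age = age[match(mc$node, pn$pre$nodes)],
      deviance = mc[[paste0("deviance_", metric)]],
      total_scans = as.integer(pn$pre$focal_counts[mc$node] +
                                 pn$post$focal_counts[mc$node]),
      delta = mc[[paste0("delta_", metric)]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: spline basis size shrinks on small samples so the model keeps
# residual degrees of freedom (5 cubic B-spline functions at the study scale)
change_model_formula <- function(n) {
  df <- max(3, min(5, n - 10))
  stats::as.formula(sprintf(
    "delta ~ orphan + age + deviance + splines::bs(total_scans, df = %d) + (1 | incident)",
    df))
}

#' Mixed model for change in network position
#'
#' Fits the change in a normalized network metric on orphan status, age,
#' and the deviance of the initial value from the immature mean, with a
#' cubic B-spline smooth of the total focal-scan count (5 basis functions,
#' fewer when the sample is too small to support them) and a random
#' intercept per maternal-loss incident. The orphan
#' t-statistic is the quantity referenced against the permutation null. If
#' the mixed fit fails, the model falls back to the fixed-effect spline
#' regression with a warning.
#'
#' @param records Change-record table (see [assemble_change_records()] or
#'   [simulate_change_records()]).
#' @param statistic_only If `TRUE` return only the orphan t-statistic
#'   (fast path for the permutation loop).
#' @return List of class `change_model_fit` with `coefficients` (term, est,
#'   se, t, p), `t_orphan`, and `n`; or a single number if
#'   `statistic_only = TRUE`.
#' @export
fit_change_model <- function(records, statistic_only = FALSE) {
  check_that(length(unique(records$incident)) >= 2, "need >= 2 incidents")
  check_that(any(records$orphan) && any(!records$orphan),
             "need both orphan and non-orphan records")
  if (stats::sd(records$delta) == 0) {
    # degenerate no-signal case: all coefficients and statistics are zero
    if (statistic_only) return(0)
    co <- data.frame(term = "orphanTRUE", est = 0, se = NA_real_, t = 0,
                     p = 1, stringsAsFactors = FALSE)
    return(structure(list(coefficients = co, t_orphan = 0,
                          n = nrow(records)), class = "change_model_fit"))
  }
  f <- change_model_formula(nrow(records))
  fit <- tryCatch(
    lme4::lmer(f, data = records, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixed fit failed; falling back to fixed-effect spline regression")
    lmfit <- stats::lm(stats::update(f, . ~ . - (1 | incident)),
                       data = records)
    s <- summary(lmfit)$coefficients
    co <- data.frame(term = rownames(s), est = s[, 1], se = s[, 2],
                     t = s[, 3], p = s[, 4], stringsAsFactors = FALSE)
  } else {
    s <- summary(fit)$coefficients
    co <- data.frame(term = rownames(s), est = s[, 1], se = s[, 2],
                     t = s[, 3], p = 2 * stats::pnorm(-abs(s[, 3])),
                     stringsAsFactors = FALSE)
  }
  rownames(co) <- NULL
  t_orphan <- co$t[co$term == "orphanTRUE"]
  if (statistic_only) return(t_orphan)
  structure(list(coefficients = co, t_orphan = t_orphan, n = nrow(records)),
            class = "change_model_fit")
}

#' @export
print.change_model_fit <- function(x, ...) {
  cat(sprintf("Change-in-network-position model (n = %d)\n", x$n))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Node-label permutation sets
#'
#' Builds a thinned chain of orphan-label permutations: each elementary
#' move picks a maternal-loss incident at random and swaps the labels of
#' two of its immatures drawn with replacement (a no-op when the draw
#' repeats an individual or pairs two identical labels, which makes the
#' chain aperiodic even for two-individual incidents). Every `thin`-th
#' state is emitted. Per-incident orphan counts are conserved in every
#' emitted set.
#'
#' @param records Change-record table with `incident` and `orphan`.
#' @param n_sets Number of label sets to emit (study default 10,000).
#' @param thin Moves between emitted sets (study default 200).
#' @param seed Integer seed.
#' @return Logical matrix, `n_sets` rows by `nrow(records)` columns.
#' @export
permute_orphan_labels <- function(records, n_sets = 10000, thin = 200,
                                  seed = 1L) {
  by_inc <- split(seq_len(nrow(records)), records$incident)
  bad <- vapply(by_inc, function(ix) all(records$orphan[ix]) ||
                  all(!records$orphan[ix]), logical(1))
  if (any(bad)) stop("incident(s) with single-status immatures: ",
                     paste(names(by_inc)[bad], collapse = ", "),
                     " (exclude upstream)", call. = FALSE)
  set.seed(substream_seed(seed, "permutation"))
  state <- records$orphan
  out <- matrix(NA, n_sets, length(state))
  inc_of_move <- sample(length(by_inc), n_sets * thin, replace = TRUE)
  m <- 0L
  for (s in seq_len(n_sets)) {
    for (k in seq_len(thin)) {
      m <- m + 1L
      ix <- by_inc[[inc_of_move[m]]]
      pick <- ix[sample.int(length(ix), 2, replace = TRUE)]
      tmp <- state[pick[1]]
      state[pick[1]] <- state[pick[2]]
      state[pick[2]] <- tmp
    }
    out[s, ] <- state
  }
  out
}

#' Two-tailed permutation p-value
#'
#' For an observed statistic above the median of the null distribution,
#' `p = 2 * #(null > observed) / N`; below the median,
#' `p = 2 * #(null < observed) / N`; ties count as neither greater nor
#' lesser. At the median both formulas are evaluated and the larger value
#' reported. The result is capped at 1.
#'
#' @param observed_t Observed statistic.
#' @param null_t Numeric vector of null statistics.
#' @return p-value in `[0, 1]`.
#' @export
p_null <- function(observed_t, null_t) {
  check_that(length(null_t) > 0, "empty null distribution")
  n <- length(null_t)
  med <- stats::median(null_t)
  upper <- 2 * sum(null_t > observed_t) / n
  lower <- 2 * sum(null_t < observed_t) / n
  p <- if (observed_t > med) upper
       else if (observed_t < med) lower
       else max(upper, lower)
  min(p, 1)
}

#' Permutation test of orphan status on change in network position
#'
#' Fits the change model on the observed orphan labels, refits it on every
#' emitted permutation set (same design, permuted labels only), and
#' references the observed orphan t-statistic against the null t
#' distribution with the two-tailed [p_null()].
#'
#' @inheritParams permute_orphan_labels
#' @return List of class `permutation_result`: `observed` (the full fit),
#'   `observed_t`, `null_t`, `p_null`, `n_sets`, `thin`, `seed`.
#' @export
permutation_test <- function(records, n_sets = 10000, thin = 200, seed = 1L) {
  observed <- fit_change_model(records)
  if (stats::sd(records$delta) == 0) {
    # degenerate constant response: every statistic is zero by convention
    return(structure(list(observed = observed, observed_t = 0,
                          null_t = rep(0, n_sets), p_null = 1,
                          n_sets = n_sets, thin = thin, seed = seed),
                     class = "permutation_result"))
  }
  labels <- permute_orphan_labels(records, n_sets, thin, seed)
  # fast refit path: the design only changes in the orphan column, so the
  # parsed model structures are built once and the column swapped in place
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  f <- change_model_formula(nrow(records))
  lf <- suppressMessages(lme4::lFormula(f, data = records, REML = TRUE,
                                        control = ctrl))
  j <- match("orphanTRUE", colnames(lf$X))
  refit_t <- function(lab) {
    lf$X[, j] <- lab
    devfun <- do.call(lme4::mkLmerDevfun, lf)
    opt <- lme4::optimizeLmer(devfun, control = ctrl$optCtrl)
    fit <- lme4::mkMerMod(environment(devfun), opt, lf$reTrms, fr = lf$fr)
    lme4::fixef(fit)[[j]] / sqrt(as.matrix(stats::vcov(fit))[j, j])
  }
  rec <- records
  null_t <- vapply(seq_len(n_sets), function(s) {
    tryCatch(refit_t(labels[s, ]), error = function(e) {
      rec$orphan <- labels[s, ]
      suppressWarnings(fit_change_model(rec, statistic_only = TRUE))
    })
  }, numeric(1))
  structure(list(observed = observed, observed_t = observed$t_orphan,
                 null_t = null_t,
                 p_null = p_null(observed$t_orphan, null_t),
                 n_sets = n_sets, thin = thin, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  co <- x$observed$coefficients
  i <- match("orphanTRUE", co$term)
  cat(sprintf(
    "Node-label permutation test: Est = %.3f +/- %.3f, t = %.3f, p = %.3g, P_null = %.3g (%d sets)\n",
    co$est[i], co$se[i], co$t[i], co$p[i], x$p_null, x$n_sets))
  invisible(x)
}
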