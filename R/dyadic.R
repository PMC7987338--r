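#' Dyadic SRI-change table around maternal-loss incidents
#'
#' One record per (immature, group member, association type): the change in
#' SRI weight from the pre to the post network, with the covariates the
#' dyadic models need. Mother-offspring dyads are excluded (the mother is
#' already absent from the paired networks), as are non-orphan immatures'
#' dyads whose partner is an orphan. Partner age-sex class is assigned at
#' the loss date; records whose partner class cannot be resolved are
#' dropped with a warning.
#'
#' @param paired_list Named list of `paired_networks`, one per incident.
#' @param roster Roster data.frame.
#' @param incidents Incidents data.frame.
#' @param orphan_table Orphan table (`incident`, `id`).
#' @return Data.frame with columns `incident`, `group`, `immature`,
#'   `partner`, `orphan`, `immature_age`, `immature_sex`, `partner_class`,
#'   `age_mate`, `sibling`, `father`, `mean_scans`, `delta_sri`.
#' @export
build_dyad_table <- function(paired_list, roster, incidents, orphan_table) {
  rows <- list()
  for (inc_id in names(paired_list)) {
    pn <- paired_list[[inc_id]]
    inc <- incidents[incidents$incident == inc_id, ]
    nodes <- pn$pre$nodes
    ri <- match(nodes, roster$id)
    if (anyNA(ri)) {
      warning("partner class unresolvable for ",
              paste(nodes[is.na(ri)], collapse = ", "), "; records dropped")
      nodes <- nodes[!is.na(ri)]; ri <- ri[!is.na(ri)]
    }
    age <- years_between(roster$birth_date[ri], inc$date)
    sex <- roster$sex[ri]
    dom <- roster$dominant[ri]
    mom <- roster$mother_id[ri]
    dad <- roster$father_id[ri]
    cls <- as.character(age_sex_class(age, sex, dom))
    orphan_ids <- orphan_table$id[orphan_table$incident == inc_id]
    imm <- nodes[age >= 2 & age < 8]
    delta <- pn$post$weights[nodes, nodes] - pn$pre$weights[nodes, nodes]
    mean_scans <- (pn$pre$focal_counts[nodes] + pn$post$focal_counts[nodes]) / 2
    for (o in imm) {
      oi <- match(o, nodes)
      partners <- setdiff(nodes, o)
      is_orphan <- o %in% orphan_ids
      # non-orphans' dyads with orphan partners are excluded
      if (!is_orphan) partners <- setdiff(partners, orphan_ids)
      # mother-offspring dyads excluded (mother absent anyway, but also skip
      # the immature's own offspringless mother edge defensively)
      partners <- setdiff(partners, mom[oi])
      if (!length(partners)) next
      pi <- match(partners, nodes)
      rows[[length(rows) + 1L]] <- data.frame(
        incident = inc_id, group = inc$group, immature = o,
        partner = partners, orphan = is_orphan,
        immature_age = age[oi], immature_sex = sex[oi],
        partner_class = cls[pi],
        age_mate = abs(age[pi] - age[oi]) < 2,
        sibling = mom[pi] == mom[oi] & mom[oi] != "unknown",
        father = ifelse(dad[oi] == "unknown", NA, partners == dad[oi]),
        mean_scans = (mean_scans[oi] + mean_scans[pi]) / 2,
        delta_sri = delta[oi, pi],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$partner_class <- factor(out$partner_class,
                              levels = levels(age_sex_class(1, "F")))
  rownames(out) <- NULL
  out
}

# internal: fit a spline-smoothed LMM and return a tidy coefficient table
fit_dyadic_lmm <- function(formula, data, unstable_min = 2) {
  fit <- lme4::lmer(formula, data = data, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  s <- summary(fit)$coefficients
  co <- data.frame(term = rownames(s), est = s[, 1], se = s[, 2],
                   z = s[, 3], p = 2 * stats::pnorm(-abs(s[, 3])),
                   stringsAsFactors = FALSE)
  rownames(co) <- NULL
  # flag levels with too few records to estimate stably
  tab <- table(data$partner_class)
  co$unstable <- vapply(co$term, function(tm) {
    hit <- names(tab)[vapply(names(tab), function(l) grepl(l, tm, fixed = TRUE),
                             logical(1))]
    length(hit) > 0 && any(tab[hit] < unstable_min)
  }, logical(1))
  structure(list(coefficients = co, n = nrow(data), model = fit),
            class = "dyadic_model_fit")
}

#' @export
print.dyadic_model_fit <- function(x, ...) {
  cat(sprintf("Dyadic SRI-change model (n = %d records)\n", x$n))
  print(x$coefficients[, c("term", "est", "se", "z", "p")], digits = 3)
  if (any(x$coefficients$unstable))
    cat("note: coefficients involving sparsely observed classes flagged unstable\n")
  invisible(x)
}

#' Dyadic change model over all immatures (orphan x class interaction)
#'
#' Mixed model of the dyadic SRI change for all immatures (orphans and
#' non-orphans) on immature age and sex, partner age-sex class, orphan
#' status, and the orphan-by-class interaction, with a cubic B-spline
#' smooth of mean focal scans and random intercepts for the immature
#' nested in incident nested in group, and for the partner. Wald Z and
#' normal-based p-values are reported.
#'
#' @param records A dyad table ([build_dyad_table()] or
#'   [simulate_dyad_records()]), single association type.
#' @return `dyadic_model_fit`.
#' @export
fit_all_immature_model <- function(records) {
  check_that(any(records$orphan) && any(!records$orphan),
             "need both orphan and non-orphan records")
  if (all(records$delta_sri == 0)) return(zero_dyadic_fit(records))
  fit_dyadic_lmm(
    delta_sri ~ immature_age + immature_sex + orphan * partner_class +
      splines::bs(mean_scans, df = 5) +
      (1 | group / incident / immature) + (1 | partner),
    records)
}

#' Orphan-only dyadic change model
#'
#' Mixed model restricted to orphans' dyads: orphan age and sex, age-mate
#' and maternal-sibling flags, partner age-sex class (reference: dominant
#' male) and the class-by-sibling interaction, with the mean-scans spline
#' smooth and random intercepts for the orphan nested in group and for the
#' partner.
#'
#' @param records Dyad table restricted to orphans.
#' @return `dyadic_model_fit`.
#' @export
fit_orphan_only_model <- function(records) {
  check_that(all(records$orphan), "records must be orphans' dyads only")
  if (all(records$delta_sri == 0)) return(zero_dyadic_fit(records))
  fit_dyadic_lmm(
    delta_sri ~ immature_age + immature_sex + age_mate +
      partner_class * sibling + splines::bs(mean_scans, df = 5) +
      (1 | group / immature) + (1 | partner),
    records)
}

#' Adult-male dyadic change model (dominance, sibling, paternity)
#'
#' Restricted to orphans' dyads with adult-male partners: orphan age and
#' sex, male dominance, maternal sibling, genetic paternity, and the
#' dominance-by-sibling interaction (no dominance-by-paternity interaction;
#' the two are collinear in groups where the dominant male sires most
#' offspring). Records with unknown paternity are excluded.
#'
#' @param records Dyad table restricted to orphans' adult-male dyads
#'   (`partner_class` dominant_male or subordinate_male; `father` logical
#'   or NA for unknown).
#' @return `dyadic_model_fit`.
#' @export
fit_adult_male_model <- function(records) {
  records <- records[records$partner_class %in%
                       c("dominant_male", "subordinate_male"), ]
  records <- records[!is.na(records$father), ]
  check_that(nrow(records) > 0, "all paternity labels unknown")
  records$dominant <- records$partner_class == "dominant_male"
  if (all(records$delta_sri == 0)) return(zero_dyadic_fit(records))
  fit_dyadic_lmm(
    delta_sri ~ immature_age + immature_sex + dominant * sibling + father +
      splines::bs(mean_scans, df = 5) +
      (1 | immature) + (1 | partner),
    records)
}

# internal: degenerate all-zero response short-circuit
zero_dyadic_fit <- function(records) {
  co <- data.frame(term = "(all-zero response)", est = 0, se = NA_real_,
                   z = 0, p = 1, unstable = FALSE, stringsAsFactors = FALSE)
  structure(list(coefficients = co, n = nrow(records), model = NULL),
            class = "dyadic_model_fit")
}
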