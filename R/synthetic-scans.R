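#' Latent dyadic association probabilities
#'
#' Builds per-scan Bernoulli association probabilities for every dyad of a
#' group: `p_proximity` is the chance a partner is within 2 m of the focal
#' on any one scan, and `p_contact <= p_proximity` the chance they are in
#' affiliative contact (contact implies proximity). Mother-offspring and
#' dominant-male-immature dyads get elevated baselines, mirroring the strong
#' bonds typical of gorilla groups; everything else is drawn from a diffuse
#' baseline. Associations are independent across scans, which keeps the
#' Simple Ratio Index an unbiased estimate of the latent probability.
#'
#' @param roster Roster data.frame (one group or several; dyads are built
#'   within groups only).
#' @param base_range Range of baseline proximity probabilities.
#' @param mother_p,dominant_p Proximity baselines for mother-offspring and
#'   dominant-male-immature dyads.
#' @param contact_frac_range Contact probability as a fraction of proximity.
#' @param seed Integer seed.
#' @return Data.frame with columns `a`, `b` (unordered dyad, a < b),
#'   `group`, `p_proximity`, `p_contact`; class `latent_associations`.
#' @export
latent_associations <- function(roster, base_range = c(0.02, 0.25),
                                mother_p = 0.4, dominant_p = 0.3,
                                contact_frac_range = c(0.2, 0.6),
                                seed = 1L) {
  set.seed(substream_seed(seed, "latent"))
  out <- list()
  for (g in unique(roster$group)) {
    r <- roster[roster$group == g, ]
    if (nrow(r) < 2) next
    pairs <- utils::combn(sort(r$id), 2)
    a <- pairs[1, ]; b <- pairs[2, ]
    p_prox <- stats::runif(length(a), base_range[1], base_range[2])
    is_mo <- paste(a, b) %in% c(paste(r$id, r$mother_id),
                                paste(r$mother_id, r$id))
    p_prox[is_mo] <- mother_p
    dom <- r$id[r$dominant]
    if (length(dom)) {
      imm <- r$id[grepl("_IM", r$id)]
      is_dom_imm <- (a %in% dom & b %in% imm) | (b %in% dom & a %in% imm)
      p_prox[is_dom_imm] <- dominant_p
    }
    p_con <- p_prox * stats::runif(length(a), contact_frac_range[1],
                                   contact_frac_range[2])
    out[[g]] <- data.frame(a = a, b = b, group = g,
                           p_proximity = p_prox, p_contact = p_con,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("latent_associations", "data.frame"))
}

#' Apply a maternal-loss incident to a latent association set
#'
#' Removes the mother's dyads and additively boosts the orphans' dyads
#' according to the partner's age-sex class, age-mate status (within 2
#' years), and maternal-sibling status. Probabilities are clipped to `[0,1]`
#' with a warning; contact is re-clipped so that contact <= proximity always
#' holds. Dyads not involving an orphan are untouched.
#'
#' @param latent A [latent_associations()] table (pre-loss).
#' @param roster Roster data.frame covering all ids in `latent`.
#' @param incident One row of the incidents table (needs `mother`, `date`).
#' @param orphans Orphan table rows for this incident (needs `id`).
#' @param effects An [orphan_effects()] object.
#' @return The post-period latent set.
#' @export
apply_maternal_loss <- function(latent, roster, incident, orphans, effects) {
  check_that(incident$mother %in% c(latent$a, latent$b),
             "incident's mother absent from the pre-period latent set")
  check_that(all(orphans$id %in% c(latent$a, latent$b)),
             "unknown orphan id")
  post <- latent[latent$a != incident$mother & latent$b != incident$mother, ]
  age_at <- function(ids) years_between(roster$birth_date[match(ids, roster$id)],
                                        incident$date)
  cls_at <- function(ids) as.character(
    age_sex_class(age_at(ids), roster$sex[match(ids, roster$id)],
                  roster$dominant[match(ids, roster$id)]))
  mother_of <- function(ids) roster$mother_id[match(ids, roster$id)]
  boost_of <- function(map, cls) {
    v <- rep(0, length(cls))
    hit <- cls %in% names(map)
    v[hit] <- unlist(map[cls[hit]])
    v
  }
  for (oid in orphans$id) {
    io <- post$a == oid | post$b == oid
    if (!any(io)) next
    partner <- ifelse(post$a[io] == oid, post$b[io], post$a[io])
    pcls <- cls_at(partner)
    add <- boost_of(effects$boost_by_class, pcls)
    if (effects$age_mate_boost != 0) {
      am <- abs(age_at(partner) - age_at(oid)) < 2
      add <- add + effects$age_mate_boost * am
    }
    if (length(effects$sibling_boost_by_class)) {
      sib <- mother_of(partner) == mother_of(oid) &
        mother_of(partner) != "unknown"
      add <- add + boost_of(effects$sibling_boost_by_class, pcls) * sib
    }
    post$p_proximity[io] <- post$p_proximity[io] + add
    post$p_contact[io] <- post$p_contact[io] + add
  }
  if (any(post$p_proximity > 1 | post$p_contact > 1 |
          post$p_proximity < 0 | post$p_contact < 0)) {
    warning("latent probabilities clipped to [0, 1] after orphan boosts")
  }
  post$p_proximity <- pmin(pmax(post$p_proximity, 0), 1)
  post$p_contact <- pmin(pmax(post$p_contact, 0), 1)
  post$p_contact <- pmin(post$p_contact, post$p_proximity)
  post
}

#' Simulate a focal-scan stream
#'
#' Emulates the monitoring protocol: each day, observers work through a
#' randomly ordered list of the group's members; each 50-minute focal
#' contributes five 10-minute instantaneous scans, up to `scans_per_day`
#' scans per group per day. On every scan each co-resident partner enters
#' the 2-m proximity set with its latent `p_proximity` and, conditionally,
#' the affiliative-contact set with `p_contact / p_proximity`, so that the
#' contact set is always a subset of the proximity set.
#'
#' @param roster Roster data.frame (single group or several).
#' @param latent A [latent_associations()] table covering every co-resident
#'   dyad.
#' @param window Length-2 Date vector (first and last day, inclusive).
#' @param scans_per_day Scans per group per day (default 24, i.e. about 4
#'   monitored hours).
#' @param seed Integer seed.
#' @return Data.frame with columns `date`, `group`, `focal`,
#'   `proximity_partners`, `contact_partners` (list columns of id vectors).
#' @export
simulate_focal_scans <- function(roster, latent, window, scans_per_day = 24,
                                 seed = 1L) {
  window <- as.Date(window)
  check_that(length(window) == 2L && window[2] >= window[1], "empty window")
  check_that(scans_per_day >= 1, "negative or zero scans_per_day")
  set.seed(substream_seed(seed, "scans"))
  days <- seq(window[1], window[2], by = "day")
  out <- vector("list", length(days) * length(unique(roster$group)))
  k <- 0L
  for (g in unique(roster$group)) {
    r <- roster[roster$group == g, ]
    lat <- latent[latent$group == g, , drop = FALSE]
    if (nrow(lat) == 0) lat <- latent  # single-group latent without group col match
    # dyad lookup tables
    key <- function(x, y) paste(pmin(x, y), pmax(x, y))
    lkey <- key(lat$a, lat$b)
    for (d in days) {
      d <- as.Date(d, origin = "1970-01-01")
      # alive and resident that day
      alive <- is.na(r$death_date) | r$death_date >= d
      born <- r$birth_date <= d
      ids <- r$id[alive & born]
      if (length(ids) < 2) next
      order_today <- sample(ids)
      focal_seq <- rep(rep(order_today, each = 5L),
                       length.out = scans_per_day)
      for (f in focal_seq) {
        partners <- setdiff(ids, f)
        pk <- key(f, partners)
        idx <- match(pk, lkey)
        pp <- lat$p_proximity[idx]
        pc <- lat$p_contact[idx]
        pp[is.na(pp)] <- 0; pc[is.na(pc)] <- 0
        u <- stats::runif(length(partners))
        prox <- partners[u < pp]
        if (length(prox)) {
          ppx <- pp[match(key(f, prox), pk)]
          pcx <- pc[match(key(f, prox), pk)]
          cond <- ifelse(ppx > 0, pcx / ppx, 0)
          contact <- prox[stats::runif(length(prox)) < cond]
        } else contact <- character(0)
        k <- k + 1L
        out[[k]] <- list(date = d, group = g, focal = f,
                         proximity_partners = prox,
                         contact_partners = contact)
      }
    }
  }
  out <- out[seq_len(k)]
  data.frame(
    date = as.Date(vapply(out, function(x) as.numeric(x$date), numeric(1)),
                   origin = "1970-01-01"),
    group = vapply(out, `[[`, character(1), "group"),
    focal = vapply(out, `[[`, character(1), "focal"),
    proximity_partners = I(lapply(out, `[[`, "proximity_partners")),
    contact_partners = I(lapply(out, `[[`, "contact_partners")),
    stringsAsFactors = FALSE)
}
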