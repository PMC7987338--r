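#' Simple Ratio Index of a dyad
#'
#' The SRI here is the proportion of focal scans of either member of the
#' dyad during which the pair was recorded associating: with one focal per
#' scan, the denominator is the sum of the two members' focal-scan counts
#' and the numerator the number of those scans on which the non-focal
#' member appeared in the relevant partner set.
#'
#' @param scans Focal-scan data.frame (see [simulate_focal_scans()]).
#' @param a,b Ids of the dyad.
#' @param assoc_type `"proximity"` or `"contact"`.
#' @return SRI weight in `[0, 1]`.
#' @export
compute_sri <- function(scans, a, b, assoc_type = c("proximity", "contact")) {
  assoc_type <- match.arg(assoc_type)
  col <- paste0(assoc_type, "_partners")
  fa <- scans$focal == a
  fb <- scans$focal == b
  denom <- sum(fa) + sum(fb)
  if (denom == 0) stop("unsampled dyad: neither member was a focal",
                       call. = FALSE)
  joint <- sum(vapply(which(fa), function(i) b %in% scans[[col]][[i]], logical(1))) +
    sum(vapply(which(fb), function(i) a %in% scans[[col]][[i]], logical(1)))
  joint / denom
}

# internal: SRI adjacency matrix over a fixed node set from a scan subset
sri_matrix <- function(scans, nodes, assoc_type) {
  col <- paste0(assoc_type, "_partners")
  n <- length(nodes)
  counts <- matrix(0, n, n, dimnames = list(nodes, nodes))
  focal_counts <- stats::setNames(integer(n), nodes)
  for (i in seq_len(nrow(scans))) {
    f <- scans$focal[i]
    fi <- match(f, nodes)
    if (is.na(fi)) next
    focal_counts[fi] <- focal_counts[fi] + 1L
    p <- intersect(scans[[col]][[i]], nodes)
    if (length(p)) {
      pi <- match(p, nodes)
      counts[fi, pi] <- counts[fi, pi] + 1L
    }
  }
  joint <- counts + t(counts)
  denom <- outer(focal_counts, focal_counts, `+`)
  w <- ifelse(denom > 0, joint / denom, 0)
  diag(w) <- 0
  list(weights = w, focal_counts = focal_counts)
}

#' Paired pre/post association networks around a maternal-loss incident
#'
#' Builds the weighted undirected SRI network for the 183-day window before
#' the loss and the 183-day window from the loss date onward (the loss day
#' itself belongs to the post window). The node set is identical in both
#' periods: individuals with strictly more than `min_scans` focal scans in
#' *both* windows, excluding the orphans' mother. If an orphan itself fails
#' the scan threshold the incident carries inadequate data and an error of
#' class `inadequate_data` is thrown.
#'
#' @param scans Focal-scan data.frame.
#' @param incident One row of an incidents table (`date`, `mother`, `group`).
#' @param orphans Orphan ids for this incident.
#' @param assoc_type `"proximity"` or `"contact"`.
#' @param min_scans Scan threshold; inclusion requires `> min_scans` scans
#'   in each window (strict inequality).
#' @param window_days Window length in days (183 = six months).
#' @return Object of class `paired_networks`: list with `pre` and `post`
#'   (each class `sri_network` with `nodes`, `focal_counts`, `weights`,
#'   `period`, `assoc_type`, `incident`), plus `mother_sri`, the orphans'
#'   pre-loss SRI with their mother, extracted separately before the mother
#'   is dropped.
#' @export
build_paired_networks <- function(scans, incident, orphans,
                                  assoc_type = c("proximity", "contact"),
                                  min_scans = 12, window_days = 183) {
  assoc_type <- match.arg(assoc_type)
  loss <- as.Date(incident$date)
  pre_w <- c(loss - window_days, loss - 1)
  post_w <- c(loss, loss + window_days - 1)
  in_win <- function(w) scans$date >= w[1] & scans$date <= w[2] &
    scans$group == incident$group
  pre <- scans[in_win(pre_w), , drop = FALSE]
  post <- scans[in_win(post_w), , drop = FALSE]
  if (nrow(pre) == 0) stop("window uncovered: no scans in pre period",
                           call. = FALSE)
  if (nrow(post) == 0) stop("window uncovered: no scans in post period",
                            call. = FALSE)
  cnt <- function(s) table(factor(s$focal, levels = unique(c(pre$focal, post$focal))))
  pre_n <- cnt(pre); post_n <- cnt(post)
  eligible <- names(pre_n)[pre_n > min_scans & post_n > min_scans]
  if (!all(orphans %in% eligible)) {
    stop(structure(class = c("inadequate_data", "error", "condition"),
                   list(message = paste0(
                     "inadequate data: orphan(s) ",
                     paste(setdiff(orphans, eligible), collapse = ", "),
                     " below the focal-scan threshold; incident dropped"),
                     call = NULL)))
  }
  # orphans' pre-loss SRI with the mother, before she is excluded
  mother_sri <- if (incident$mother %in% c(pre$focal,
                                           unlist(pre$proximity_partners))) {
    vapply(orphans, function(o)
      tryCatch(compute_sri(pre, o, incident$mother, assoc_type),
               error = function(e) NA_real_), numeric(1))
  } else stats::setNames(rep(NA_real_, length(orphans)), orphans)
  nodes <- sort(setdiff(eligible, incident$mother))
  if (length(nodes) < 2) stop("fewer than 2 eligible nodes", call. = FALSE)
  mk <- function(s, period) {
    m <- sri_matrix(s, nodes, assoc_type)
    structure(list(incident = incident$incident, period = period,
                   assoc_type = assoc_type, nodes = nodes,
                   focal_counts = m$focal_counts, weights = m$weights),
              class = "sri_network")
  }
  structure(list(pre = mk(pre, "pre"), post = mk(post, "post"),
                 mother_sri = mother_sri, orphans = orphans),
            class = "paired_networks")
}

#' @export
print.sri_network <- function(x, ...) {
  cat(sprintf("SRI network (%s, %s period): %d nodes, %d nonzero edges\n",
              x$assoc_type, x$period, length(x$nodes),
              sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Normalized node metrics of an SRI network
#'
#' Binary degree (number of nonzero edges), weighted degree (sum of
#' incident SRI weights), and eigenvector centrality of the weighted
#' adjacency, each scaled by the maximum over all nodes in the network so
#' every metric lies in `[0, 1]` with at least one node at 1. Eigenvector
#' centrality is computed on the weighted graph; on disconnected networks
#' the score concentrates on the dominant component and isolated nodes
#' score 0.
#'
#' @param network An `sri_network`.
#' @return Data.frame with `node`, `binary_degree_norm`,
#'   `weighted_degree_norm`, `eigenvector`.
#' @export
node_metrics <- function(network) {
  w <- network$weights
  check_that(nrow(w) >= 2, "network needs at least 2 nodes")
  bd <- rowSums(w > 0)
  wd <- rowSums(w)
  if (all(w == 0)) {
    warning("all-zero network: all metrics set to 0")
    ev <- rep(0, nrow(w))
  } else {
    # leading eigenvector of the symmetric weighted adjacency (Perron
    # vector, non-negative); deterministic dense solve
    e <- eigen(w, symmetric = TRUE)
    ev <- abs(e$vectors[, which.max(e$values)])
    ev[bd == 0] <- 0
    ev <- ev / max(ev)
  }
  norm <- function(v) if (max(v) > 0) v / max(v) else v
  data.frame(node = network$nodes,
             binary_degree_norm = norm(bd),
             weighted_degree_norm = norm(wd),
             eigenvector = as.numeric(ev),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Long-format node-metric table for a set of paired networks
#'
#' One row per (incident, node, metric) with the pre value, post value, and
#' their difference — the export format for downstream plotting or archival
#' alongside the change-record table.
#'
#' @param paired_list Named list of `paired_networks`.
#' @param orphan_table Orphan table (`incident`, `id`) used to flag orphans.
#' @return Data.frame with `incident`, `node`, `orphan`, `metric`, `pre`,
#'   `post`, `delta`.
#' @export
network_metric_table <- function(paired_list, orphan_table) {
  rows <- lapply(names(paired_list), function(inc_id) {
    pn <- paired_list[[inc_id]]
    pre <- node_metrics(pn$pre); post <- node_metrics(pn$post)
    orphans <- orphan_table$id[orphan_table$incident == inc_id]
    do.call(rbind, lapply(
      c("binary_degree_norm", "weighted_degree_norm", "eigenvector"),
      function(m) data.frame(
        incident = inc_id, node = pre$node, orphan = pre$node %in% orphans,
        metric = m, pre = pre[[m]],
        post = post[[m]][match(pre$node, post$node)],
        delta = post[[m]][match(pre$node, post$node)] - pre[[m]],
        stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pre-to-post change in node metrics
#'
#' Per-node differences (post minus pre) for each normalized metric,
#' together with the "deviance" covariate: the pre-period value minus the
#' mean pre-period value over the immature nodes of the network (signed),
#' which guards the change model against regression to the mean.
#'
#' @param pre,post [node_metrics()] tables on the same node set.
#' @param immatures Ids of the immature nodes (deviance baseline).
#' @return Data.frame with `node` and, per metric, `delta_*` and
#'   `deviance_*` columns.
#' @export
metric_change <- function(pre, post, immatures = pre$node) {
  check_that(identical(sort(pre$node), sort(post$node)), "node-set mismatch")
  post <- post[match(pre$node, post$node), ]
  imm <- pre$node %in% immatures
  check_that(any(imm), "no immature nodes for the deviance baseline")
  out <- data.frame(node = pre$node, stringsAsFactors = FALSE)
  for (m in c("binary_degree_norm", "weighted_degree_norm", "eigenvector")) {
    out[[paste0("delta_", m)]] <- post[[m]] - pre[[m]]
    out[[paste0("deviance_", m)]] <- pre[[m]] - mean(pre[[m]][imm])
  }
  out
}
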