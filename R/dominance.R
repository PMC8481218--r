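#' Dominant taxa per sample and per zone
#'
#' The per-sample dominant is the taxon with the highest relative abundance
#' in that sample (ties: the taxon that appears first in the table). The
#' zone dominant is the taxon with the highest mean relative abundance over
#' the zone's samples.
#'
#' @param x a [community_ts()] with relative abundances.
#' @param zones optional `zone_labeling` from [cut_zones()]; when supplied,
#'   zone dominants are returned as well.
#' @return A list with `samples` — a tibble `(sample, axis, dominant,
#'   rel_abund)` — and, when `zones` is given, `zones` — a tibble
#'   `(zone, dominant, mean_rel_abund)`.
#' @export
dominance_profile <- function(x, zones = NULL) {
  stopifnot(inherits(x, "community_ts"))
  X <- abundance_matrix(x, "rel_abund")
  work <- X
  work[x$missing] <- -Inf
  idx <- apply(work, 1, which.max)   # which.max: first maximum -> column order
  samples <- tibble(sample = seq_len(nrow(X)), axis = x$axis,
                    dominant = x$taxa[idx],
                    rel_abund = X[cbind(seq_len(nrow(X)), idx)])
  out <- list(samples = samples)
  if (!is.null(zones)) {
    zd <- purrr::map_dfr(seq_len(nrow(zones)), function(z) {
      rows <- zones$start[z]:zones$end[z]
      mu <- colMeans(X[rows, , drop = FALSE], na.rm = TRUE)
      j <- which.max(mu)
      tibble(zone = zones$zone[z], dominant = x$taxa[j], mean_rel_abund = mu[j])
    })
    out$zones <- zd
  }
  out
}

#' Choose a zone count whose zones show the dominance turnovers
#'
#' Scans `k` from 2 up to `cap` and returns the smallest `k` whose zones
#' carry the largest number of distinct zone dominants seen over the scan;
#' `NA` if no cut up to `cap` shows a dominance change at all. Taking the
#' maximum (rather than stopping at the first change) keeps a weaker early
#' turnover visible when a later one — e.g. a strong recovery phase —
#' dominates the coarsest cut. Used as the automatic default when the
#' analyst does not fix `k` from the dendrogram.
#'
#' @param x a [community_ts()].
#' @param tree its [constrained_upgma()] tree.
#' @param cap largest `k` tried (default 6).
#' @return Integer `k`, or `NA_integer_`.
#' @export
choose_zone_count <- function(x, tree, cap = 6) {
  ks <- 2:min(cap, tree$n)
  distinct <- vapply(ks, function(k) {
    zd <- dominance_profile(x, cut_zones(tree, k))$zones$dominant
    length(unique(zd))
  }, integer(1))
  if (max(distinct) < 2) return(NA_integer_)
  ks[which.max(distinct)]
}

#' Locate the collapse-zone boundary and assign zone roles
#'
#' Applies the dominance rule to the zones of a constrained-clustering cut:
#' (a) zones sharing the first zone's dominant are all `pre_collapse`, even
#' when the dendrogram separates them; (b) the collapse zone starts at the
#' first zone whose dominant differs; (c) if the per-sample dominance
#' turnover — the first sample at which the collapse-zone dominant has
#' overtaken the old dominant and stays dominant up to the cluster boundary —
#' occurs strictly earlier than the cluster boundary, the boundary is moved
#' to that sample (the abundance record outranks the dendrogram); (d) zones
#' after the collapse zone whose dominant changes again are `recovery`.
#'
#' If no zone dominant ever changes, all zones stay `pre_collapse` and the
#' labeling carries `collapse_detected = FALSE`.
#'
#' @param x a [community_ts()] with relative abundances, fully observed.
#' @param tree its [constrained_upgma()] tree.
#' @param k zone count; default `NULL` picks [choose_zone_count()] (falling
#'   back to 2 when no dominance change exists at any cut).
#' @return A `zone_labeling` tibble with roles and zone dominants filled in,
#'   and attributes `boundary_sample` (first sample of the collapse zone;
#'   `NA` if none) and `collapse_detected`.
#' @export
collapse_boundary <- function(x, tree, k = NULL) {
  stopifnot(inherits(x, "community_ts"), inherits(tree, "zone_tree"))
  if (is.null(k)) {
    k <- choose_zone_count(x, tree)
    if (is.na(k)) k <- min(2L, tree$n)
  }
  zl <- cut_zones(tree, k)
  prof <- dominance_profile(x, zl)
  zd <- prof$zones$dominant
  # single-sample outlier zones are event samples, not communities: they do
  # not define dominance changes
  outs <- if (tree$n >= 4) detect_tree_outliers(tree) else integer(0)
  is_event_zone <- zl$start == zl$end & zl$start %in% outs
  comm <- which(!is_event_zone)
  pre_dom <- zd[comm[1]]
  first_diff <- comm[which(zd[comm] != pre_dom)[1]]

  if (is.na(first_diff)) {
    return(new_zone_labeling(x$axis, zl$start, zl$end,
                             roles = rep("pre_collapse", nrow(zl)),
                             dominants = zd,
                             boundary_sample = NA_integer_,
                             collapse_detected = FALSE))
  }

  c_start <- zl$start[first_diff]
  c_dom <- zd[first_diff]

  # per-sample turnover override: longest run of the collapse dominant
  # ending right at the cluster boundary pulls the boundary earlier
  sdom <- prof$samples$dominant
  s <- c_start
  while (s > 1 && sdom[s - 1] == c_dom) s <- s - 1L
  boundary <- s

  # rebuild zone breaks: drop cluster breaks swallowed by the override
  starts <- zl$start
  starts <- sort(unique(c(1L, starts[starts < boundary | starts > c_start],
                          boundary)))
  ends <- c(starts[-1] - 1L, tree$n)

  # roles: pre before boundary; recovery from the first later zone whose
  # dominant differs from the collapse dominant; collapse in between
  Xd <- dominance_profile(x, new_zone_labeling(x$axis, starts, ends))$zones
  ev2 <- starts == ends & starts %in% outs
  roles <- character(length(starts))
  phase <- "pre_collapse"
  for (z in seq_along(starts)) {
    if (phase == "pre_collapse" && starts[z] >= boundary) phase <- "collapse"
    if (phase == "collapse" && starts[z] > boundary && !ev2[z] &&
        Xd$dominant[z] != c_dom) {
      phase <- "recovery"
    }
    roles[z] <- phase
  }
  new_zone_labeling(x$axis, starts, ends, roles = roles,
                    dominants = Xd$dominant,
                    boundary_sample = as.integer(boundary),
                    collapse_detected = TRUE)
}
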