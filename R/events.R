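#' Upward threshold crossings of a ratio series
#'
#' Finds every sample at which the ratio moves strictly above `threshold`
#' from at-or-below at the previous valid sample, and flags the crossing as
#' *sustained* when the ratio stays strictly above for at least `persist`
#' consecutive samples (or through the end of the series). A sustained
#' crossing of a temperature-tracking taxon ratio is the signature of a
#' step-like environmental shift, as opposed to the one-sample excursion a
#' pulse leaves.
#'
#' @param ratio an `indicator_series` (see [species_ratio()]).
#' @param threshold critical ratio value (default 0.5).
#' @param persist samples the ratio must stay above the threshold (default 2).
#' @return A tibble `(sample, axis, value, sustained)`.
#' @export
ratio_threshold_crossings <- function(ratio, threshold = 0.5, persist = 2) {
  s <- as_indicator(ratio)
  idx <- which(s$valid & !is.na(s$value))
  v <- s$value[idx]
  out <- list()
  for (p in seq_along(idx)) {
    if (p == 1 || v[p] <= threshold || v[p - 1] > threshold) next
    run <- v[p:length(v)]
    above <- cumprod(run > threshold) == 1
    n_above <- sum(above)
    sustained <- n_above >= persist || all(above)
    out[[length(out) + 1]] <- tibble(sample = idx[p], axis = s$axis[idx[p]],
                                     value = v[p], sustained = sustained)
  }
  if (!length(out)) {
    return(tibble(sample = integer(), axis = numeric(), value = numeric(),
                  sustained = logical()))
  }
  dplyr::bind_rows(out)
}

new_event_calls <- function(rows) {
  cols <- tibble(sample = integer(), axis = numeric(), kind = character(),
                 tree_outlier = logical(), dominant_trough = logical(),
                 indicator_peak = logical(), subcluster_start = logical(),
                 sustained_ratio = logical(), abundance_slope_drop = logical(),
                 confidence = numeric())
  out <- if (is.null(rows) || !nrow(rows)) cols else
    dplyr::bind_rows(cols, rows)
  structure(out, class = c("event_calls", class(tibble())))
}

#' @export
print.event_calls <- function(x, ...) {
  cat("<event_calls> ", nrow(x), " event(s)\n", sep = "")
  NextMethod()
}

#' Detect pulse events
#'
#' A pulse — a one-sample abrupt perturbation such as an impact or transient
#' glaciation — is called at a sample when at least `quorum` of three pieces
#' of evidence co-occur: (i) the sample is a dendrogram outlier
#' ([detect_tree_outliers()]); (ii) the dominant taxon's series has a
#' small-scale trough at the sample or at the immediately following one (the
#' dominant's crash may register one step late); (iii) some non-dominant
#' taxon has a small-scale peak at the sample. Each flag is recorded in the
#' call's evidence ledger; `confidence` is the fraction of flags satisfied.
#'
#' @param x a fully observed [community_ts()] with relative abundances.
#' @param tree its [constrained_upgma()] tree.
#' @param dominant pre-collapse dominant taxon id; default: the dominant of
#'   the first zone of [collapse_boundary()].
#' @param candidates character vector of indicator taxa scanned for peaks;
#'   default all non-dominant taxa.
#' @param outlier_factor see [detect_tree_outliers()].
#' @param span,degree,quantile_prob band parameters for the per-taxon
#'   signal extraction.
#' @param quorum flags required for a call (default 2 of 3).
#' @param peak_alpha familywise false-positive level of the binomial
#'   peak-significance gate, Bonferroni-corrected over the scanned samples
#'   and candidate taxa (default 0.05; used when counts are available).
#' @param pulse_sigma minimum peak excursion in robust (MAD) residual
#'   scales of the taxon's own series — the fallback gate for percent-only
#'   data (default 3).
#' @param before when the collapse boundary is known, its first sample:
#'   detection then runs on the pre-collapse window only (samples strictly
#'   before `before`), the interval over which collapse-triggering events
#'   are defined; `NULL` scans the whole series.
#' @return An `event_calls` tibble (possibly empty) with `kind = "pulse"`.
#' @export
detect_pulse_events <- function(x, tree, dominant = NULL, candidates = NULL,
                                outlier_factor = 2, span = 1, degree = 2,
                                quantile_prob = 0.95, quorum = 2,
                                peak_alpha = 0.05, pulse_sigma = 3,
                                before = NULL) {
  stopifnot(inherits(x, "community_ts"), inherits(tree, "zone_tree"))
  if (is.null(dominant)) {
    zl <- collapse_boundary(x, tree)
    dominant <- zl$dominant[1]
    before <- before %||% attr(zl, "boundary_sample")
  }
  n <- if (is.null(before) || is.na(before)) n_samples(x) else before - 1L
  if (n < degree + 3) return(new_event_calls(NULL))
  xw <- if (n < n_samples(x)) truncate_series(x, n) else x
  candidates <- candidates %||% setdiff(x$taxa, dominant)
  outliers <- detect_tree_outliers(tree, outlier_factor)
  # robustified band for event evidence: excursions flagged by a first fit
  # are masked and the trend refit without them, so one strong feature (a
  # step plateau, an opportunist hump) cannot bend the curve or inflate the
  # residual scale and hide a shallower pulse elsewhere; every sample is
  # then re-judged against the refit band, and the robust residual scale of
  # the refit curve calibrates the pulse-size gate below
  band_of <- function(taxon) {
    s <- dominant_rel_abund(xw, taxon)
    b <- confidence_band(loess_fit_with_se(s, span = span, degree = degree),
                         quantile_prob)
    flagged <- small_scale_signals(b)$sample
    keep <- s$valid & !(seq_len(nrow(s)) %in% flagged)
    if (length(flagged) && sum(keep) >= degree + 2) {
      s2 <- s
      s2$valid <- keep
      fit <- loess_fit_with_se(s2, span = span, degree = degree)
      pr <- suppressWarnings(predict(attr(fit, "loess"),
                                     newdata = data.frame(pos = s$axis),
                                     se = TRUE))
      tq <- qt(quantile_prob, pr$df)
      b$fitted <- as.numeric(pr$fit)
      b$lower <- b$fitted - tq * as.numeric(pr$se.fit)
      b$upper <- b$fitted + tq * as.numeric(pr$se.fit)
    }
    attr(b, "s_rob") <- stats::mad(b$value[b$valid] - b$fitted[b$valid])
    b
  }
  # pulse evidence must be temporary — a one-sample local extremum, since
  # the first sample of a step stays at the new level
  transient <- function(band, kind) {
    sg <- small_scale_signals(band)
    ss <- sg$sample[sg$kind == kind]
    v <- band$value
    keep <- vapply(ss, function(t) {
      if (t <= 1 || t >= length(v)) return(FALSE)
      if (any(!is.finite(v[(t - 1):(t + 1)]))) return(FALSE)
      if (kind == "trough") v[t] < min(v[t - 1], v[t + 1])
      else v[t] > max(v[t - 1], v[t + 1])
    }, logical(1))
    ss[keep]
  }
  troughs <- transient(band_of(dominant), "trough")
  # indicator-peak evidence is scanned over every candidate taxon, so it
  # carries a large multiplicity; each candidate bloom is therefore tested
  # directly: a one-sample local maximum whose count significantly exceeds
  # the taxon's local median composition, by an exact binomial upper tail
  # at a Bonferroni-corrected level (small expected counts are strongly
  # right-skewed, so a normal approximation would leak false peaks). For
  # percent-only data a robust difference-scale gate stands in.
  totals <- if (!is.null(xw$counts)) round(total_abundance(xw)$value) else NULL
  alpha_cell <- peak_alpha / (n * max(1, length(candidates)))
  X <- abundance_matrix(xw, "rel_abund")
  # local reference share: mean of the surrounding window excluding the
  # sample itself, floored at half a count so sparse taxa with all-zero
  # neighbourhoods cannot make a stray single count look significant
  local_ref <- function(v, t) {
    w <- setdiff(max(1, t - 3):min(length(v), t + 3), t)
    mean(v[w], na.rm = TRUE)
  }
  peak_at <- function(tx) {
    j <- match(tx, xw$taxa)
    v <- X[, j]
    ok <- vapply(2:(n - 1), function(t) {
      if (any(!is.finite(v[(t - 1):(t + 1)]))) return(FALSE)
      if (v[t] <= max(v[t - 1], v[t + 1])) return(FALSE)
      floor_p <- if (!is.null(totals)) 0.5 / max(totals[t], 1) else 1e-5
      pref <- min(max(local_ref(v, t) / 100, floor_p), 1 - 1e-5)
      if (!is.null(totals)) {
        stats::pbinom(xw$counts[t, j] - 1, max(totals[t], 1), pref,
                      lower.tail = FALSE) <= alpha_cell
      } else {
        scale_d <- stats::mad(diff(v)) / sqrt(2)
        is.finite(scale_d) && scale_d > 0 &&
          (v[t] - 100 * pref) >= pulse_sigma * scale_d
      }
    }, logical(1))
    which(ok) + 1L
  }
  peak_samples <- unique(unlist(lapply(candidates, peak_at)))
  rows <- purrr::map_dfr(seq_len(n), function(t) {
    f1 <- t %in% outliers
    f2 <- t %in% troughs || (t + 1) %in% troughs
    f3 <- t %in% peak_samples
    votes <- sum(f1, f2, f3)
    if (votes < quorum) return(NULL)
    tibble(sample = t, axis = x$axis[t], kind = "pulse",
           tree_outlier = f1, dominant_trough = f2, indicator_peak = f3,
           confidence = votes / 3)
  })
  new_event_calls(rows)
}

#' Detect step events
#'
#' A step — an abrupt but persistent environmental shift such as sustained
#' warming — is called at a sample when at least `quorum` of three pieces of
#' evidence co-occur: (i) the sample begins a new sub-cluster at a finer cut
#' of the constrained tree; (ii) a monitored taxon ratio crosses its
#' critical threshold there and stays across it
#' ([ratio_threshold_crossings()]); (iii) the loess trend of total
#' abundance has a "gentler" slope change within one sample (only when
#' counts are available; otherwise this flag is inapplicable and recorded
#' `NA`).
#'
#' @param x a fully observed [community_ts()].
#' @param tree its [constrained_upgma()] tree.
#' @param ratio an `indicator_series` of the monitored ratio, or a length-2
#'   character vector `c(numerator, denominator)` of taxa.
#' @param threshold,persist see [ratio_threshold_crossings()].
#' @param subcluster_k explicit zone count for the fine cut; default `NULL`
#'   uses the scale-free rule instead: a sub-cluster starts wherever the
#'   constrained tree keeps adjacent blocks apart at a merge height above
#'   `subcluster_factor` times the median merge height.
#' @param subcluster_factor multiplier of the median merge height for the
#'   automatic sub-cluster rule (default 1.5).
#' @param span,degree,min_run,slope_factor trend parameters for the
#'   total-abundance fit.
#' @param quorum flags required for a call (default 2).
#' @param before first collapse sample, when known: detection is restricted
#'   to the pre-collapse window (samples strictly before `before`); `NULL`
#'   scans the whole series.
#' @return An `event_calls` tibble (possibly empty) with `kind = "step"`.
#' @export
detect_step_events <- function(x, tree, ratio, threshold = 0.5, persist = 2,
                               subcluster_k = NULL, subcluster_factor = 1.5,
                               span = 1, degree = 2,
                               min_run = 3, slope_factor = 2, quorum = 2,
                               before = NULL) {
  stopifnot(inherits(x, "community_ts"), inherits(tree, "zone_tree"))
  if (is.character(ratio)) {
    stopifnot(length(ratio) == 2)
    ratio <- species_ratio(x, ratio[1], ratio[2])
  }
  n <- if (is.null(before) || is.na(before)) n_samples(x) else before - 1L
  if (n < 3) return(new_event_calls(NULL))
  if (is.null(subcluster_k)) {
    m <- tree$merges
    thr <- subcluster_factor * median(m$height)
    zone_starts <- m$right_start[m$height > thr]
  } else {
    zl <- cut_zones(tree, subcluster_k)
    zone_starts <- setdiff(zl$start, 1L)
  }
  rt <- dplyr::slice_head(as_tibble(ratio), n = n)
  cross <- ratio_threshold_crossings(rt, threshold, persist)
  sustained <- cross$sample[cross$sustained]
  drop_near <- integer(0)
  have_counts <- !is.null(x$counts)
  xw <- if (n < n_samples(x)) truncate_series(x, n) else x
  if (have_counts && n >= degree + 3) {
    ta <- total_abundance(xw)
    fit <- loess_fit_with_se(ta, span = span, degree = degree)
    # the large-scale trend must not be bent by one-sample excursions:
    # mask small-scale signals of total abundance and refit
    excur <- small_scale_signals(confidence_band(fit))$sample
    if (length(excur) && sum(ta$valid) - length(excur) >= degree + 2) {
      ta$valid[excur] <- FALSE
      fit <- loess_fit_with_se(ta, span = span, degree = degree)
    }
    ls <- large_scale_signals(fit, min_run, slope_factor)
    g <- dplyr::filter(ls, .data$kind == "slope_change",
                       .data$direction == "gentler")
    if (nrow(g)) {
      drop_near <- unique(unlist(purrr::map2(g$start_sample, g$end_sample,
                                             function(a, b) (a - 1L):(b + 1L))))
    }
  }
  rows <- purrr::map_dfr(seq_len(n), function(t) {
    f1 <- t %in% zone_starts
    f2 <- t %in% sustained
    f3 <- if (have_counts) t %in% drop_near else NA
    votes <- sum(f1, f2, f3, na.rm = TRUE)
    if (votes < quorum) return(NULL)
    tibble(sample = t, axis = x$axis[t], kind = "step",
           subcluster_start = f1, sustained_ratio = f2,
           abundance_slope_drop = f3,
           confidence = votes / sum(!is.na(c(f1, f2, f3))))
  })
  new_event_calls(rows)
}

#' Reconcile pulse and step calls at the same position
#'
#' Persistence is what separates the two event kinds: a step's onset can
#' mimic a pulse for one sample, but not the reverse. When a pulse call
#' falls within `tol` samples of a step call, the pulse call is therefore
#' dropped in favour of the step.
#'
#' @param events an `event_calls` tibble mixing kinds.
#' @param tol coincidence tolerance in samples (default 1).
#' @return The reconciled `event_calls`.
#' @export
reconcile_events <- function(events, tol = 1) {
  steps <- events$sample[events$kind == "step"]
  if (!length(steps)) return(events)
  drop <- events$kind == "pulse" &
    vapply(events$sample, function(t) any(abs(t - steps) <= tol), logical(1))
  new_event_calls(dplyr::filter(as_tibble(events), !drop))
}

#' Write event calls as TSV
#'
#' @param events an `event_calls` tibble.
#' @param path output file path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
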