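#' @keywords internal
new_indicator_series <- function(axis, value, valid, name) {
  structure(tibble(axis = axis, value = value, valid = valid),
            class = c("indicator_series", class(tibble())),
            indicator = name)
}

indicator_name <- function(x) attr(x, "indicator") %||% "indicator"

#' @export
print.indicator_series <- function(x, ...) {
  cat("<indicator_series> ", indicator_name(x), " (", sum(x$valid), "/",
      nrow(x), " valid)\n", sep = "")
  NextMethod()
}

as_indicator <- function(x, axis = NULL, name = "series") {
  if (inherits(x, "indicator_series")) return(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("axis", "value") %in% names(x)))
    v <- if ("valid" %in% names(x)) x$valid else !is.na(x$value)
    return(new_indicator_series(x$axis, x$value, v, name))
  }
  x <- as.numeric(x)
  axis <- axis %||% seq_along(x)
  new_indicator_series(axis, x, !is.na(x), name)
}

#' Total abundance per sample
#'
#' Number of individuals counted in each sample: the per-sample sum of raw
#' counts over taxa. Requires counts — percentages carry no information
#' about assemblage size.
#'
#' @param x a [community_ts()] carrying counts.
#' @return An `indicator_series` tibble `(axis, value, valid)`.
#' @family indicators
#' @export
total_abundance <- function(x) {
  stopifnot(inherits(x, "community_ts"))
  if (is.null(x$counts)) {
    abort("total abundance needs raw counts, not percentages; the series carries none")
  }
  cnt <- x$counts
  cnt[x$missing] <- NA_real_
  new_indicator_series(x$axis, rowSums(cnt, na.rm = TRUE),
                       rep(TRUE, n_samples(x)), "total_abundance")
}

#' Species richness per sample
#'
#' Number of taxa whose abundance exceeds `presence_threshold` in the sample
#' (strictly; masked cells do not count as present).
#'
#' @param x a [community_ts()].
#' @param presence_threshold minimum abundance (same units as the matrix
#'   used) for a taxon to count as present; default 0.
#' @family indicators
#' @export
species_richness <- function(x, presence_threshold = 0) {
  stopifnot(inherits(x, "community_ts"))
  v <- if (!is.null(x$rel_abund)) x$rel_abund else x$counts
  v[x$missing] <- NA_real_
  rich <- rowSums(v > presence_threshold, na.rm = TRUE)
  new_indicator_series(x$axis, as.numeric(rich), rep(TRUE, n_samples(x)),
                       "species_richness")
}

#' Across-taxon standard deviation per sample
#'
#' The sample standard deviation (divisor `m - 1`) of the relative
#' abundances across the taxa of each sample, masked cells excluded. This
#' spreadsheet-style row-wise dispersion is computed without any rolling
#' window; rows with fewer than two observed taxa are marked invalid.
#'
#' @param x a [community_ts()] with relative abundances.
#' @family indicators
#' @export
cross_sd <- function(x) {
  stopifnot(inherits(x, "community_ts"))
  X <- abundance_matrix(x, "rel_abund")
  X[x$missing] <- NA_real_
  v <- apply(X, 1, sd, na.rm = TRUE)
  nobs <- rowSums(!is.na(X))
  new_indicator_series(x$axis, ifelse(nobs >= 2, v, NA_real_), nobs >= 2,
                       "cross_sd")
}

#' Rolling-window lag-1 autoregression
#'
#' The classic critical-slowing-down indicator: for each right-aligned
#' window of `window` consecutive samples, the ordinary least-squares slope
#' (with intercept) of the value at time *t* regressed on the value at
#' *t - 1* over the window's consecutive pairs. The estimate is placed at
#' the window's last sample; samples before the first complete window, and
#' windows with zero lag-variance or any invalid member, are masked.
#'
#' @param x an `indicator_series`, a tibble with `axis`/`value` columns, or
#'   a plain numeric vector.
#' @param window window length in samples (default 20, at least 3).
#' @param axis axis positions when `x` is a bare vector.
#' @family indicators
#' @export
rolling_ar1 <- function(x, window = 20, axis = NULL) {
  s <- as_indicator(x, axis)
  if (window < 3) abort("`window` must be at least 3")
  n <- nrow(s)
  out <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  if (n < window) {
    warn(paste0("series length ", n, " < window ", window,
                "; AR(1) series is all-invalid"))
  } else {
    for (t in window:n) {
      idx <- (t - window + 1L):t
      if (!all(s$valid[idx])) next
      v <- s$value[idx]
      xl <- v[-window]
      y <- v[-1]
      vx <- var(xl)
      if (!is.finite(vx) || vx <= 0) next
      out[t] <- cov(xl, y) / vx
      ok[t] <- TRUE
    }
  }
  new_indicator_series(s$axis, out, ok,
                       paste0("ar1_", indicator_name(s)))
}

match_taxon <- function(x, taxon) {
  j <- match(taxon, x$taxa)
  if (is.na(j)) {
    abort(paste0("unknown taxon '", taxon, "'; known taxa: ",
                 paste(x$taxa, collapse = ", ")))
  }
  j
}

#' Relative abundance of one taxon (typically the pre-collapse dominant)
#'
#' @param x a [community_ts()] with relative abundances.
#' @param taxon taxon identifier.
#' @family indicators
#' @export
dominant_rel_abund <- function(x, taxon) {
  stopifnot(inherits(x, "community_ts"))
  j <- match_taxon(x, taxon)
  X <- abundance_matrix(x, "rel_abund")
  v <- X[, j]
  ok <- !x$missing[, j] & !is.na(v)
  v[!ok] <- NA_real_
  new_indicator_series(x$axis, v, ok, paste0("rel_abund_", taxon))
}

#' Ratio of two taxa's relative abundances
#'
#' Per-sample `numerator / denominator`; samples where the denominator is 0
#' or either cell is unobserved are masked.
#'
#' @param x a [community_ts()] with relative abundances.
#' @param numerator,denominator taxon identifiers.
#' @family indicators
#' @export
species_ratio <- function(x, numerator, denominator) {
  stopifnot(inherits(x, "community_ts"))
  jn <- match_taxon(x, numerator)
  jd <- match_taxon(x, denominator)
  X <- abundance_matrix(x, "rel_abund")
  num <- X[, jn]; den <- X[, jd]
  ok <- !x$missing[, jn] & !x$missing[, jd] & !is.na(num) & !is.na(den) &
    den != 0
  v <- ifelse(ok, num / den, NA_real_)
  new_indicator_series(x$axis, v, ok,
                       paste0("ratio_", numerator, "_", denominator))
}

#' Write an indicator table as TSV
#'
#' One row per sample: axis, then a value and validity column per indicator.
#'
#' @param indicators a named list of `indicator_series` on a common axis.
#' @param path output file path.
#' @export
write_indicator_tsv <- function(indicators, path) {
  stopifnot(length(indicators) > 0)
  axis <- indicators[[1]]$axis
  cols <- list(axis = axis)
  for (nm in names(indicators)) {
    s <- indicators[[nm]]
    stopifnot(identical(s$axis, axis))
    cols[[nm]] <- s$value
    cols[[paste0(nm, "_valid")]] <- s$valid
  }
  utils::write.table(as.data.frame(cols), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
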