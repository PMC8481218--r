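#' Ordered community abundance series
#'
#' `community_ts()` bundles an ordered sample axis (age in Ma, depth in mbsf,
#' or calendar year) with a samples-by-taxa abundance matrix. Either raw
#' counts, relative abundances in percent, or both may be supplied; cells with
#' no observation are tracked in a missing-value mask so that downstream
#' indicators can exclude them rather than treat them as zeros.
#'
#' Analyses in this package always run oldest-to-youngest. For calendar-time
#' axes (`axis_direction = "time"`) the axis must increase; for age or depth
#' axes (`axis_direction = "age_depth"`, Ma or mbsf) it must decrease, since
#' larger ages/depths are older and are placed first.
#'
#' @param axis numeric vector of sample positions, strictly monotonic, length
#'   at least 3.
#' @param counts optional numeric matrix (samples x taxa) of non-negative
#'   raw counts.
#' @param rel_abund optional numeric matrix (samples x taxa) of relative
#'   abundances in percent. At least one of `counts`/`rel_abund` is required.
#' @param taxa character vector of taxon identifiers; defaults to the column
#'   names of the abundance matrix.
#' @param missing optional logical matrix marking unobserved cells; defaults
#'   to `is.na()` of the supplied values.
#' @param axis_direction `"time"` (calendar year, increasing) or
#'   `"age_depth"` (Ma/mbsf, decreasing: oldest first).
#'
#' @return An object of class `community_ts`: a list with elements `axis`,
#'   `taxa`, `counts`, `rel_abund`, `missing`, `axis_direction`.
#' @seealso [read_community_table()], [interpolate_missing()], [to_relative()]
#' @export
#' @examples
#' m <- matrix(c(70, 20, 10, 60, 25, 15, 10, 30, 60), 3, byrow = TRUE,
#'             dimnames = list(NULL, c("A", "B", "C")))
#' community_ts(axis = 1:3, rel_abund = m, axis_direction = "time")
community_ts <- function(axis, counts = NULL, rel_abund = NULL, taxa = NULL,
                         missing = NULL, axis_direction = c("time", "age_depth")) {
  axis_direction <- match.arg(axis_direction)
  if (is.null(counts) && is.null(rel_abund)) {
    abort("supply at least one of `counts` or `rel_abund`")
  }
  ref <- if (!is.null(rel_abund)) rel_abund else counts
  ref <- as.matrix(ref)
  if (is.null(taxa)) taxa <- colnames(ref)
  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(ncol(ref)))
  if (!is.null(counts)) counts <- as.matrix(counts)
  if (!is.null(rel_abund)) rel_abund <- as.matrix(rel_abund)
  if (is.null(missing)) {
    missing <- is.na(ref)
    if (!is.null(counts) && !is.null(rel_abund)) {
      missing <- is.na(counts) | is.na(rel_abund)
    }
  }
  x <- structure(
    list(axis = as.numeric(axis), taxa = as.character(taxa), counts = counts,
         rel_abund = rel_abund, missing = missing,
         axis_direction = axis_direction),
    class = "community_ts"
  )
  validate_community_ts(x)
}

# rowsum_rows: indices whose percent row-sum is checked (NULL = all fully
# observed rows). Interpolated rows are exempt: filling gaps shifts the sum.
validate_community_ts <- function(x, rowsum_rows = NULL, tol = 0.5) {
  n <- length(x$axis)
  if (n < 3) abort("a community series needs at least 3 samples")
  if (anyNA(x$axis)) abort("axis positions must not be missing")
  d <- diff(x$axis)
  if (any(d == 0)) {
    dup <- unique(x$axis[duplicated(x$axis)])
    abort(paste0("duplicate axis positions: ",
                 paste(format(dup), collapse = ", ")))
  }
  ok <- if (x$axis_direction == "time") all(d > 0) else all(d < 0)
  if (!ok) {
    abort(paste0("axis must be strictly ",
                 if (x$axis_direction == "time") "increasing" else
                   "decreasing (oldest = largest Ma/mbsf first)",
                 " for axis_direction = '", x$axis_direction, "'"))
  }
  m <- length(x$taxa)
  for (nm in c("counts", "rel_abund")) {
    v <- x[[nm]]
    if (is.null(v)) next
    if (!all(dim(v) == c(n, m))) abort(paste0("`", nm, "` must be ", n, " x ", m))
    obs <- !x$missing & !is.na(v)
    if (any(v[obs] < 0)) abort(paste0("negative values in `", nm, "`"))
  }
  if (!all(dim(x$missing) == c(n, m))) abort("`missing` mask has wrong shape")
  if (!is.null(x$rel_abund)) {
    obs_row <- rowSums(x$missing | is.na(x$rel_abund)) == 0
    check <- if (is.null(rowsum_rows)) which(obs_row) else
      intersect(rowsum_rows, which(obs_row))
    if (length(check)) {
      rs <- rowSums(x$rel_abund[check, , drop = FALSE])
      bad <- abs(rs - 100) > tol
      if (any(bad)) {
        abort(paste0("relative-abundance rows must sum to 100 ± ", tol,
                     "%; offending sample(s): ",
                     paste(check[bad], collapse = ", "), " (sum ",
                     paste(format(rs[bad], digits = 5), collapse = ", "), ")"))
      }
    }
    if (!is.null(x$counts)) {
      cnt <- x$counts
      cnt[x$missing] <- NA_real_
      rs <- rowSums(cnt, na.rm = TRUE)
      comp <- which(rs > 0)
      if (!is.null(rowsum_rows)) comp <- intersect(comp, rowsum_rows)
      expect <- sweep(cnt[comp, , drop = FALSE], 1, rs[comp], "/") * 100
      diffm <- abs(expect - x$rel_abund[comp, , drop = FALSE])
      if (any(diffm > tol, na.rm = TRUE)) {
        abort("`rel_abund` disagrees with 100 * counts / rowsum(counts)")
      }
    }
  }
  x
}

#' @export
print.community_ts <- function(x, ...) {
  cat("<community_ts> ", n_samples(x), " samples x ", length(x$taxa),
      " taxa\n", sep = "")
  cat("  axis: ", format(x$axis[1]), " ... ", format(x$axis[n_samples(x)]),
      " (", x$axis_direction, ", oldest first)\n", sep = "")
  cat("  values: ",
      paste(c("counts", "rel_abund")[!c(is.null(x$counts), is.null(x$rel_abund))],
            collapse = " + "),
      "; missing cells: ", sum(x$missing), "\n", sep = "")
  invisible(x)
}

n_samples <- function(x) length(x$axis)

#' @method as_tibble community_ts
#' @export
as_tibble.community_ts <- function(x, ..., values = c("rel_abund", "counts")) {
  values <- match.arg(values)
  v <- x[[values]]
  if (is.null(v)) abort(paste0("series carries no `", values, "`"))
  v[x$missing] <- NA_real_
  out <- as_tibble(as.data.frame(v))
  names(out) <- x$taxa
  dplyr::bind_cols(tibble(axis = x$axis), out)
}

# matrix of relative abundances (preferred) or counts, for internal use
abundance_matrix <- function(x, what = c("rel_abund", "counts")) {
  what <- match.arg(what)
  v <- x[[what]]
  if (is.null(v)) abort(paste0("series carries no `", what, "`"))
  v
}

# restrict a series to its first `upto` samples (pre-collapse windowing)
truncate_series <- function(x, upto) {
  upto <- as.integer(upto)
  stopifnot(upto >= 3, upto <= n_samples(x))
  idx <- seq_len(upto)
  out <- structure(
    list(axis = x$axis[idx],
         taxa = x$taxa,
         counts = if (!is.null(x$counts)) x$counts[idx, , drop = FALSE],
         rel_abund = if (!is.null(x$rel_abund))
           x$rel_abund[idx, , drop = FALSE],
         missing = x$missing[idx, , drop = FALSE],
         axis_direction = x$axis_direction),
    class = "community_ts")
  validate_community_ts(out, rowsum_rows = integer(0))
}

require_complete <- function(x, op) {
  if (any(x$missing)) {
    abort(paste0(op, " needs a fully observed series; run interpolate_missing() first"))
  }
  invisible(x)
}

#' Read an ordered community abundance table
#'
#' Reads a delimited text table in the layout used by open paleo-data
#' supplements: the first column (or a named column) is the ordered axis, the
#' remaining columns are taxa, blank/NA cells are unobserved. Rows are sorted
#' oldest-first according to `axis_direction`.
#'
#' @param path file path of a tab- or comma-delimited UTF-8 table with a
#'   header row.
#' @param value_kind whether the body holds relative abundances in percent
#'   (default) or raw counts.
#' @param axis_col column name (or index) of the axis; default first column.
#' @param axis_direction see [community_ts()]. `"age_depth"` covers both Ma
#'   and mbsf axes.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A [community_ts()].
#' @export
read_community_table <- function(path, value_kind = c("percent", "counts"),
                                 axis_col = 1L,
                                 axis_direction = c("time", "age_depth"),
                                 sep = NULL) {
  value_kind <- match.arg(value_kind)
  axis_direction <- match.arg(axis_direction)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("", "NA", "NaN"), quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (is.character(axis_col)) {
    if (!axis_col %in% names(df)) abort(paste0("no column named '", axis_col, "'"))
    axis_idx <- match(axis_col, names(df))
  } else axis_idx <- as.integer(axis_col)
  axis <- as.numeric(df[[axis_idx]])
  vals <- as.matrix(df[, -axis_idx, drop = FALSE])
  storage.mode(vals) <- "double"
  ord <- order(axis, decreasing = (axis_direction == "age_depth"))
  axis <- axis[ord]
  vals <- vals[ord, , drop = FALSE]
  if (value_kind == "percent") {
    community_ts(axis, rel_abund = vals, taxa = colnames(vals),
                 axis_direction = axis_direction)
  } else {
    community_ts(axis, counts = vals, taxa = colnames(vals),
                 axis_direction = axis_direction)
  }
}

#' Write a community series back to delimited text
#'
#' Inverse of [read_community_table()]: axis first column, one column per
#' taxon, masked cells written as empty fields.
#'
#' @param x a [community_ts()].
#' @param path output file path.
#' @param values which matrix to write.
#' @param sep field separator.
#' @param axis_name header for the axis column.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(x, path, values = c("rel_abund", "counts"),
                                  sep = "\t", axis_name = "axis") {
  values <- match.arg(values)
  v <- abundance_matrix(x, values)
  v[x$missing] <- NA_real_
  df <- data.frame(x$axis, v, check.names = FALSE)
  names(df) <- c(axis_name, x$taxa)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Fill unobserved cells by linear interpolation along the axis
#'
#' Gaps are filled per taxon by 1-D linear interpolation against the axis
#' coordinate (not the row index, so uneven stratigraphic spacing is
#' respected); leading and trailing gaps take the nearest observed value.
#' The missing-value mask is cleared; observed cells are unchanged. The
#' operation is idempotent.
#'
#' @param x a [community_ts()].
#' @return A fully observed [community_ts()].
#' @export
interpolate_missing <- function(x) {
  stopifnot(inherits(x, "community_ts"))
  if (!any(x$missing)) return(x)
  had_gap <- which(rowSums(x$missing) > 0)
  fill <- function(v) {
    obs <- !x$missing[, j] & !is.na(v)
    if (!any(obs)) abort(paste0("taxon '", x$taxa[j], "' has no observed values"))
    if (all(obs)) return(v)
    approx(x$axis[obs], v[obs], xout = x$axis, method = "linear", rule = 2)$y
  }
  for (j in seq_along(x$taxa)) {
    if (!is.null(x$counts)) x$counts[, j] <- fill(x$counts[, j])
    if (!is.null(x$rel_abund)) x$rel_abund[, j] <- fill(x$rel_abund[, j])
  }
  x$missing[] <- FALSE
  # interpolated rows are exempt from the percent row-sum check: filling a
  # gap by per-taxon interpolation does not preserve closure to 100%
  validate_community_ts(x, rowsum_rows = setdiff(seq_len(n_samples(x)), had_gap))
}

#' Convert counts to relative abundances (percent)
#'
#' @param x a [community_ts()] carrying counts.
#' @return The series with `rel_abund` set to `100 * count / rowsum` per
#'   sample; counts are retained.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "community_ts"))
  cnt <- abundance_matrix(x, "counts")
  work <- cnt
  work[x$missing] <- NA_real_
  rs <- rowSums(work, na.rm = TRUE)
  if (any(rs == 0)) {
    abort(paste0("sample(s) with zero total count: ",
                 paste(which(rs == 0), collapse = ", ")))
  }
  x$rel_abund <- sweep(work, 1, rs, "/") * 100
  x$rel_abund[x$missing] <- NA_real_
  validate_community_ts(x, tol = 1e-6)
}
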