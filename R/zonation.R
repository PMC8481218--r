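#' Temporally constrained UPGMA clustering (stratigraphic zonation)
#'
#' Agglomerative average-linkage (UPGMA) clustering of samples on the
#' Euclidean distances between their relative-abundance vectors, with the
#' temporal constraint that only blocks of adjacent samples may merge. Every
#' cut of the resulting tree therefore yields contiguous zones, the standard
#' zonation device of stratigraphic ecology. Inter-cluster distance is the
#' arithmetic mean of all cross-pair sample distances, maintained with the
#' exact Lance-Williams update for average linkage.
#'
#' Equal candidate heights are resolved by merging the left-most (oldest)
#' pair first, so the tree is deterministic.
#'
#' @param x a [community_ts()] with relative abundances and no missing cells
#'   (see [interpolate_missing()]).
#' @return An object of class `zone_tree`: a list with `merges` (a tibble
#'   with one row per merge: the two joined blocks as sample-index intervals,
#'   the boundary position between them, and the UPGMA height), `n`, and the
#'   sample `axis`.
#' @seealso [cut_zones()], [detect_tree_outliers()], [collapse_boundary()]
#' @export
constrained_upgma <- function(x) {
  stopifnot(inherits(x, "community_ts"))
  require_complete(x, "constrained_upgma()")
  X <- abundance_matrix(x, "rel_abund")
  n <- nrow(X)
  D <- as.matrix(dist(X))
  size <- rep(1L, n)
  lo <- seq_len(n)       # block start per active cluster
  hi <- seq_len(n)       # block end
  active <- seq_len(n)   # column indices into D of active clusters, in order
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    adj <- D[cbind(active[-k], active[-1L])]
    m <- which.min(adj)                     # ties -> left-most pair
    i <- active[m]; j <- active[m + 1L]
    h <- adj[m]
    merges[[step]] <- tibble(
      step = step,
      left_start = lo[i], left_end = hi[i],
      right_start = lo[j], right_end = hi[j],
      height = h
    )
    # Lance-Williams average-linkage update against every other cluster
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      dnew <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[i, others] <- dnew
      D[others, i] <- dnew
    }
    size[i] <- size[i] + size[j]
    hi[i] <- hi[j]
    active <- active[-(m + 1L)]
  }
  structure(list(merges = dplyr::bind_rows(merges), n = n, axis = x$axis),
            class = "zone_tree")
}

#' @export
print.zone_tree <- function(x, ...) {
  cat("<zone_tree> constrained UPGMA over", x$n, "samples\n")
  print(x$merges, ...)
  invisible(x)
}

#' @rdname constrained_upgma
#' @param x,... a `zone_tree`; further arguments ignored.
#' @method tidy zone_tree
#' @export
tidy.zone_tree <- function(x, ...) x$merges

#' @method glance zone_tree
#' @export
glance.zone_tree <- function(x, ...) {
  tibble(n_samples = x$n, n_merges = nrow(x$merges),
         height_median = median(x$merges$height),
         height_max = max(x$merges$height))
}

# step index of the merge that created block [s, e] (NA for singletons)
merge_of_block <- function(tree, s, e) {
  if (s == e) return(NA_integer_)
  m <- tree$merges
  idx <- which(m$left_start == s & m$right_end == e)
  stopifnot(length(idx) == 1L)
  m$step[idx]
}

#' Cut a constrained tree into contiguous zones
#'
#' Splits the tree top-down into `k` contiguous blocks by undoing `k - 1`
#' merges, always undoing the highest merge among those currently at the top
#' of a retained subtree (equal heights: the later merge is undone first).
#' For a height-monotone tree this is exactly "undo the k - 1 highest
#' merges"; the top-down formulation stays well defined when constrained
#' trees contain height reversals, and makes cuts nested in `k`.
#'
#' @param tree a [constrained_upgma()] tree.
#' @param k number of zones, `1 <= k <= n`.
#' @return A `zone_labeling` tibble: one row per zone with sample-index
#'   interval (`start`, `end`), axis interval, mean-abundance dominant
#'   (`NA` here; see [collapse_boundary()]), and `role = "unassigned"`.
#' @export
cut_zones <- function(tree, k) {
  stopifnot(inherits(tree, "zone_tree"))
  n <- tree$n
  if (!(k >= 1 && k <= n)) abort(paste0("k must be in [1, ", n, "]"))
  m <- tree$merges
  # top merges of retained subtrees, as merge steps; NA = singleton block
  top <- merge_of_block(tree, 1L, n)
  blocks <- list(c(1L, n, top))
  while (length(blocks) < k) {
    cand <- vapply(blocks, function(b) b[3], numeric(1))
    hs <- ifelse(is.na(cand), -Inf, m$height[cand])
    pick <- order(hs, ifelse(is.na(cand), -Inf, cand), decreasing = TRUE)[1]
    b <- blocks[[pick]]
    row <- m[b[3], ]
    left <- c(row$left_start, row$left_end,
              merge_of_block(tree, row$left_start, row$left_end))
    right <- c(row$right_start, row$right_end,
               merge_of_block(tree, row$right_start, row$right_end))
    blocks <- append(blocks[-pick], list(left, right))
  }
  starts <- sort(vapply(blocks, function(b) b[1], numeric(1)))
  ends <- sort(vapply(blocks, function(b) b[2], numeric(1)))
  new_zone_labeling(tree$axis, as.integer(starts), as.integer(ends))
}

new_zone_labeling <- function(axis, starts, ends, roles = NULL,
                              dominants = NULL, boundary_sample = NA_integer_,
                              collapse_detected = FALSE) {
  z <- tibble(
    zone = seq_along(starts),
    start = starts, end = ends,
    axis_start = axis[starts], axis_end = axis[ends],
    dominant = dominants %||% rep(NA_character_, length(starts)),
    role = roles %||% rep("unassigned", length(starts))
  )
  structure(z, class = c("zone_labeling", class(tibble())),
            boundary_sample = boundary_sample,
            collapse_detected = collapse_detected)
}

#' @export
print.zone_labeling <- function(x, ...) {
  cat("<zone_labeling> ", nrow(x), " zones; collapse ",
      if (isTRUE(attr(x, "collapse_detected")))
        paste0("boundary at sample ", attr(x, "boundary_sample"))
      else "not detected", "\n", sep = "")
  NextMethod()
}

#' Flag dendrogram outlier samples
#'
#' A sample is an outlier when it joins the tree as a singleton block at a
#' height exceeding `factor` times the median of all merge heights — the
#' dendrogram signature of a one-sample (pulse) perturbation.
#'
#' @param tree a [constrained_upgma()] tree over at least 4 samples.
#' @param factor positive multiplier of the median merge height (default 2).
#' @return Integer vector of outlier sample indices (possibly empty).
#' @export
detect_tree_outliers <- function(tree, factor = 2) {
  stopifnot(inherits(tree, "zone_tree"), factor > 0)
  if (tree$n < 4) abort("outlier detection needs at least 4 samples")
  m <- tree$merges
  thr <- factor * median(m$height)
  out <- integer(0)
  for (r in seq_len(nrow(m))) {
    if (m$height[r] > thr) {
      if (m$left_start[r] == m$left_end[r]) out <- c(out, m$left_start[r])
      if (m$right_start[r] == m$right_end[r]) out <- c(out, m$right_start[r])
    }
  }
  sort(unique(out))
}

#' Export a constrained tree
#'
#' `as.hclust()` converts to the base-R dendrogram representation (heights
#' may contain reversals, which `stats::hclust` plots with a warning);
#' `write_tree_newick()` writes a Newick string via \pkg{ape} with merge
#' heights as node depths.
#'
#' @param x a `zone_tree`.
#' @param ... ignored.
#' @return An `hclust` object, or (invisibly) the Newick file path.
#' @export
as.hclust.zone_tree <- function(x, ...) {
  m <- x$merges
  n <- x$n
  id_of <- function(s, e, upto) {
    if (s == e) return(-s)
    idx <- which(m$left_start == s & m$right_end == e & m$step < upto)
    m$step[idx]
  }
  merge <- matrix(0L, n - 1L, 2L)
  for (r in seq_len(n - 1L)) {
    merge[r, 1] <- id_of(m$left_start[r], m$left_end[r], r)
    merge[r, 2] <- id_of(m$right_start[r], m$right_end[r], r)
  }
  structure(list(merge = merge, height = m$height, order = seq_len(n),
                 labels = as.character(x$axis), method = "constrained-upgma",
                 dist.method = "euclidean"),
            class = "hclust")
}

#' @rdname as.hclust.zone_tree
#' @param tree a `zone_tree`.
#' @param path output file path.
#' @export
write_tree_newick <- function(tree, path) {
  hc <- as.hclust.zone_tree(tree)
  # guard against small height reversals, which ape rejects
  hc$height <- cummax(hc$height)
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' @rdname cut_zones
#' @param x a `zone_labeling`.
#' @param path output TSV path.
#' @export
write_zones_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
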