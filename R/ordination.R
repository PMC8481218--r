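#' Principal component ordination of a community series
#'
#' Eigendecomposition of the covariance matrix of the column-centered
#' relative-abundance matrix (samples as observations, taxa as variables;
#' `n - 1` divisor). Components are ordered by decreasing eigenvalue; each
#' component's sign is fixed so that its largest-magnitude taxon loading is
#' positive.
#'
#' @param x a [community_ts()] with relative abundances, at least 2 samples,
#'   no missing cells.
#' @return An object of class `pca_result` with `eigenvalues`, `scores`
#'   (samples x components), `loadings` (taxa x components), `center`
#'   (removed taxon means), `taxa`, `axis`.
#' @export
pca_covariance <- function(x) {
  stopifnot(inherits(x, "community_ts"))
  require_complete(x, "pca_covariance()")
  X <- abundance_matrix(x, "rel_abund")
  if (nrow(X) < 2) abort("PCA needs at least 2 samples")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  eg <- eigen(cov(X), symmetric = TRUE)
  V <- eg$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(x$taxa, paste0("PC", seq_len(ncol(V))))
  scores <- Xc %*% V
  structure(list(eigenvalues = eg$values, scores = scores, loadings = V,
                 center = ctr, taxa = x$taxa, axis = x$axis),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- pmax(x$eigenvalues, 0)
  cat("<pca_result>", length(x$axis), "samples,", length(x$taxa), "taxa\n")
  cat("  var explained (PC1..PC3):",
      paste0(format(100 * ev[seq_len(min(3, length(ev)))] / sum(ev),
                    digits = 3), "%", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pca_covariance
#' @param x,... a `pca_result`; further arguments ignored.
#' @param matrix which quantity to tabulate: per-sample `"scores"`,
#'   per-taxon `"loadings"`, or the `"eigenvalues"`.
#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                            ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = dplyr::bind_cols(tibble(sample = seq_along(x$axis), axis = x$axis),
                              as_tibble(as.data.frame(x$scores))),
    loadings = dplyr::bind_cols(tibble(taxon = x$taxa),
                                as_tibble(as.data.frame(x$loadings))),
    eigenvalues = tibble(component = seq_along(x$eigenvalues),
                         eigenvalue = x$eigenvalues,
                         prop_variance = pmax(x$eigenvalues, 0) /
                           sum(pmax(x$eigenvalues, 0)))
  )
}

#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  ev <- pmax(x$eigenvalues, 0)
  tibble(n_samples = length(x$axis), n_taxa = length(x$taxa),
         total_variance = sum(x$eigenvalues),
         prop_pc1 = ev[1] / sum(ev),
         prop_pc12 = sum(ev[seq_len(min(2, length(ev)))]) / sum(ev))
}
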