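#' Classical multidimensional scaling of pairwise F_ST
#'
#' Embeds samples by classical (Torgerson) MDS of the pairwise theta matrix:
#' double-centre the squared distances and keep the top-`k` eigenvectors
#' scaled by the square root of their eigenvalues. Pairwise theta can be
#' slightly negative while a distance cannot, so negative cells are clamped
#' to zero before squaring. Negative eigenvalues are truncated; if fewer than
#' `k` positive eigenvalues exist, `k` is reduced with a warning.
#'
#' Coordinates are determined only up to sign and rotation; downstream
#' checks should compare inter-point distances, not raw coordinates.
#'
#' @param x A `pairwise_fst` object or a symmetric numeric matrix.
#' @param k Embedding dimension (default 2).
#' @return An object of class `fst_mds`: a tibble with columns `sample`,
#'   `dim1` ... `dimk`, with the eigenvalues (descending) in attribute
#'   `eigenvalues`. The coordinate centroid is at the origin.
#' @export
fst_mds <- function(x, k = 2) {
  m <- if (inherits(x, "pairwise_fst")) as.matrix(x) else as.matrix(x)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort("`x` must be a symmetric matrix (or pairwise_fst).")
  }
  if (anyNA(m)) abort("Distance matrix contains missing cells; cannot embed.")
  if (k < 1) abort("`k` must be at least 1.")
  m[m < 0] <- 0
  diag(m) <- 0
  fit <- stats::cmdscale(stats::as.dist(m), k = min(k, nrow(m) - 1), eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > max(eig) * 1e-9)
  if (k > n_pos) {
    warn(sprintf("Only %d positive eigenvalue(s); reducing k from %d.", n_pos, k))
    k <- max(1L, n_pos)
    fit <- stats::cmdscale(stats::as.dist(m), k = k, eig = TRUE)
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  labs <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  out <- as_tibble(setNames(as.data.frame(coords), paste0("dim", seq_len(k))))
  out <- dplyr::bind_cols(tibble(sample = labs), out)
  structure(out, eigenvalues = sort(eig, decreasing = TRUE),
            class = c("fst_mds", class(out)))
}

#' @describeIn fst_mds Scatter plot of the first two embedding dimensions.
#' @param object An `fst_mds` object.
#' @param ... Unused.
#' @method autoplot fst_mds
#' @export
autoplot.fst_mds <- function(object, ...) {
  if (!"dim2" %in% names(object)) object$dim2 <- 0
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dim1, y = .data$dim2, label = .data$sample)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "MDS 1", y = "MDS 2",
                  title = "Classical MDS of pairwise F_ST") +
    ggplot2::theme_minimal()
}

#' @describeIn pairwise_fst Heatmap of the pairwise theta matrix.
#' @param object A `pairwise_fst` object.
#' @param ... Unused.
#' @method autoplot pairwise_fst
#' @export
autoplot.pairwise_fst <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_1, y = .data$sample_2, fill = .data$theta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                                  midpoint = 0, name = expression(theta)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pairwise Weir-Cockerham theta") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
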