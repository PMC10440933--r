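# Population structure: pairwise identity-by-state distance and
# classical (metric) multidimensional scaling.

#' Pairwise IBS distance matrix
#'
#' `d(i, j) = 1 - (IBS2 + 0.5 * IBS1) / n_joint` over jointly
#' non-missing variants, the allele-sharing distance behind MDS plots
#' of population structure.  Run on MAF-filtered, LD-pruned genotypes.
#'
#' @param geno A [genotype_matrix()].
#' @return Symmetric numeric matrix with zero diagonal, sample IDs as
#'   dimnames, values in `[0, 1]`.
#' @export
ibs_distance <- function(geno) {
  n <- n_samples(geno)
  calls <- geno$calls
  d <- matrix(0, n, n,
              dimnames = list(geno$samples$sample_id,
                              geno$samples$sample_id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
      nj <- sum(ok)
      if (nj == 0) abort_rohscan("pair with zero jointly observed variants: ",
                                 rownames(d)[i], " / ", rownames(d)[j])
      ibs <- 2 - abs(calls[i, ok] - calls[j, ok])
      d[i, j] <- d[j, i] <- 1 - sum(ibs / 2) / nj
    }
  }
  d
}

#' Classical multidimensional scaling
#'
#' Metric MDS via double-centering of squared distances and
#' eigendecomposition; coordinates are the top-`k_dims` eigenvectors
#' scaled by the square root of their (non-negative) eigenvalues,
#' ordered by descending eigenvalue.  Axes follow the sign convention
#' that the first nonzero loading of each axis (taking samples in ID
#' order, so the result is permutation-invariant) is positive.  If fewer
#' than `k_dims` positive eigenvalues exist, the result is truncated
#' with a warning; negative eigenvalues are reported but never used
#' for scaling.
#'
#' @param dist Symmetric distance matrix (e.g. from [ibs_distance()]).
#' @param k_dims Number of dimensions requested, default 2.
#' @param samples Optional tibble with `sample_id` (and `species`) to
#'   attach to the coordinates.
#' @return Object of class `roh_mds`: list with `coordinates` (tibble:
#'   `sample_id`, `C1..Ck`, optional `species`) and `eigenvalues`.
#' @export
classical_mds <- function(dist, k_dims = 2, samples = NULL) {
  stopifnot(k_dims >= 1)
  n <- nrow(dist)
  fit <- stats::cmdscale(stats::as.dist(dist), k = min(k_dims, n - 1),
                         eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  k_eff <- min(k_dims, n_pos)
  if (k_eff < k_dims) {
    warning("only ", k_eff, " positive-eigenvalue dimension(s) available; ",
            "requested ", k_dims)
  }
  pts <- fit$points[, seq_len(k_eff), drop = FALSE]
  # sign convention: first nonzero loading positive, "first" taken in
  # sample-ID order so the coordinates are invariant to row permutation
  id_order <- order(rownames(dist))
  for (c in seq_len(ncol(pts))) {
    nz <- id_order[abs(pts[id_order, c]) > 1e-12]
    if (length(nz) > 0 && pts[nz[1], c] < 0) pts[, c] <- -pts[, c]
  }
  coords <- tibble::tibble(sample_id = rownames(dist))
  for (c in seq_len(ncol(pts))) coords[[paste0("C", c)]] <- pts[, c]
  if (!is.null(samples)) {
    coords <- dplyr::left_join(coords, tibble::as_tibble(samples),
                               by = "sample_id")
  }
  structure(list(coordinates = coords, eigenvalues = eig),
            class = "roh_mds")
}

#' @export
print.roh_mds <- function(x, ...) {
  k <- sum(grepl("^C[0-9]+$", names(x$coordinates)))
  cat(sprintf("<roh_mds> %d samples in %d dimension(s)\n",
              nrow(x$coordinates), k))
  invisible(x)
}

#' Tidy MDS coordinates
#' @param x A `roh_mds` object.
#' @param ... Unused.
#' @return The coordinate tibble.
#' @method tidy roh_mds
#' @export
tidy.roh_mds <- function(x, ...) x$coordinates

#' @rdname tidy.roh_mds
#' @return For `glance`: one-row tibble with eigenvalue diagnostics.
#' @method glance roh_mds
#' @export
glance.roh_mds <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_positive_eigenvalues = sum(x$eigenvalues > 0),
    n_negative_eigenvalues = sum(x$eigenvalues < 0),
    prop_variance_first_two = sum(pmax(x$eigenvalues, 0)[1:2]) /
      sum(pmax(x$eigenvalues, 0))
  )
}

#' Plot MDS coordinates
#'
#' Scatter of the first two MDS dimensions, coloured by species when
#' available.
#'
#' @param object A `roh_mds` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roh_mds
#' @export
autoplot.roh_mds <- function(object, ...) {
  d <- object$coordinates
  if (!all(c("C1", "C2") %in% names(d))) {
    abort_rohscan("need at least two MDS dimensions to plot")
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$C1, y = .data$C2))
  p <- if ("species" %in% names(d)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$species), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = "Dimension 1", y = "Dimension 2",
                    title = "Classical MDS of IBS distances") +
    ggplot2::theme_minimal()
}
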