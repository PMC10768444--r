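# Classical (Torgerson) multidimensional scaling of a profile-distance
# matrix, for visualisation and outlier inspection. MDS coordinates are
# defined up to rotation and reflection, so embeddings are only ever
# compared through their pairwise distances.

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centres `-D^2/2`, eigendecomposes, and scales the top eigenvectors
#' (via [stats::cmdscale()]). Dimensions with non-positive eigenvalues --
#' which arise when down-sampling noise makes the matrix slightly
#' non-Euclidean -- are clipped with a warning, following classical-scaling
#' convention. Coordinates are centred at the origin and ordered by
#' descending eigenvalue.
#'
#' @param D symmetric distance matrix with zero diagonal and sample-id
#'   dimnames.
#' @param k number of requested dimensions.
#' @return object of class `mds_embedding`: `points` (n x k' matrix,
#'   `k' <= k`), `eig` (full spectrum), `sample_ids`, `k_requested`.
#' @export
classical_mds <- function(D, k = 2L) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("D must be a symmetric matrix")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  if (any(D < 0)) stop("D must be non-negative")
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(D)
  fit <- stats::cmdscale(D, k = min(k, n - 1L), eig = TRUE)
  eig <- fit$eig
  pts <- as.matrix(fit$points)
  pos <- which(eig[seq_len(ncol(pts))] > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (length(pos) < ncol(pts)) {
    warning(sprintf(
      "clipping %d dimension(s) with non-positive eigenvalues",
      ncol(pts) - length(pos)))
    pts <- pts[, pos, drop = FALSE]
  }
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  rownames(pts) <- rownames(D) %||% paste0("s", seq_len(n))
  structure(list(points = pts, eig = eig,
                 sample_ids = rownames(pts), k_requested = as.integer(k)),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d samples in %d dimension(s)\n",
              nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' Group colours used in the cohort plots
#' @keywords internal
group_palette <- function() {
  c(MEsa = "red", MEmm = "gold", MS = "green3", HC = "blue",
    unknown = "grey50")
}

#' Plot an MDS embedding coloured by sample group
#'
#' Scatter of the requested axes, coloured by group (MEsa red, MEmm yellow,
#' MS green, HC blue). With three axes a panel is drawn for each axis pair
#' (1-2, 1-3, 2-3). Samples missing from the metadata are shown as
#' "unknown" with a warning.
#'
#' @param e an [classical_mds()] embedding.
#' @param metadata data frame with columns `sample_id` and `group`.
#' @param axes `c(1, 2)` or `c(1, 2, 3)`.
#' @param file optional output path (`.png`/`.pdf`/`.svg`); when given the
#'   figure is written there.
#' @return the ggplot object, invisibly if written to file.
#' @export
plot_embedding <- function(e, metadata, axes = c(1, 2), file = NULL) {
  stopifnot(inherits(e, "mds_embedding"))
  if (nrow(e$points) == 0L) stop("empty embedding")
  axes <- as.integer(axes)
  if (any(axes > ncol(e$points)))
    stop("requested axis exceeds available dimensions")
  grp <- metadata$group[match(e$sample_ids, metadata$sample_id)]
  if (anyNA(grp)) {
    warning("samples missing from metadata rendered as 'unknown'")
    grp[is.na(grp)] <- "unknown"
  }
  base <- tibble::tibble(sample_id = e$sample_ids, group = grp)
  pairs <- if (length(axes) >= 3L)
    list(axes[c(1, 2)], axes[c(1, 3)], axes[c(2, 3)]) else list(axes[1:2])
  df <- dplyr::bind_rows(lapply(pairs, function(ax) {
    dplyr::mutate(base,
                  x = e$points[, ax[1]], y = e$points[, ax[2]],
                  panel = sprintf("dim%d vs dim%d", ax[1], ax[2]))
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = group_palette()) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, colour = "group") +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 5 * length(pairs), height = 4.5,
                    dpi = 150)
    return(invisible(p))
  }
  p
}

#' Write embedding coordinates and eigenvalues as TSV
#'
#' @param e an [classical_mds()] embedding.
#' @param coords_path,eig_path output files (either may be `NULL`).
#' @return `e`, invisibly.
#' @export
write_embedding <- function(e, coords_path = NULL, eig_path = NULL) {
  if (!is.null(coords_path)) {
    df <- data.frame(sample_id = e$sample_ids, e$points, check.names = FALSE)
    utils::write.table(df, coords_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(eig_path)) {
    utils::write.table(
      data.frame(dimension = seq_along(e$eig), eigenvalue = e$eig),
      eig_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(e)
}
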