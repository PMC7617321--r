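#' Shape-normalize a cell boundary
#'
#' Maps centered boundary points through the inverse principal square root
#' of their second-moment tensor, so that the transformed point set has
#' isotropic second moments (eigenvalue ratio 1). This "compresses cells
#' into regular shapes" and is what makes the PCA polarity score insensitive
#' to cell eccentricity: an elongated cell is whitened back to a circle
#' before intensity anisotropy is measured.
#'
#' @param points n x 2 matrix of (x, y) boundary coordinates.
#' @return n x 2 matrix of whitened displacements from the centroid.
#' @export
shape_normalize <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 3)
  ctr <- colMeans(points)
  U <- sweep(points, 2, ctr)
  M <- crossprod(U) / nrow(U)
  ev <- eigen(M, symmetric = TRUE)
  if (ev$values[2] <= 1e-12 * ev$values[1])
    stop("rank-deficient boundary (collinear points); cannot shape-normalize")
  W <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  U %*% W
}

#' PCA polarity of a single cell
#'
#' Computes the axial polarity of one cell from intensities attached to its
#' boundary points. The boundary is first shape-normalized (see
#' [shape_normalize()]) and the intensities are divided by their own mean
#' (per-cell normalization removes illumination differences between cells).
#' The polarity angle is the direction (mod 180, SOP-normalized) that
#' maximizes the intensity-weighted variance of boundary-point displacement
#' from the centroid, i.e. the principal axis of the weighted second-moment
#' matrix of whitened displacements. The magnitude is the normalized
#' eigenvalue anisotropy `(lambda1 - lambda2)/(lambda1 + lambda2)` of that
#' matrix, a dimensionless score in `[0, 1]`; an isotropic intensity
#' distribution gives magnitude 0 (angle reported as 0 by convention).
#'
#' @param cell A cell record of a [segmented_tissue()], or any list with a
#'   `boundary` n x 2 matrix.
#' @param boundary_intensities Nonnegative intensities, one per boundary
#'   point.
#' @param axis A [reference_axis()].
#' @return List with `cell_id`, `angle` (degrees in `[0, 180)`),
#'   `magnitude`.
#' @export
pca_polarity <- function(cell, boundary_intensities, axis = reference_axis(0)) {
  pts <- cell$boundary
  n <- nrow(pts)
  if (is.null(pts) || n < 8) stop("need at least 8 boundary points")
  w <- as.numeric(boundary_intensities)
  if (length(w) != n) stop("one intensity per boundary point required")
  if (!all(is.finite(w))) stop("non-finite boundary intensities")
  if (all(w == 0)) stop("all boundary intensities are zero")
  w <- w / mean(w)
  U <- shape_normalize(pts)
  M <- crossprod(U * sqrt(w)) / n
  s <- tensor_shape(M, axis)
  list(cell_id = cell$id, angle = s$angle, magnitude = s$magnitude)
}

#' Per-cell polarity over a whole tissue
#'
#' Samples an intensity image at each cell's boundary pixels and scores
#' every cell with [pca_polarity()]. Cells with too few boundary pixels or
#' an all-zero boundary signal are returned with NA scores.
#'
#' @param tissue A [segmented_tissue()].
#' @param intensity_image Matrix, same shape as the label map.
#' @param axis A [reference_axis()].
#' @return Data frame `cell_id, angle_deg, magnitude, interior`.
#' @export
tissue_polarity <- function(tissue, intensity_image, axis = reference_axis(0)) {
  stopifnot(identical(dim(intensity_image), dim(tissue$label_map)))
  ny <- nrow(intensity_image)
  rows <- lapply(tissue$cells, function(cl) {
    b <- cl$boundary
    out <- data.frame(cell_id = cl$id, angle_deg = NA_real_,
                      magnitude = NA_real_, interior = cl$interior)
    if (nrow(b) < 8) return(out)
    ival <- intensity_image[(b[, "x"]) * ny + b[, "y"] + 1L]
    if (all(ival == 0) || !all(is.finite(ival))) return(out)
    p <- pca_polarity(cl, ival, axis)
    out$angle_deg <- p$angle
    out$magnitude <- p$magnitude
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coarse-grain cell polarities into a nematic block field
#'
#' Cells are binned into square spatial tiles whose side is
#' `block_cells` times the median cell diameter (approximating averages
#' over `block_cells x block_cells` groups of cells in an irregular
#' tissue), and each tile's polarities are averaged as nematic tensors:
#' `Q = mean(m * (cos 2 theta, sin 2 theta))`, `mean_angle = atan2(Qy, Qx)/2`
#' mod 180, `mean_magnitude = |Q|`. Axial data must be averaged this way;
#' naive angle means are wrong for orientations defined modulo 180.
#'
#' @param polarities Data frame from [tissue_polarity()] (NA rows dropped).
#' @param tissue The [segmented_tissue()] the polarities came from.
#' @param block_cells Tile side in cell diameters (default 3).
#' @return Data frame `block_x, block_y, mean_angle, mean_magnitude,
#'   n_cells`.
#' @export
coarse_grain <- function(polarities, tissue, block_cells = 3) {
  pol <- polarities[!is.na(polarities$angle_deg), , drop = FALSE]
  if (nrow(pol) == 0) stop("no cells with defined polarity")
  cells <- tissue$cells[as.character(pol$cell_id)]
  cx <- vapply(cells, function(c) c$centroid[["x"]], 0)
  cy <- vapply(cells, function(c) c$centroid[["y"]], 0)
  diam <- stats::median(vapply(cells, function(c) 2 * sqrt(c$area / pi), 0))
  side <- block_cells * diam
  bx <- floor(cx / side); by <- floor(cy / side)
  keys <- paste(bx, by, sep = ",")
  grp <- split(seq_len(nrow(pol)), keys)
  out <- lapply(grp, function(g) {
    nm <- nematic_mean(pol$angle_deg[g], pol$magnitude[g])
    data.frame(block_x = bx[g[1]], block_y = by[g[1]],
               mean_angle = nm$angle, mean_magnitude = nm$magnitude,
               n_cells = length(g))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$block_y, out$block_x), ]
  rownames(out) <- NULL
  out
}

#' Magnitude-weighted circular histogram (10-degree bins)
#'
#' Bins axial angles into the fixed 18 bins `[0,10), ..., [170,180)`.
#' In `magnitude_sum` mode each angle's bin is incremented by its weight;
#' in `magnitude_mean` mode the bin total is divided by the bin count
#' (empty bins report 0); `count` mode ignores weights.
#'
#' @param angle Angles in `[0, 180)`.
#' @param weight Nonnegative weights (polarity magnitudes), recycled to
#'   length of `angle`.
#' @param mode One of `"magnitude_sum"`, `"magnitude_mean"`, `"count"`.
#' @return An `angular_distribution`: list with `bin_edges` (0..180 by 10),
#'   `bin_weights` (length 18), `n_items`, `mode`.
#' @export
weighted_angle_histogram <- function(angle, weight = 1,
                                     mode = c("magnitude_sum",
                                              "magnitude_mean", "count")) {
  mode <- match.arg(mode)
  if (length(angle) && any(angle < 0 | angle >= 180))
    stop("angles must lie in [0, 180)")
  weight <- rep_len(weight, length(angle))
  stopifnot(all(weight >= 0))
  edges <- seq(0, 180, by = 10)
  bin <- findInterval(angle, edges, rightmost.closed = FALSE)
  w <- numeric(18)
  cnt <- numeric(18)
  for (k in seq_along(angle)) {
    w[bin[k]] <- w[bin[k]] + weight[k]
    cnt[bin[k]] <- cnt[bin[k]] + 1
  }
  if (mode == "count") w <- cnt
  if (mode == "magnitude_mean") w <- ifelse(cnt > 0, w / cnt, 0)
  structure(list(bin_edges = edges, bin_weights = w,
                 n_items = length(angle), mode = mode),
            class = "angular_distribution")
}

#' @export
print.angular_distribution <- function(x, ...) {
  cat(sprintf("Angular distribution (%s), %d items\n", x$mode, x$n_items))
  tb <- data.frame(bin = sprintf("[%d,%d)", x$bin_edges[-19], x$bin_edges[-1]),
                   weight = round(x$bin_weights, 4))
  print(tb, row.names = FALSE)
  invisible(x)
}
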