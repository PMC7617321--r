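#' Segmented tissue: label map plus derived per-cell geometry
#'
#' A `segmented_tissue` wraps one frame of a segmented epithelium: an integer
#' label map (0 = background, k >= 1 = cell k) together with per-cell
#' geometry derived from it (centroid, area, ordered boundary pixels, second
#' moment tensor). The label map is stored as an integer matrix indexed
#' `[y + 1, x + 1]`; pixel coordinates are 0-based with x rightward and y
#' downward.
#'
#' @param label_map Integer matrix of cell labels (0 = background).
#' @param pixel_size Pixel edge length in micrometers (> 0).
#' @param frame_index Integer frame number (0-based).
#' @return A `segmented_tissue` with elements `label_map`, `pixel_size`,
#'   `frame_index` and `cells` (a named list of cell records, see
#'   [tissue_cell()]).
#' @export
segmented_tissue <- function(label_map, pixel_size = 0.21, frame_index = 0L) {
  stopifnot(is.matrix(label_map), pixel_size > 0)
  storage.mode(label_map) <- "integer"
  if (any(label_map < 0)) stop("label map must be nonnegative")
  cells <- extract_cells(label_map)
  structure(list(label_map = label_map,
                 pixel_size = as.numeric(pixel_size),
                 frame_index = as.integer(frame_index),
                 cells = cells),
            class = "segmented_tissue")
}

#' @export
print.segmented_tissue <- function(x, ...) {
  cat(sprintf("Segmented tissue: %d cells, %dx%d px (%.3g um/px), frame %d\n",
              length(x$cells), ncol(x$label_map), nrow(x$label_map),
              x$pixel_size, x$frame_index))
  invisible(x)
}

#' Per-cell geometry record
#'
#' Describes the record stored for each cell of a [segmented_tissue()]:
#' `id`, `centroid` (x, y in pixels), `area` (pixels^2), `boundary` (n x 2
#' matrix of boundary pixel coordinates ordered by angle around the
#' centroid), `moment` (2 x 2 centered second-moment tensor of the cell's
#' pixels) and `interior` (TRUE if no boundary pixel touches background or
#' the image edge).
#'
#' @name tissue_cell
NULL

## Derive all cell records from a label map in one vectorized pass.
extract_cells <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  idx <- which(lab > 0L)
  if (length(idx) == 0L) stop("label map is empty (no cells)")
  row <- ((idx - 1L) %% ny) + 1L
  col <- ((idx - 1L) %/% ny) + 1L
  lb <- lab[idx]

  ## 4-neighbor labels with -1 sentinel outside the image
  nb <- function(dr, dc) {
    r <- row + dr; c <- col + dc
    ok <- r >= 1L & r <= ny & c >= 1L & c <= nx
    v <- rep.int(-1L, length(idx))
    v[ok] <- lab[cbind(r[ok], c[ok])]
    v
  }
  nU <- nb(-1L, 0L); nD <- nb(1L, 0L); nL <- nb(0L, -1L); nR <- nb(0L, 1L)
  is_bnd <- nU != lb | nD != lb | nL != lb | nR != lb
  touches_out <- (nU <= 0L) | (nD <= 0L) | (nL <= 0L) | (nR <= 0L)

  x <- col - 1L; y <- row - 1L
  ord <- order(lb)
  groups <- split(seq_along(idx)[ord], lb[ord])

  cells <- lapply(groups, function(g) {
    cx <- mean(x[g]); cy <- mean(y[g])
    dx <- x[g] - cx; dy <- y[g] - cy
    mom <- matrix(c(mean(dx * dx), mean(dx * dy),
                    mean(dx * dy), mean(dy * dy)), 2, 2)
    b <- g[is_bnd[g]]
    ## order boundary pixels by angle around the centroid (cells from
    ## segmentation are near-convex; angular order closes the loop)
    bo <- b[order(atan2(y[b] - cy, x[b] - cx))]
    list(id = lb[g[1L]],
         centroid = c(x = cx, y = cy),
         area = length(g),
         boundary = cbind(x = x[bo], y = y[bo]),
         moment = mom,
         interior = !any(touches_out[g]))
  })
  names(cells) <- vapply(cells, function(c) as.character(c$id), "")
  cells
}

#' Cell elongation axis and magnitude
#'
#' Principal axis of the cell's pixel second-moment tensor, SOP-normalized,
#' with magnitude the normalized eigenvalue anisotropy
#' `(lambda1 - lambda2) / (lambda1 + lambda2)` in `[0, 1]`. An isotropic cell
#' reports angle 0 with magnitude 0 by convention.
#'
#' @param cell A cell record from a [segmented_tissue()].
#' @param axis A [reference_axis()].
#' @return List with `angle` (degrees in `[0, 180)`) and `magnitude`.
#' @export
cell_shape <- function(cell, axis = reference_axis(0)) {
  if (is.null(cell$area) || cell$area <= 0) stop("degenerate cell: area <= 0")
  tensor_shape(cell$moment, axis)
}

## Shared eigen-decomposition for 2x2 symmetric shape/polarity tensors.
tensor_shape <- function(M, axis) {
  ev <- eigen(M, symmetric = TRUE)
  l1 <- ev$values[1]; l2 <- ev$values[2]
  tot <- l1 + l2
  if (tot <= .Machine$double.eps) stop("degenerate tensor: zero total moment")
  mag <- (l1 - l2) / tot
  if (mag < 1e-12) return(list(angle = 0, magnitude = 0))
  v <- ev$vectors[, 1]
  raw <- axial_angle(v[1], v[2])
  ## tensor was built in image coords (y down): axial_angle already flips y,
  ## but the moment tensor's eigenvector is sign-free so mod 180 is enough
  list(angle = normalize_angle(raw, axis), magnitude = mag)
}

#' Read / write label-map TIFF files
#'
#' Label maps travel as single-channel 16-bit TIFFs, one file per frame,
#' background 0.
#'
#' @param path File path.
#' @return `read_label_tiff` returns an integer matrix.
#' @export
read_label_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  storage.mode(img) <- "integer"
  img
}

#' @param label_map Integer matrix of labels (max 65535).
#' @rdname read_label_tiff
#' @export
write_label_tiff <- function(label_map, path) {
  stopifnot(max(label_map) < 65536L)
  tiff::writeTIFF(label_map / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Tracking table
#'
#' Long-format lineage table with columns `frame`, `cell_id`, `lineage_id`,
#' `parent_lineage_id` (NA for founder lineages). Cell ids are unique within
#' a frame; a division replaces a mother lineage by exactly two daughter
#' lineages carrying its id as parent. The table is the single source of
#' lineage truth; label maps are per-frame only.
#'
#' @param df Data frame with the four columns above.
#' @return Validated data frame of class `tracking_table`.
#' @export
tracking_table <- function(df) {
  need <- c("frame", "cell_id", "lineage_id", "parent_lineage_id")
  stopifnot(all(need %in% names(df)))
  df <- df[need]
  if (anyDuplicated(df[c("frame", "cell_id")]))
    stop("cell_id must be unique within a frame")
  ch <- unique(df[!is.na(df$parent_lineage_id),
                  c("parent_lineage_id", "lineage_id")])
  nk <- table(ch$parent_lineage_id)
  if (any(nk > 2)) stop("a lineage has more than 2 children")
  class(df) <- c("tracking_table", "data.frame")
  df
}

#' @param path CSV path.
#' @rdname tracking_table
#' @export
read_tracking_csv <- function(path) {
  tracking_table(utils::read.csv(path))
}

#' @rdname tracking_table
#' @export
write_tracking_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}
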