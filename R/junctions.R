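#' Build the junction graph of a segmented tissue
#'
#' Enumerates every internal cell-cell junction (adjacent pair of nonzero
#' labels sharing at least one 4-connected pixel face) and measures, per
#' junction: chord length, SOP-normalized chord orientation, and mean
#' intensity per channel inside a band along the shared boundary.
#'
#' The junction chord runs between the two most distant interface points;
#' its angle is the junction orientation (end-to-end, not per-pixel
#' tangents). Intensity is averaged over pixels of the two partner cells
#' within a band of width `band_width` pixels centered on the interface,
#' excluding pixels that also belong to a band of a junction with any third
#' cell (vertex pixels).
#'
#' @param tissue A [segmented_tissue()].
#' @param intensity_images Named list of intensity matrices (same shape as
#'   the label map), or NULL for a geometry-only graph.
#' @param axis A [reference_axis()].
#' @param band_width Intensity band width in pixels (odd, default 3).
#' @param compute_bands Collect band pixel indices (needed for intensity
#'   measurement or painting); skipped by default for geometry-only graphs.
#' @return A `junction_graph`: list with `junctions` (data frame
#'   `junction_id, cell_a, cell_b, length_um, orientation_deg, n_interface`
#'   plus one `intensity_<channel>` column per channel), `interface`
#'   (list of interface-point matrices), `band` (list of linear pixel
#'   indices), `pixel_size`, `frame_index`.
#' @export
build_junction_graph <- function(tissue, intensity_images = NULL,
                                 axis = reference_axis(0), band_width = 3,
                                 compute_bands = !is.null(intensity_images)) {
  stopifnot(inherits(tissue, "segmented_tissue"), band_width >= 1)
  lab <- tissue$label_map
  ny <- nrow(lab); nx <- ncol(lab)

  ## interface pairs from face-sharing neighbors (vectorized two-pass scan)
  v1 <- lab[-ny, , drop = FALSE]; v2 <- lab[-1, , drop = FALSE]
  h1 <- lab[, -nx, drop = FALSE]; h2 <- lab[, -1, drop = FALSE]
  iv <- which(v1 != v2 & v1 > 0L & v2 > 0L)  # vertical face between (r,c),(r+1,c)
  ih <- which(h1 != h2 & h1 > 0L & h2 > 0L)  # horizontal face

  rv <- ((iv - 1L) %% (ny - 1L)) + 1L; cv <- ((iv - 1L) %/% (ny - 1L)) + 1L
  rh <- ((ih - 1L) %% ny) + 1L;        ch <- ((ih - 1L) %/% ny) + 1L

  la <- c(pmin(v1[iv], v2[iv]), pmin(h1[ih], h2[ih]))
  lbb <- c(pmax(v1[iv], v2[iv]), pmax(h1[ih], h2[ih]))
  ## interface point = midpoint between the two pixel centers (0-based coords)
  px <- c(cv - 1, ch - 1 + 0.5)
  py <- c(rv - 1 + 0.5, rh - 1)
  vert <- c(rep(TRUE, length(iv)), rep(FALSE, length(ih)))
  rr <- c(rv, rh); cc <- c(cv, ch)

  if (length(la) == 0L) {
    jx <- empty_junction_table(intensity_images)
    return(structure(list(junctions = jx, interface = list(), band = list(),
                          pixel_size = tissue$pixel_size,
                          frame_index = tissue$frame_index),
                     class = "junction_graph"))
  }

  key <- paste(la, lbb, sep = "-")
  ord <- order(key)
  grp <- split(seq_along(key)[ord], key[ord])

  half <- (band_width - 1) / 2
  res <- vector("list", length(grp))
  bands <- vector("list", length(grp))
  pts <- vector("list", length(grp))
  for (k in seq_along(grp)) {
    g <- grp[[k]]
    a <- la[g[1]]; b <- lbb[g[1]]
    P <- cbind(x = px[g], y = py[g])
    ## chord endpoints: the two most distant interface points
    if (nrow(P) == 1L) {
      e1 <- e2 <- 1L
    } else {
      D <- as.matrix(stats::dist(P))
      w <- which(D == max(D), arr.ind = TRUE)[1, ]
      e1 <- w[1]; e2 <- w[2]
    }
    dx <- P[e2, 1] - P[e1, 1]; dy <- P[e2, 2] - P[e1, 2]
    len <- sqrt(dx^2 + dy^2) * tissue$pixel_size
    ori <- if (len == 0) 0 else normalize_angle(axial_angle(dx, dy), axis)

    ## band pixels: cells a/b pixels within the band box of each interface pair
    bi <- integer(0)
    if (compute_bands) {
      brow <- integer(0); bcol <- integer(0)
      for (i in seq_along(g)) {
        gi <- g[i]
        if (vert[gi]) { r0 <- rr[gi]:(rr[gi] + 1L); c0 <- (cc[gi] - half):(cc[gi] + half)
        } else        { r0 <- (rr[gi] - half):(rr[gi] + half); c0 <- cc[gi]:(cc[gi] + 1L) }
        r0 <- r0[r0 >= 1 & r0 <= ny]; c0 <- c0[c0 >= 1 & c0 <= nx]
        e <- expand.grid(r = r0, c = c0)
        brow <- c(brow, e$r); bcol <- c(bcol, e$c)
      }
      bi <- unique((bcol - 1L) * ny + brow)
      bi <- bi[lab[bi] == a | lab[bi] == b]
    }

    res[[k]] <- data.frame(cell_a = a, cell_b = b, length_um = len,
                           orientation_deg = ori, n_interface = nrow(P))
    bands[[k]] <- bi
    pts[[k]] <- P
  }
  jx <- do.call(rbind, res)
  jx <- cbind(junction_id = seq_len(nrow(jx)), jx)

  ## vertex exclusion: a band pixel used by junctions of a third cell is
  ## dropped from every band
  all_bi <- unlist(bands)
  dup <- unique(all_bi[duplicated(all_bi)])
  if (length(dup)) {
    bands <- lapply(bands, function(b) b[!(b %in% dup)])
  }

  if (!is.null(intensity_images)) {
    if (is.null(names(intensity_images)))
      names(intensity_images) <- paste0("ch", seq_along(intensity_images))
    for (chn in names(intensity_images)) {
      im <- intensity_images[[chn]]
      stopifnot(identical(dim(im), dim(lab)))
      jx[[paste0("intensity_", chn)]] <- vapply(bands, function(b) {
        if (length(b) == 0) NA_real_ else mean(im[b])
      }, 0)
    }
  }

  structure(list(junctions = jx, interface = pts, band = bands,
                 pixel_size = tissue$pixel_size,
                 frame_index = tissue$frame_index),
            class = "junction_graph")
}

empty_junction_table <- function(intensity_images) {
  jx <- data.frame(junction_id = integer(0), cell_a = integer(0),
                   cell_b = integer(0), length_um = numeric(0),
                   orientation_deg = numeric(0), n_interface = integer(0))
  if (!is.null(intensity_images)) {
    nm <- names(intensity_images)
    if (is.null(nm)) nm <- paste0("ch", seq_along(intensity_images))
    for (chn in nm) jx[[paste0("intensity_", chn)]] <- numeric(0)
  }
  jx
}

#' @export
print.junction_graph <- function(x, ...) {
  cat(sprintf("Junction graph: %d internal junctions (frame %d)\n",
              nrow(x$junctions), x$frame_index))
  invisible(x)
}

#' Classify junctions as PD- or AP-oriented
#'
#' @param graph A `junction_graph`.
#' @return The junction table with an added `orientation_class` column
#'   (`"PD"` for chord angles in `[0,45) U [135,180)`, `"AP"` for
#'   `[45,135)`).
#' @export
classify_junctions <- function(graph) {
  jx <- graph$junctions
  jx$orientation_class <- classify_orientation(jx$orientation_deg)
  jx
}

#' Write a junction table CSV
#'
#' Columns: `junction_id, frame, cell_a, cell_b, length_um, orientation_deg`
#' plus intensity channels.
#'
#' @param graph A `junction_graph`.
#' @param path Output CSV path.
#' @export
write_junction_csv <- function(graph, path) {
  jx <- graph$junctions
  jx <- cbind(jx[1], frame = graph$frame_index, jx[-1])
  utils::write.csv(jx, path, row.names = FALSE)
  invisible(path)
}
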