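#' Division angle from the new-junction angle
#'
#' The division axis is perpendicular to the new junction formed between the
#' two daughter cells: 90 degrees is added to the junction angle, modulo 180.
#'
#' @param new_junction_angle Degrees in `[0, 180)`.
#' @return Division angle, degrees in `[0, 180)`.
#' @export
division_angle <- function(new_junction_angle) {
  stopifnot(all(new_junction_angle >= 0 & new_junction_angle < 180))
  (new_junction_angle + 90) %% 180
}

#' Detect oriented cell divisions from tracking
#'
#' A division is a lineage that is replaced, in a single frame, by exactly
#' two child lineages. The new-junction angle is the orientation of the
#' junction between the two daughters in their first shared frame; the
#' division angle adds 90 degrees. Daughters that share no junction in that
#' frame are flagged `no_shared_junction` with NA angles rather than
#' dropped.
#'
#' @param tracking A [tracking_table()].
#' @param graphs Named list of `junction_graph`s, one per frame (names =
#'   frame indices as character).
#' @return Data frame `frame, mother_lineage, daughter_a, daughter_b,
#'   new_junction_angle, division_angle, flag`.
#' @export
detect_divisions <- function(tracking, graphs) {
  tr <- as.data.frame(tracking)
  ch <- tr[!is.na(tr$parent_lineage_id), , drop = FALSE]
  if (nrow(ch) == 0)
    return(data.frame(frame = integer(0), mother_lineage = integer(0),
                      daughter_a = integer(0), daughter_b = integer(0),
                      new_junction_angle = numeric(0),
                      division_angle = numeric(0), flag = character(0)))
  ## first frame each child lineage appears
  first <- stats::aggregate(frame ~ lineage_id + parent_lineage_id, ch, min)
  grp <- split(first, first$parent_lineage_id)
  rows <- lapply(grp, function(d) {
    if (nrow(d) != 2 || d$frame[1] != d$frame[2]) return(NULL)
    f <- d$frame[1]
    ids <- vapply(d$lineage_id, function(l) {
      tr$cell_id[tr$frame == f & tr$lineage_id == l][1]
    }, 0)
    jx <- graphs[[as.character(f)]]$junctions
    hit <- jx[(jx$cell_a == min(ids) & jx$cell_b == max(ids)), , drop = FALSE]
    if (nrow(hit) == 1) {
      nja <- hit$orientation_deg
      data.frame(frame = f, mother_lineage = d$parent_lineage_id[1],
                 daughter_a = ids[1], daughter_b = ids[2],
                 new_junction_angle = nja, division_angle = division_angle(nja),
                 flag = "")
    } else {
      data.frame(frame = f, mother_lineage = d$parent_lineage_id[1],
                 daughter_a = ids[1], daughter_b = ids[2],
                 new_junction_angle = NA_real_, division_angle = NA_real_,
                 flag = "no_shared_junction")
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- detect_divisions(tracking_table(tr[0, ]), graphs)
  rownames(out) <- NULL
  out[order(out$frame, out$mother_lineage), , drop = FALSE]
}

## Adjacency of cell pairs at one frame, thresholded at the bond cutoff:
## junctions shorter than the cutoff count as 4-way vertices (not adjacent).
pair_adjacency <- function(graph, cutoff_um) {
  jx <- graph$junctions
  list(all = paste(jx$cell_a, jx$cell_b, sep = "-"),
       long = paste(jx$cell_a, jx$cell_b, sep = "-")[jx$length_um >= cutoff_um],
       table = jx)
}

#' Detect T1 transitions (neighbor exchanges) from tracked junction graphs
#'
#' Junctions shorter than `bond_cutoff` pixels are contracted to 4-way
#' vertices. A T1 event is emitted at the first frame where a previously
#' adjacent cell pair (junction >= cutoff) has lost contact while the
#' opposite diagonal pair of the quartet (common neighbors of both losing
#' cells) has gained a junction >= cutoff. Events involving a cell that
#' divides within one frame of the exchange are excluded (divisions create
#' spurious local rearrangements); exclusions are returned in the
#' `filtered` attribute, not raised.
#'
#' @param tracking A [tracking_table()].
#' @param graphs Named list of per-frame `junction_graph`s.
#' @param bond_cutoff Junction-length cutoff in pixels (default 4).
#' @return Data frame `frame, cell_a, cell_b, gain_a, gain_b,
#'   new_junction_angle` (losing pair `cell_*`, gaining pair `gain_*`).
#' @export
detect_t1 <- function(tracking, graphs, bond_cutoff = 4) {
  tr <- as.data.frame(tracking)
  frames <- sort(as.integer(names(graphs)))
  ## frames at which each lineage divides (for the +/- 1 frame exclusion)
  ch <- tr[!is.na(tr$parent_lineage_id), , drop = FALSE]
  div_frames <- if (nrow(ch)) {
    fst <- stats::aggregate(frame ~ lineage_id + parent_lineage_id, ch, min)
    fst
  } else NULL
  dividing_cells_near <- function(f) {
    if (is.null(div_frames)) return(integer(0))
    lin <- unique(c(
      div_frames$parent_lineage_id[abs(div_frames$frame - f) <= 1],
      div_frames$lineage_id[abs(div_frames$frame - f) <= 1]))
    tr$cell_id[tr$lineage_id %in% lin & abs(tr$frame - f) <= 1]
  }

  out <- list()
  for (i in seq_along(frames)[-1]) {
    f0 <- frames[i - 1]; f1 <- frames[i]
    g0 <- graphs[[as.character(f0)]]; g1 <- graphs[[as.character(f1)]]
    cutoff_um <- bond_cutoff * g0$pixel_size
    a0 <- pair_adjacency(g0, cutoff_um); a1 <- pair_adjacency(g1, cutoff_um)
    present0 <- unique(c(a0$table$cell_a, a0$table$cell_b))
    present1 <- unique(c(a1$table$cell_a, a1$table$cell_b))
    persist <- intersect(present0, present1)

    lost <- setdiff(a0$long, a1$long)
    gained <- setdiff(a1$long, a0$long)
    if (!length(lost) || !length(gained)) next
    excl <- dividing_cells_near(f1)

    lostm <- do.call(rbind, strsplit(lost, "-"))
    gainm <- do.call(rbind, strsplit(gained, "-"))
    storage.mode(lostm) <- storage.mode(gainm) <- "integer"

    ## neighbor sets at f0 (any-length adjacency)
    nb0 <- split(c(a0$table$cell_b, a0$table$cell_a),
                 c(a0$table$cell_a, a0$table$cell_b))
    for (k in seq_len(nrow(lostm))) {
      a <- lostm[k, 1]; b <- lostm[k, 2]
      if (!(a %in% persist) || !(b %in% persist)) next
      common <- intersect(nb0[[as.character(a)]], nb0[[as.character(b)]])
      for (m in seq_len(nrow(gainm))) {
        c1 <- gainm[m, 1]; c2 <- gainm[m, 2]
        if (!(c1 %in% common) || !(c2 %in% common)) next
        quartet <- c(a, b, c1, c2)
        if (length(unique(quartet)) != 4) next
        if (any(quartet %in% excl)) next
        jx1 <- a1$table
        hit <- jx1[jx1$cell_a == min(c1, c2) & jx1$cell_b == max(c1, c2), ]
        out[[length(out) + 1]] <- data.frame(
          frame = f1, cell_a = a, cell_b = b, gain_a = c1, gain_b = c2,
          new_junction_angle = hit$orientation_deg[1])
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), cell_a = integer(0),
                      cell_b = integer(0), gain_a = integer(0),
                      gain_b = integer(0), new_junction_angle = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize event orientations as AP vs PD
#'
#' Counts angles by the AP band `[45, 135)`, forms the AP:PD ratio and an
#' 18-bin count histogram. With no PD events the ratio is reported NA
#' (undefined), never infinity.
#'
#' @param angles Degrees in `[0, 180)`; NAs are dropped (counted in
#'   `n_undefined`).
#' @return List of class `orientation_summary`: `n_AP, n_PD, ap_pd_ratio,
#'   n_undefined, histogram`.
#' @export
summarize_orientations <- function(angles) {
  n_undef <- sum(is.na(angles))
  a <- angles[!is.na(angles)]
  cls <- classify_orientation(a)
  n_ap <- sum(cls == "AP"); n_pd <- sum(cls == "PD")
  structure(list(
    n_AP = n_ap, n_PD = n_pd,
    ap_pd_ratio = if (n_pd > 0) n_ap / n_pd else NA_real_,
    n_undefined = n_undef,
    histogram = weighted_angle_histogram(a, mode = "count")),
    class = "orientation_summary")
}

#' @export
print.orientation_summary <- function(x, ...) {
  cat(sprintf("Orientation summary: %d AP, %d PD (AP:PD = %s)%s\n",
              x$n_AP, x$n_PD,
              if (is.na(x$ap_pd_ratio)) "undefined" else
                format(x$ap_pd_ratio, digits = 4),
              if (x$n_undefined) sprintf(", %d undefined", x$n_undefined)
              else ""))
  invisible(x)
}
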