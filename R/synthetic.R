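#' Synthetic data generators
#'
#' Every input the pipeline consumes can be generated with known ground
#' truth: Voronoi epithelia with controllable cell elongation, junction
#' intensity fields with a tunable planar-polarity enrichment, event-bearing
#' time-lapses (scripted divisions and T1 exchanges), FRAP traces on the
#' standard acquisition schedule, and post-ablation ellipse recoils. All
#' generators are pure functions of their parameters and a seed; sub-streams
#' are derived from the master seed with stable per-generator keys so adding
#' a generator never perturbs existing fixtures.
#'
#' @name synthetic-data
NULL

## Stable sub-seed derivation (31-bit, well below .Machine$integer.max).
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((as.numeric(seed) * 48271 + key * 1009) %% 2147483629)
}

seed_keys <- c(tissue = 1L, polarity = 2L, timelapse = 3L, frap = 4L,
               recoil = 5L)

#' Generate a synthetic segmented epithelium
#'
#' Seeded Voronoi tessellation on the pixel grid with two Lloyd relaxation
#' iterations, giving a near-regular epithelium like a segmented pupal wing
#' field. An optional global anisotropic stretch elongates all cells along
#' a chosen axis (ratio `stretch`:1).
#'
#' @param n_cells Number of cells (>= 4).
#' @param mean_cell_diameter_um Target mean cell diameter in micrometers.
#' @param pixel_size Micrometers per pixel.
#' @param elongation_axis Axis of cell elongation, degrees in `[0, 180)`.
#' @param stretch Elongation ratio (1 = isotropic).
#' @param seed Integer seed.
#' @return A [segmented_tissue()].
#' @export
make_tissue <- function(n_cells = 1000, mean_cell_diameter_um = 3,
                        pixel_size = 0.21, elongation_axis = 0, stretch = 1,
                        seed = 1) {
  stopifnot(n_cells >= 4, stretch >= 1)
  set.seed(derive_seed(seed, seed_keys[["tissue"]]))
  diam <- mean_cell_diameter_um / pixel_size
  side <- ceiling(sqrt(n_cells))
  W <- H <- as.integer(round(side * diam))
  sx <- stats::runif(n_cells, 0, W)
  sy <- stats::runif(n_cells, 0, H)

  ## metric transform: compress along the elongation axis so Voronoi cells
  ## in real space are stretched `stretch`:1 along it
  u <- axial_unit(elongation_axis)[1, ]
  Tm <- diag(2)
  if (stretch > 1) {
    R <- cbind(c(u[1], u[2]), c(-u[2], u[1]))  # columns: along-axis, normal
    Tm <- R %*% diag(c(1 / stretch, 1)) %*% t(R)
  }
  gx <- rep(seq_len(W) - 1, each = H)
  gy <- rep(seq_len(H) - 1, times = W)
  ## pixel matrix is [y+1, x+1]; build transformed pixel coordinates once
  Pt <- cbind(gx, gy) %*% t(Tm)

  assign_px <- function(sx, sy) {
    St <- cbind(sx, sy) %*% t(Tm)
    as.integer(class::knn1(St, Pt, factor(seq_along(sx))))
  }
  lab <- assign_px(sx, sy)
  for (it in 1:2) {  # Lloyd relaxation
    sx <- tapply(gx, lab, mean)[as.character(seq_len(n_cells))]
    sy <- tapply(gy, lab, mean)[as.character(seq_len(n_cells))]
    keep <- !is.na(sx)
    sx[!keep] <- stats::runif(sum(!keep), 0, W)
    sy[!keep] <- stats::runif(sum(!keep), 0, H)
    lab <- assign_px(sx, sy)
  }
  m <- matrix(0L, nrow = H, ncol = W)
  m[cbind(gy + 1L, gx + 1L)] <- lab
  segmented_tissue(m, pixel_size = pixel_size, frame_index = 0L)
}

#' Paint a planar-polarized junction intensity field
#'
#' Assigns each internal junction the intensity
#' `base * (1 + contrast * cos 2(theta_j - enrichment_axis))` plus optional
#' Gaussian noise, and paints it into an image over the junction's boundary
#' band. With `enrichment_axis = 0` the signal is enriched on PD-oriented
#' junctions, which sit on cells' anterior/posterior sides, so the per-cell
#' PCA polarity readout concentrates at 90 degrees (AP) - the geometry of a
#' distally-enriched atypical cadherin.
#'
#' @param tissue A [segmented_tissue()].
#' @param graph Its junction graph built with bands
#'   (`build_junction_graph(tissue, compute_bands = TRUE)`).
#' @param enrichment_axis Junction orientation of maximal intensity
#'   (degrees, SOP frame).
#' @param contrast Modulation depth `c` in `[0, 1)`.
#' @param base Mean junction intensity (arbitrary units).
#' @param noise_sd Additive Gaussian noise on painted pixels.
#' @param seed Integer seed.
#' @return List `image` (matrix), `junction_intensity` (data frame
#'   `junction_id, orientation_deg, intensity`).
#' @export
paint_polarity <- function(tissue, graph, enrichment_axis = 0,
                           contrast = 0.5, base = 100, noise_sd = 0,
                           seed = 1) {
  stopifnot(contrast >= 0, contrast < 1, base > 0)
  set.seed(derive_seed(seed, seed_keys[["polarity"]]))
  img <- matrix(0, nrow = nrow(tissue$label_map), ncol = ncol(tissue$label_map))
  jx <- graph$junctions
  ival <- base * (1 + contrast *
                    cos(2 * (jx$orientation_deg - enrichment_axis) * pi / 180))
  for (k in seq_len(nrow(jx))) {
    b <- graph$band[[k]]
    if (!length(b)) next
    img[b] <- ival[k] + if (noise_sd > 0) stats::rnorm(length(b), 0, noise_sd)
      else 0
  }
  list(image = img,
       junction_intensity = data.frame(junction_id = jx$junction_id,
                                       orientation_deg = jx$orientation_deg,
                                       intensity = ival))
}

## --- time-lapse with scripted topological events ------------------------

## OLS slope helper for t = 1..6 velocity calibration
ols_slope <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

## Split the pixels of cell `id` along a line through its centroid with the
## interface at axial angle `theta_nj`; returns list(idx1, idx2) of linear
## pixel indices or NULL if a side would be too small.
split_cell_pixels <- function(lab, id, theta_nj, min_side = 12L) {
  ny <- nrow(lab)
  idx <- which(lab == id)
  x <- (idx - 1L) %/% ny; y <- (idx - 1L) %% ny
  cx <- mean(x); cy <- mean(y)
  u <- axial_unit(theta_nj)[1, ]           # along new junction
  nvec <- c(-u[2], u[1])                   # normal
  s <- (x - cx) * nvec[1] + (y - cy) * nvec[2]
  side1 <- s >= 0
  if (sum(side1) < min_side || sum(!side1) < min_side) return(NULL)
  list(idx1 = idx[side1], idx2 = idx[!side1])
}

## Local pair-adjacency classification in a window: for each touching pair,
## TRUE if chord length >= cutoff_px. Used to validate T1 surgery.
window_pairs <- function(lab, rows, cols, cutoff_px) {
  sub <- lab[rows, cols, drop = FALSE]
  ny <- nrow(sub); nx <- ncol(sub)
  v1 <- sub[-ny, , drop = FALSE]; v2 <- sub[-1, , drop = FALSE]
  h1 <- sub[, -nx, drop = FALSE]; h2 <- sub[, -1, drop = FALSE]
  iv <- which(v1 != v2 & v1 > 0L & v2 > 0L)
  ih <- which(h1 != h2 & h1 > 0L & h2 > 0L)
  rv <- ((iv - 1L) %% (ny - 1L)) + 1L; cv <- ((iv - 1L) %/% (ny - 1L)) + 1L
  rh <- ((ih - 1L) %% ny) + 1L;        ch <- ((ih - 1L) %/% ny) + 1L
  a <- c(pmin(v1[iv], v2[iv]), pmin(h1[ih], h2[ih]))
  b <- c(pmax(v1[iv], v2[iv]), pmax(h1[ih], h2[ih]))
  px <- c(cv - 1, ch - 0.5); py <- c(rv - 0.5, rh - 1)
  key <- paste(a, b, sep = "-")
  out <- vapply(split(seq_along(key), key), function(g) {
    if (length(g) == 1) return(0)
    D <- stats::dist(cbind(px[g], py[g]))
    max(D)
  }, 0)
  out >= cutoff_px
}

#' Generate a time-lapse with scripted divisions and T1 transitions
#'
#' Starting from a static tissue, divisions (a mother cell is split along a
#' line through its centroid, the daughter interface drawn at an axial
#' von Mises angle) and T1 exchanges (the pixels around a junction are
#' reassigned to the diagonal cell pair so the old neighbors lose contact
#' and the diagonal pair gains a junction at the scripted angle) are applied
#' to the label map frame by frame, with a tracking table and a ground-truth
#' event list recorded. Each T1 surgery is validated on the local adjacency
#' pattern (only the intended pair is lost and only the diagonal pair
#' gained, at the bond cutoff); candidates failing validation are reverted
#' and another junction is tried. Cell ids are never reused, and every cell
#' participates in at most one event.
#'
#' @param tissue A [segmented_tissue()] for frame 0.
#' @param n_divisions,n_t1s Event counts.
#' @param mu,kappa Axial von Mises parameters for division axes and new T1
#'   junction angles (degrees / concentration).
#' @param n_frames Number of frames (>= 2); events are spread over frames
#'   `1..n_frames - 1`.
#' @param bond_cutoff Bond cutoff in pixels used for T1 feasibility.
#' @param seed Integer seed.
#' @return List `frames` (label matrices per frame), `tracking`
#'   ([tracking_table()]), `truth` (list `divisions`, `t1s` data frames),
#'   `pixel_size`.
#' @export
make_timelapse <- function(tissue, n_divisions = 10, n_t1s = 10,
                           mu = 90, kappa = 4, n_frames = 6,
                           bond_cutoff = 4, seed = 1) {
  set.seed(derive_seed(seed, seed_keys[["timelapse"]]))
  lab <- tissue$label_map
  ny <- nrow(lab)
  px_size <- tissue$pixel_size
  n0 <- max(lab)
  next_id <- n0 + 1L
  parent <- list()
  used <- integer(0)

  ## event schedule over frames 1..n_frames-1
  ev_frames <- rep(seq_len(n_frames - 1),
                   length.out = n_divisions + n_t1s)
  ev_type <- sample(c(rep("div", n_divisions), rep("t1", n_t1s)))
  div_truth <- list(); t1_truth <- list()
  frames <- list(`0` = lab)
  track_rows <- list(data.frame(frame = 0L, cell_id = sort(unique(lab[lab > 0]))))

  interior_ids <- vapply(tissue$cells, function(c) c$interior, TRUE)
  interior_ids <- as.integer(names(interior_ids)[interior_ids])

  for (f in seq_len(n_frames - 1)) {
    todo <- ev_type[ev_frames == f]
    ## divisions first, then T1s, so the per-frame junction graph used for
    ## T1 candidate selection is built once
    for (ev in todo[todo == "div"]) {
      done <- FALSE
      theta_div <- rvonmises_axial(1, mu, kappa)
      theta_nj <- (theta_div + 90) %% 180
      cand <- setdiff(interior_ids, used)
      cand <- cand[cand <= n0]  # only original, never-divided cells
      for (id in sample(cand)) {
        sp <- split_cell_pixels(lab, id, theta_nj)
        if (is.null(sp)) next
        d1 <- next_id; d2 <- next_id + 1L
        lab[sp$idx1] <- d1; lab[sp$idx2] <- d2
        next_id <- next_id + 2L
        parent[[as.character(d1)]] <- id
        parent[[as.character(d2)]] <- id
        used <- c(used, id, d1, d2)
        div_truth[[length(div_truth) + 1]] <- data.frame(
          frame = f, mother = id, daughter_a = d1, daughter_b = d2,
          division_angle = theta_div, new_junction_angle = theta_nj)
        done <- TRUE
        break
      }
      if (!done) stop("infeasible event placement: no cell divisible")
    }
    n_t1_here <- sum(todo == "t1")
    if (n_t1_here > 0) {
      g <- build_junction_graph(
        segmented_tissue(lab, pixel_size = px_size), compute_bands = FALSE)
      cents <- centroids_of(lab)
      for (i in seq_len(n_t1_here)) {
        theta_new <- rvonmises_axial(1, mu, kappa)
        if (!plant_t1(environment(), theta_new, f, g, cents))
          stop("infeasible event placement: no T1 candidate junction")
      }
    }
    frames[[as.character(f)]] <- lab
    track_rows[[length(track_rows) + 1]] <-
      data.frame(frame = f, cell_id = sort(unique(lab[lab > 0])))
  }

  tr <- do.call(rbind, track_rows)
  tr$lineage_id <- tr$cell_id
  tr$parent_lineage_id <- vapply(as.character(tr$cell_id), function(k) {
    p <- parent[[k]]
    if (is.null(p)) NA_integer_ else as.integer(p)
  }, 0L)
  list(frames = frames, tracking = tracking_table(tr),
       truth = list(divisions = if (length(div_truth))
         do.call(rbind, div_truth) else NULL,
         t1s = if (length(t1_truth)) do.call(rbind, t1_truth) else NULL),
       pixel_size = px_size)
}

## T1 surgery on the generator state (mutates lab/used/t1_truth in `env`).
## `g`/`cents` are the frame's junction graph and centroid table, computed
## once per frame; junctions touching already-used cells are skipped, and
## every candidate is validated against the current label map, so reuse
## within a frame is safe. Returns TRUE on success.
plant_t1 <- function(env, theta_new, f, g, cents) {
  lab <- env$lab
  ny <- nrow(lab); nx <- ncol(lab)
  cutoff_px <- env$bond_cutoff
  jx <- g$junctions
  len_px <- jx$length_um / env$px_size
  ok <- len_px >= cutoff_px & len_px <= 2.5 * cutoff_px &
    !(jx$cell_a %in% env$used) & !(jx$cell_b %in% env$used)
  cand <- which(ok)
  if (!length(cand)) return(FALSE)
  ## neighbor sets
  nb <- split(c(jx$cell_b, jx$cell_a), c(jx$cell_a, jx$cell_b))
  adj_key <- paste(jx$cell_a, jx$cell_b, sep = "-")

  for (k in sample(cand)) {
    a <- jx$cell_a[k]; b <- jx$cell_b[k]
    common <- intersect(nb[[as.character(a)]], nb[[as.character(b)]])
    common <- setdiff(common, c(a, b, env$used))
    if (length(common) != 2) next
    c1 <- common[1]; c2 <- common[2]
    if (paste(min(c1, c2), max(c1, c2), sep = "-") %in% adj_key) next

    ## band: pixels of a/b near the a-b interface
    P <- g$interface[[k]]
    m <- colMeans(P)
    r <- max(4, max(stats::dist(P)) / 2 + 2)
    rr <- max(1, floor(m[2] - r - 1) + 1):min(ny, ceiling(m[2] + r + 1) + 1)
    cc <- max(1, floor(m[1] - r - 1) + 1):min(nx, ceiling(m[1] + r + 1) + 1)
    sub <- lab[rr, cc, drop = FALSE]
    sel <- which(sub == a | sub == b)
    sy <- rr[((sel - 1L) %% length(rr)) + 1L] - 1
    sx <- cc[((sel - 1L) %/% length(rr)) + 1L] - 1
    dmin2 <- rep(Inf, length(sel))
    for (q in seq_len(nrow(P)))
      dmin2 <- pmin(dmin2, (sx - P[q, 1])^2 + (sy - P[q, 2])^2)
    band <- sel[dmin2 <= r^2]
    if (!length(band)) next

    u <- axial_unit(theta_new)[1, ]
    nvec <- c(-u[2], u[1])
    side <- ((sx - m[1]) * nvec[1] + (sy - m[2]) * nvec[2])[dmin2 <= r^2]
    s1 <- sign((cents[as.character(c1), 1] - m[1]) * nvec[1] +
                 (cents[as.character(c1), 2] - m[2]) * nvec[2])
    s2 <- sign((cents[as.character(c2), 1] - m[1]) * nvec[1] +
                 (cents[as.character(c2), 2] - m[2]) * nvec[2])
    if (s1 == s2 || s1 == 0 || s2 == 0) next

    old <- sub[band]
    sub[band] <- ifelse(side * s1 >= 0, c1, c2)
    lab2 <- lab
    lab2[rr, cc] <- sub

    ## validate: in a window around the site, the only long-bond changes are
    ## a-b lost and c1-c2 gained
    wr <- max(1, min(rr) - 12):min(ny, max(rr) + 12)
    wc <- max(1, min(cc) - 12):min(nx, max(cc) + 12)
    before <- window_pairs(lab, wr, wc, cutoff_px)
    after <- window_pairs(lab2, wr, wc, cutoff_px)
    keys <- union(names(before), names(after))
    b0 <- stats::setNames(rep(FALSE, length(keys)), keys)
    b1 <- b0
    b0[names(before)] <- before; b1[names(after)] <- after
    changed <- keys[b0 != b1]
    want_lost <- paste(min(a, b), max(a, b), sep = "-")
    want_gain <- paste(min(c1, c2), max(c1, c2), sep = "-")
    if (!setequal(changed, c(want_lost, want_gain))) next
    if (!b1[want_gain] || b0[want_lost] != TRUE) next
    ## also require full loss of a-b contact
    if (want_lost %in% names(after)) next

    env$lab <- lab2
    env$used <- c(env$used, a, b, c1, c2)
    env$t1_truth[[length(env$t1_truth) + 1]] <- data.frame(
      frame = f, lose_a = a, lose_b = b, gain_a = c1, gain_b = c2,
      new_junction_angle = theta_new)
    return(TRUE)
  }
  FALSE
}

centroids_of <- function(lab) {
  ny <- nrow(lab)
  idx <- which(lab > 0)
  x <- (idx - 1L) %/% ny; y <- (idx - 1L) %% ny
  cx <- tapply(x, lab[idx], mean)
  cy <- tapply(y, lab[idx], mean)
  cbind(cx, cy)
}

#' Generate FRAP traces with known recovery parameters
#'
#' Simulates the two-channel FRAP readout on the standard acquisition
#' schedule: the underlying bleached-junction signal recovers as
#' `pre * ((1 - d) + d * y_max * (1 - exp(-alpha t)))` with bleach depth
#' `d`, while every acquired post-bleach image multiplies both channels by
#' a geometric per-frame photobleaching factor calibrated so the end-to-end
#' acquisition bleaching equals `acq_bleach_pct`. Observed intensities add
#' the scalar background and optional Gaussian noise. Running the analysis
#' chain on noiseless output returns `y_max` and `alpha` exactly.
#'
#' @param n_pupae Number of pupae per class.
#' @param y_max,alpha Named per-orientation-class truth, e.g.
#'   `c(PD = 0.6, AP = 0.8)` (a scalar is recycled to both classes).
#' @param init_bleach_pct Target initial bleaching percentage.
#' @param acq_bleach_pct Target acquisition bleaching percentage (< 100).
#' @param noise_sd Gaussian noise, in units of the pre-bleach signal.
#' @param n_rois ROIs per class per pupa (4 in the standard design).
#' @param pre_signal,background Pre-bleach signal amplitude and background.
#' @param seed Integer seed.
#' @return Long-format data frame `pupa_id, roi_id, orientation,
#'   timepoint_s, intensity, control_intensity, background`.
#' @export
make_frap <- function(n_pupae = 10, y_max = c(PD = 0.6, AP = 0.8),
                      alpha = 0.02, init_bleach_pct = 60,
                      acq_bleach_pct = 15, noise_sd = 0, n_rois = 4,
                      pre_signal = 100, background = 10, seed = 1) {
  if (acq_bleach_pct >= 100) stop("requested acquisition bleaching >= 100%")
  set.seed(derive_seed(seed, seed_keys[["frap"]]))
  classes <- if (!is.null(names(y_max))) names(y_max) else c("PD", "AP")
  y_max <- rep_len(unname(y_max), length(classes))
  alpha <- rep_len(unname(alpha), length(classes))
  sch <- frap_schedule()
  n_post <- length(sch$post)
  rho <- (1 - acq_bleach_pct / 100)^(1 / (n_post - 1))
  b_n <- rho^(seq_len(n_post) - 1)
  pre_obs <- pre_signal + background
  ## bleach depth giving the requested initial bleaching through the
  ## background-free ratio formula applied to observed intensities
  d <- 1 - ((pre_obs) * (1 - init_bleach_pct / 100) - background) / pre_signal
  if (d <= 0 || d > 1) stop("initial bleaching target infeasible")

  rows <- list()
  for (p in seq_len(n_pupae)) {
    for (ci in seq_along(classes)) {
      R <- pre_signal * ((1 - d) + d * y_max[ci] *
                           (1 - exp(-alpha[ci] * sch$post)))
      for (roi in seq_len(n_rois)) {
        nz <- function(n) if (noise_sd > 0)
          stats::rnorm(n, 0, noise_sd * pre_signal) else numeric(n)
        I_pre <- pre_signal + background + nz(3)
        U_pre <- pre_signal + background + nz(3)
        I_post <- b_n * R + background + nz(n_post)
        U_post <- b_n * pre_signal + background + nz(n_post)
        rows[[length(rows) + 1]] <- data.frame(
          pupa_id = p, roi_id = sprintf("p%d_%s_r%d", p, classes[ci], roi),
          orientation = classes[ci],
          timepoint_s = c(sch$pre, sch$post),
          intensity = c(I_pre, I_post),
          control_intensity = c(U_pre, U_post),
          background = background)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a post-ablation recoil vertex series
#'
#' Ellipse axis lengths follow `L(t) = Linf - (Linf - L0) exp(-t / tau)`
#' per axis, with the total opening calibrated so the ordinary
#' least-squares slope over frames t = 1..6 equals the requested initial
#' recoil velocity exactly. Vertices are sampled on the ellipse outline at
#' 1 frame per second, the major axis along `major_angle`, plus optional
#' Gaussian positional noise.
#'
#' @param n_pupae Number of pupae.
#' @param v_major,v_minor Target initial recoil velocities (um/s, >= 0).
#' @param tau Relaxation time (s).
#' @param L0 Initial axis length (um), both axes (the ablated hole is a
#'   circle at t = 0).
#' @param major_angle Axis of the major (faster) direction, degrees.
#' @param n_vertices Tracked vertices per frame.
#' @param noise_sd Gaussian positional noise (um).
#' @param t_max Last frame (s).
#' @param seed Integer seed.
#' @return Long-format data frame `pupa_id, frame, t_s, vertex_id, x_um,
#'   y_um`.
#' @export
make_recoil <- function(n_pupae = 7, v_major = 0.2, v_minor = 0.2,
                        tau = 20, L0 = 24.3, major_angle = 0,
                        n_vertices = 12, noise_sd = 0, t_max = 180,
                        seed = 1) {
  stopifnot(v_major >= 0, v_minor >= 0, tau > 0)
  set.seed(derive_seed(seed, seed_keys[["recoil"]]))
  tt <- 0:t_max
  decay <- exp(-(1:6) / tau)
  c0 <- -ols_slope(1:6, decay)         # slope of -exp(-t/tau) over frames 1-6
  d_major <- v_major / c0
  d_minor <- v_minor / c0
  u <- axial_unit(major_angle)[1, ]
  vperp <- c(-u[2], u[1])
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  rows <- list()
  for (p in seq_len(n_pupae)) {
    Lmaj <- (L0 + d_major) - d_major * exp(-tt / tau)
    Lmin <- (L0 + d_minor) - d_minor * exp(-tt / tau)
    for (i in seq_along(tt)) {
      xy <- outer(cos(phi), u) * Lmaj[i] / 2 +
        outer(sin(phi), vperp) * Lmin[i] / 2
      if (noise_sd > 0)
        xy <- xy + matrix(stats::rnorm(length(xy), 0, noise_sd), ncol = 2)
      rows[[length(rows) + 1]] <- data.frame(
        pupa_id = p, frame = tt[i], t_s = tt[i],
        vertex_id = seq_len(n_vertices),
        x_um = xy[, 1], y_um = xy[, 2])
    }
  }
  do.call(rbind, rows)
}
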