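## Shared in-code fixtures and independent oracles.

## A circle-boundary "cell": phi parameterizes position counterclockwise on
## screen, so a point at axial angle theta has phi = theta (package
## convention: y down, angles from +x toward -y).
circle_cell <- function(n = 200, r = 10, cx = 0, cy = 0) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(id = 1L,
       boundary = cbind(x = cx + r * cos(phi), y = cy - r * sin(phi)),
       phi_deg = phi * 180 / pi)
}

## Stretched circle along axial angle `axis_deg` by factor s (area-neutral
## in x only; good enough for eccentricity-robustness checks).
stretched_cell <- function(n = 200, r = 10, s = 2, axis_deg = 0) {
  cc <- circle_cell(n, r)
  u <- cbind(cos(axis_deg * pi / 180), -sin(axis_deg * pi / 180))
  vperp <- cbind(-u[2], u[1])
  b <- cc$boundary
  along <- b[, 1] * u[1] + b[, 2] * u[2]
  across <- b[, 1] * vperp[1] + b[, 2] * vperp[2]
  cc$boundary <- cbind(x = s * along * u[1] + across * vperp[1],
                       y = s * along * u[2] + across * vperp[2])
  cc
}

## Two-cell label map split by a vertical line.
two_cell_map <- function(n = 12) {
  m <- matrix(0L, n, n)
  m[, 1:(n / 2)] <- 1L
  m[, (n / 2 + 1):n] <- 2L
  m
}

## Brute-force pairwise adjacency oracle: every 4-neighbor pixel pair with
## two distinct positive labels.
brute_adjacency <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  pairs <- character(0)
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    a <- lab[r, c]
    if (a <= 0) next
    for (d in list(c(0, 1), c(1, 0))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 > ny || c2 > nx) next
      b <- lab[r2, c2]
      if (b > 0 && b != a)
        pairs <- c(pairs, paste(min(a, b), max(a, b), sep = "-"))
    }
  }
  sort(unique(pairs))
}

## Brute-force two-sample KS D by ECDF enumeration over the pooled support.
brute_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), 0)))
}

## Pixel second-moment oracle: direct sum over interior pixels of a mask.
pixel_moment_oracle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  dx <- x - mean(x); dy <- y - mean(y)
  matrix(c(mean(dx^2), mean(dx * dy), mean(dx * dy), mean(dy^2)), 2, 2)
}

## Grid-search oracle for the intensity-weighted variance maximizer:
## for boundary displacements U (already whitened) with weights w, find the
## direction maximizing sum(w * (U %*% u)^2) over a fine angular grid.
grid_polarity_oracle <- function(U, w, step = 0.1) {
  th <- seq(0, 180 - step, by = step)
  v <- vapply(th, function(a) {
    u <- c(cos(a * pi / 180), -sin(a * pi / 180))
    sum(w * (U %*% u)^2)
  }, 0)
  th[which.max(v)]
}

## Small deterministic timelapse fixture shared by event tests.
small_timelapse <- function(seed = 5) {
  ts <- make_tissue(400, seed = seed)
  tl <- make_timelapse(ts, n_divisions = 6, n_t1s = 5, mu = 90, kappa = 4,
                       n_frames = 4, seed = seed)
  graphs <- lapply(tl$frames, function(m)
    build_junction_graph(segmented_tissue(m, pixel_size = tl$pixel_size)))
  names(graphs) <- names(tl$frames)
  list(tl = tl, graphs = graphs)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

## Smallest mod-180 separation between two axial angles.
axial_diff_test <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
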