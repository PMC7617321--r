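#' Direct least-squares ellipse fit
#'
#' Fits the conic `A x^2 + B xy + C y^2 + D x + E y + F = 0` to scattered
#' points with the ellipse-specific constraint `4AC - B^2 = 1` (direct
#' least-squares conic fitting via a generalized eigenproblem), then
#' converts to center, full axis lengths and axial orientation. Exact point
#' sets on an ellipse are interpolated to numerical precision.
#'
#' @param points n x 2 matrix or data frame of (x, y) coordinates, n >= 5.
#' @param axis A [reference_axis()] used to normalize the orientation.
#' @return List `center` (x, y), `major`, `minor` (full axis lengths, same
#'   units as the input), `orientation_deg` in `[0, 180)` (reported 0 for a
#'   circle by convention).
#' @export
fit_ellipse <- function(points, axis = reference_axis(0)) {
  P <- as.matrix(points)
  stopifnot(ncol(P) == 2)
  if (nrow(P) < 5) stop("need >= 5 points to fit an ellipse")
  x <- P[, 1]; y <- P[, 2]
  ## center and scale for conditioning
  mx <- mean(x); my <- mean(y)
  sc <- mean(sqrt((x - mx)^2 + (y - my)^2))
  if (sc <= 0) stop("degenerate point set")
  xs <- (x - mx) / sc; ys <- (y - my) / sc

  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate (collinear) points"))
  M <- S1 + S2 %*% T1
  ## premultiply by inverse of constraint matrix C = [[0,0,2],[0,-1,0],[2,0,0]]
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  k <- which(cond > 0)
  if (length(k) == 0) stop("no ellipse solution (degenerate points)")
  a1 <- evec[, k[1]]
  coefs <- c(a1, T1 %*% a1)  # A B C D E F in scaled frame

  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  Dc <- coefs[4]; E <- coefs[5]; Ff <- coefs[6]
  M0 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ctr_s <- solve(2 * M0, -c(Dc, E))
  kq <- -(as.numeric(t(ctr_s) %*% M0 %*% ctr_s) + sum(c(Dc, E) * ctr_s) + Ff)
  eg <- eigen(M0, symmetric = TRUE)
  if (any(eg$values * sign(kq) <= 0)) stop("conic is not an ellipse")
  semi <- sqrt(kq / eg$values) * sc
  center <- ctr_s * sc + c(mx, my)
  major <- 2 * max(semi); minor <- 2 * min(semi)
  vmaj <- eg$vectors[, which.max(semi)]  # longest semi-axis direction
  ori <- if ((major - minor) / major < 1e-9) 0 else
    normalize_angle(axial_angle(vmaj[1], vmaj[2]), axis)
  list(center = c(x = center[1], y = center[2]),
       major = major, minor = minor, orientation_deg = ori)
}

#' Ellipse time series from tracked ablation-edge vertices
#'
#' Fits an ellipse to the tracked vertex cloud at each frame of a circular
#' ablation movie (1 frame per second).
#'
#' @param df Data frame `pupa_id, frame, t_s, vertex_id, x_um, y_um` for
#'   one pupa.
#' @param axis A [reference_axis()].
#' @return Data frame `frame, t_s, major_um, minor_um, orientation_deg`.
#' @export
ellipse_series <- function(df, axis = reference_axis(0)) {
  stopifnot(all(c("frame", "t_s", "x_um", "y_um") %in% names(df)))
  rows <- lapply(split(df, df$frame), function(fr) {
    e <- fit_ellipse(cbind(fr$x_um, fr$y_um), axis)
    data.frame(frame = fr$frame[1], t_s = fr$t_s[1],
               major_um = e$major, minor_um = e$minor,
               orientation_deg = e$orientation_deg)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$t_s), ]
  rownames(out) <- NULL
  out
}

#' Fit saturating recoil dynamics of one ellipse axis
#'
#' Nonlinear least squares of `L(t) = Linf - (Linf - L0) * exp(-t / tau)`
#' to an axis-length series over the post-ablation window. The saturating
#' exponential is the standard viscoelastic (Kelvin-Voigt-type) relaxation
#' form for post-ablation opening; the paper-facing quantity (initial
#' recoil velocity) does not depend on this model choice.
#'
#' @param lengths Axis lengths in micrometers.
#' @param t Times in seconds (>= 6 frames).
#' @return List `L0, Linf, tau, no_recoil` (TRUE when the fitted total
#'   opening is below 1e-6 of L0).
#' @export
fit_axis_dynamics <- function(lengths, t) {
  stopifnot(length(lengths) == length(t), length(t) >= 6)
  d <- data.frame(t = t, L = lengths)
  if (stats::sd(lengths) < 1e-12 * mean(lengths)) {
    return(list(L0 = lengths[1], Linf = lengths[1], tau = NA_real_,
                no_recoil = TRUE))
  }
  do_fit <- function(st) minpack.lm::nlsLM(
    L ~ Linf - (Linf - L0) * exp(-t / tau), data = d, start = st,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, maxiter = 500))
  fit <- tryCatch(
    do_fit(list(L0 = lengths[1], Linf = lengths[length(lengths)],
                tau = max(diff(range(t)) / 3, 1))),
    error = function(e) tryCatch(
      do_fit(list(L0 = min(lengths), Linf = max(lengths),
                  tau = max(diff(range(t)) / 10, 1))),
      error = function(e2) stop("axis dynamics fit did not converge: ",
                                conditionMessage(e2))))
  cf <- stats::coef(fit)
  if (cf[["tau"]] <= 0) stop("fitted relaxation time not positive")
  list(L0 = unname(cf[["L0"]]), Linf = unname(cf[["Linf"]]),
       tau = unname(cf[["tau"]]),
       no_recoil = abs(cf[["Linf"]] - cf[["L0"]]) < 1e-6 * cf[["L0"]])
}

#' Initial recoil velocity over the first five seconds
#'
#' Ordinary least-squares slope of axis length against time over frames
#' t = 1..6 s (the first five seconds after ablation at 1 frame per
#' second). This operational definition is used directly, not the fitted
#' dynamic curve's derivative.
#'
#' @param lengths Axis lengths (micrometers).
#' @param t Frame times in seconds; must contain 1..6.
#' @return Velocity in micrometers per second.
#' @export
initial_recoil_velocity <- function(lengths, t) {
  sel <- match(1:6, t)
  if (anyNA(sel)) stop("frames t = 1..6 s are required")
  tt <- t[sel]; ll <- lengths[sel]
  sum((tt - mean(tt)) * (ll - mean(ll))) / sum((tt - mean(tt))^2)
}

#' Analyze a circular-ablation recoil experiment
#'
#' Per pupa: ellipse time series, initial recoil velocity of major and
#' minor axes (frames 1-6), and saturating NLS dynamics over the fit
#' window (default 180 s post-ablation).
#'
#' @param df Data frame `pupa_id, frame, t_s, vertex_id, x_um, y_um`.
#' @param axis A [reference_axis()].
#' @param fit_window Dynamics fit window in seconds.
#' @return A `recoil_result`: `per_pupa` data frame (`pupa_id, v_major,
#'   v_minor, anisotropy, L0/Linf/tau per axis`), `series` (list of ellipse
#'   time series).
#' @export
analyze_ablation <- function(df, axis = reference_axis(0), fit_window = 180) {
  series <- lapply(split(df, df$pupa_id), ellipse_series, axis = axis)
  rows <- lapply(names(series), function(p) {
    s <- series[[p]]
    v_maj <- initial_recoil_velocity(s$major_um, s$t_s)
    v_min <- initial_recoil_velocity(s$minor_um, s$t_s)
    w <- s$t_s <= fit_window & s$t_s >= 1
    dmaj <- if (sum(w) >= 6) fit_axis_dynamics(s$major_um[w], s$t_s[w]) else
      list(L0 = NA, Linf = NA, tau = NA, no_recoil = NA)
    dmin <- if (sum(w) >= 6) fit_axis_dynamics(s$minor_um[w], s$t_s[w]) else
      list(L0 = NA, Linf = NA, tau = NA, no_recoil = NA)
    data.frame(pupa_id = p, v_major = v_maj, v_minor = v_min,
               anisotropy = v_maj / v_min,
               major_L0 = dmaj$L0, major_Linf = dmaj$Linf,
               major_tau = dmaj$tau,
               minor_L0 = dmin$L0, minor_Linf = dmin$Linf,
               minor_tau = dmin$tau)
  })
  per_pupa <- do.call(rbind, rows)
  rownames(per_pupa) <- NULL
  structure(list(per_pupa = per_pupa, series = series),
            class = "recoil_result")
}

#' @export
print.recoil_result <- function(x, ...) {
  cat(sprintf("Ablation recoil: %d pupae\n", nrow(x$per_pupa)))
  cat(sprintf("  mean v_major = %.4f um/s, mean v_minor = %.4f um/s\n",
              mean(x$per_pupa$v_major), mean(x$per_pupa$v_minor)))
  invisible(x)
}

#' Compare major- and minor-axis recoil velocities
#'
#' Unpaired Student's t-test of per-pupa major vs minor initial recoil
#' velocities; tension is called anisotropic when p falls below
#' `alpha_level` (isotropic otherwise).
#'
#' @param result A `recoil_result` from [analyze_ablation()] (or its
#'   `per_pupa` data frame).
#' @param alpha_level Significance threshold for the isotropy call.
#' @return List `n_pupae, mean_v_major, mean_v_minor, anisotropy, t, p,
#'   isotropic`.
#' @export
compare_axes <- function(result, alpha_level = 0.05) {
  pp <- if (inherits(result, "recoil_result")) result$per_pupa else result
  if (nrow(pp) < 2) stop("comparison refused: need >= 2 pupae")
  tt <- tryCatch(stats::t.test(pp$v_major, pp$v_minor, var.equal = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) {  # zero-variance degenerate case
    p <- if (isTRUE(all.equal(mean(pp$v_major), mean(pp$v_minor)))) 1 else 0
    tt <- list(statistic = c(t = 0), p.value = p)
  }
  list(n_pupae = nrow(pp),
       mean_v_major = mean(pp$v_major), mean_v_minor = mean(pp$v_minor),
       anisotropy = mean(pp$v_major) / mean(pp$v_minor),
       t = unname(tt$statistic), p = tt$p.value,
       isotropic = tt$p.value >= alpha_level)
}
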