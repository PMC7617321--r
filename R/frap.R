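#' The FRAP acquisition schedule
#'
#' Three pre-bleach images with no delay (encoded as t = -3, -2, -1 s), an
#' immediate post-bleach image at t = 0, then five recovery images every
#' 5 s, ten every 10 s, ten every 15 s and seven every 30 s (last image at
#' t = 485 s).
#'
#' @return List with `pre` and `post` time vectors in seconds.
#' @export
frap_schedule <- function() {
  post <- c(0, 5 * (1:5), 25 + 10 * (1:10), 125 + 15 * (1:10),
            275 + 30 * (1:7))
  list(pre = c(-3, -2, -1), post = post)
}

#' FRAP trace set for one pupa and one junction-orientation class
#'
#' Bundles the bleached-ROI and paired unbleached-control intensity series
#' of the (typically four) same-orientation ROIs of one pupa, with a shared
#' scalar background. Built from long-format rows with columns
#' `pupa_id, roi_id, orientation, timepoint_s, intensity,
#' control_intensity, background`; negative timepoints are pre-bleach.
#'
#' @param df Long-format data frame (rows for one pupa and orientation).
#' @return A `frap_trace_set`.
#' @export
frap_trace_set <- function(df) {
  need <- c("pupa_id", "roi_id", "orientation", "timepoint_s", "intensity",
            "control_intensity", "background")
  stopifnot(all(need %in% names(df)))
  stopifnot(length(unique(df$pupa_id)) == 1,
            length(unique(df$orientation)) == 1)
  rois <- split(df, df$roi_id)
  rois <- lapply(rois, function(r) {
    r <- r[order(r$timepoint_s), ]
    pre <- r[r$timepoint_s < 0, ]
    post <- r[r$timepoint_s >= 0, ]
    if (nrow(pre) < 3) stop("need >= 3 pre-bleach points per ROI")
    if (any(diff(post$timepoint_s) <= 0))
      stop("post-bleach times must be strictly increasing")
    if (any(r$intensity < 0) || any(r$control_intensity < 0))
      stop("intensities must be nonnegative")
    list(t_pre = pre$timepoint_s, I_pre = pre$intensity,
         U_pre = pre$control_intensity,
         t = post$timepoint_s, I = post$intensity,
         U = post$control_intensity)
  })
  structure(list(pupa_id = df$pupa_id[1], orientation = df$orientation[1],
                 rois = rois, background = df$background[1]),
            class = "frap_trace_set")
}

#' Initial bleaching percentage
#'
#' `100 - 100 * (I0bar / Im1bar)` where `Im1bar` is the mean pre-bleach
#' intensity and `I0bar` the mean first post-bleach intensity, both averaged
#' over the same-orientation ROIs. Accepted experiments have initial
#' bleaching between 50 and 75 percent.
#'
#' @param traces A [frap_trace_set()].
#' @return Percentage.
#' @export
initial_bleaching <- function(traces) {
  i_pre <- mean(unlist(lapply(traces$rois, `[[`, "I_pre")))
  i_0 <- mean(vapply(traces$rois, function(r) r$I[1], 0))
  if (i_pre <= 0) stop("mean pre-bleach intensity must be positive")
  100 - 100 * (i_0 / i_pre)
}

#' Acquisition bleaching percentage
#'
#' `100 * (Um1bar - Uendbar) / (Um1bar - background)` from the unbleached
#' control ROIs: mean control intensity before bleaching vs at the last
#' timepoint. Accepted experiments stay below 25 percent.
#'
#' @param traces A [frap_trace_set()].
#' @return Percentage.
#' @export
acquisition_bleaching <- function(traces) {
  u_pre <- mean(unlist(lapply(traces$rois, `[[`, "U_pre")))
  u_end <- mean(vapply(traces$rois, function(r) r$U[length(r$U)], 0))
  bg <- traces$background
  if (u_pre <= bg) stop("mean pre-bleach control must exceed background")
  100 * (u_pre - u_end) / (u_pre - bg)
}

#' FRAP quality-control gates
#'
#' Passes when initial bleaching is within `[50, 75]` percent and
#' acquisition bleaching is below 25 percent.
#'
#' @param traces A [frap_trace_set()].
#' @return List `initial_bleaching_pct, acquisition_bleaching_pct, pass`.
#' @export
frap_qc <- function(traces) {
  ib <- initial_bleaching(traces)
  ab <- acquisition_bleaching(traces)
  list(initial_bleaching_pct = ib, acquisition_bleaching_pct = ab,
       pass = ib >= 50 && ib <= 75 && ab < 25)
}

#' Correct one ROI trace for acquisition bleaching and background
#'
#' `A_n = ((Um1bar - bg) / (U_n - bg)) * ((I_n - bg) / (ref - bg))`.
#' The reference denominator is the ROI's pre-bleach mean intensity, which
#' is what makes corrected pre-bleach intensities equal 1 (and is required
#' for the later 0-1 normalization to be non-degenerate). Setting
#' `literal_i0 = TRUE` instead divides by the first post-bleach intensity
#' `I_0`; this alternative reading is provided for comparison only.
#'
#' @param roi One element of `frap_trace_set$rois`.
#' @param background Scalar background.
#' @param literal_i0 Use `I_0` instead of the pre-bleach mean as reference.
#' @return Data frame `t, A` over post-bleach timepoints.
#' @export
correct_trace <- function(roi, background = 0, literal_i0 = FALSE) {
  bg <- background
  u_pre <- mean(roi$U_pre)
  ref <- if (literal_i0) roi$I[1] else mean(roi$I_pre)
  den_u <- roi$U - bg
  if (any(den_u <= 0))
    stop(sprintf("control intensity at t=%g s not above background",
                 roi$t[which(den_u <= 0)[1]]))
  if (ref - bg <= 0) stop("reference intensity not above background")
  A <- ((u_pre - bg) / den_u) * ((roi$I - bg) / (ref - bg))
  data.frame(t = roi$t, A = A)
}

#' Normalize a corrected trace to the 0-1 recovery scale
#'
#' `N(n) = (A_n - A_0) / (1 - A_0)`: the immediate post-bleach value maps to
#' 0 and the pre-bleach level to 1.
#'
#' @param corrected Data frame `t, A` from [correct_trace()].
#' @return Data frame `t, N`.
#' @export
normalize_trace <- function(corrected) {
  a0 <- corrected$A[1]
  if (a0 >= 1) stop("no bleach depth: A_0 >= 1")
  data.frame(t = corrected$t, N = (corrected$A - a0) / (1 - a0))
}

new_frap_fit <- function(coefs, ci, model, n, fit = NULL) {
  hl <- log(2) / coefs[["alpha"]]
  structure(list(coefficients = coefs, half_life = hl, ci = ci,
                 model = model, n = n, fit = fit),
            class = "frap_fit")
}

#' Fit a one-phase exponential recovery
#'
#' Nonlinear least squares of `y = y_max * (1 - exp(-alpha * t))` to a
#' normalized recovery curve. `y_max` is the fluorescence recovery plateau
#' (the mobile fraction: lower plateau = more stable protein) and `alpha`
#' the rate constant; the recovery half-life is `ln 2 / alpha`. Start
#' values: `y_max` from the last observation, `alpha` from the time to half
#' plateau; bounds `y_max` in (0, 1.5], `alpha` in (0, 10] per second.
#' 95 percent confidence intervals come from the asymptotic covariance of
#' the estimate.
#'
#' @param t Post-bleach times (seconds), starting at 0.
#' @param N Normalized intensities (N(0) = 0).
#' @return A `frap_fit` with `coefficients` (`y_max`, `alpha`),
#'   `half_life`, `ci` (2 x 2 matrix), `model`, `n`.
#' @export
fit_one_phase <- function(t, N) {
  stopifnot(length(t) == length(N), sum(t > 0) >= 6)
  y0 <- min(max(N[length(N)], 0.1), 1.4)
  th <- t[which(N >= y0 / 2)[1]]
  a0 <- if (is.na(th) || th <= 0) 0.05 else min(log(2) / th, 9)
  d <- data.frame(t = t, N = N)
  fit <- minpack.lm::nlsLM(
    N ~ ymax * (1 - exp(-alpha * t)), data = d,
    start = list(ymax = y0, alpha = a0),
    lower = c(1e-8, 1e-8), upper = c(1.5, 10),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 500))
  cf <- stats::coef(fit)
  if (cf[["alpha"]] <= 0) stop("fitted rate constant not positive")
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA, 2))
  q <- stats::qt(0.975, length(t) - 2)
  ci <- cbind(lower = cf - q * se, upper = cf + q * se)
  rownames(ci) <- c("y_max", "alpha")
  new_frap_fit(c(y_max = unname(cf[["ymax"]]), alpha = unname(cf[["alpha"]])),
               ci, "one_phase", length(t), fit)
}

#' Fit a two-phase exponential recovery
#'
#' `y = A1 * (1 - exp(-alpha1 * t)) + A2 * (1 - exp(-alpha2 * t))` with
#' `alpha1 > alpha2` (fast and slow phase). On one-phase data the model
#' collapses (one amplitude near 0 or near-equal rates) and confidence
#' intervals are frequently undefined; non-convergence or a singular
#' covariance yields NA entries rather than an error.
#'
#' @inheritParams fit_one_phase
#' @return A `frap_fit` with coefficients `A1, alpha1, A2, alpha2` (plus
#'   `y_max = A1 + A2` and `alpha = alpha1` used for half-life reporting).
#' @export
fit_two_phase <- function(t, N) {
  stopifnot(length(t) == length(N), sum(t > 0) >= 6)
  base <- tryCatch(fit_one_phase(t, N), error = function(e) NULL)
  y0 <- if (is.null(base)) max(N[length(N)], 0.2) else
    base$coefficients[["y_max"]]
  a0 <- if (is.null(base)) 0.02 else base$coefficients[["alpha"]]
  d <- data.frame(t = t, N = N)
  fit <- tryCatch(minpack.lm::nlsLM(
    N ~ A1 * (1 - exp(-a1 * t)) + A2 * (1 - exp(-a2 * t)), data = d,
    start = list(A1 = 0.6 * y0, a1 = 3 * a0, A2 = 0.4 * y0, a2 = a0 / 3),
    lower = rep(1e-9, 4), upper = c(1.5, 50, 1.5, 50),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit)) {
    cf <- c(A1 = NA_real_, alpha1 = NA_real_, A2 = NA_real_,
            alpha2 = NA_real_, y_max = NA_real_, alpha = NA_real_)
    ci <- matrix(NA_real_, 4, 2,
                 dimnames = list(c("A1", "alpha1", "A2", "alpha2"),
                                 c("lower", "upper")))
    return(structure(list(coefficients = cf, half_life = NA_real_, ci = ci,
                          model = "two_phase", n = length(t), fit = NULL),
                     class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  ## order phases fast first
  if (cf[["a1"]] < cf[["a2"]]) cf <- cf[c("A2", "a2", "A1", "a1")]
  cfv <- c(A1 = unname(cf[[1]]), alpha1 = unname(cf[[2]]),
           A2 = unname(cf[[3]]), alpha2 = unname(cf[[4]]))
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA, 4))
  q <- stats::qt(0.975, length(t) - 4)
  ci <- cbind(lower = unname(cf) - q * se, upper = unname(cf) + q * se)
  rownames(ci) <- names(cfv)
  out_cf <- c(cfv, y_max = sum(cfv[c("A1", "A2")]), alpha = cfv[["alpha1"]])
  structure(list(coefficients = out_cf,
                 half_life = log(2) / cfv[["alpha1"]],
                 ci = ci, model = "two_phase", n = length(t), fit = fit),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP %s fit (n = %d timepoints)\n", x$model, x$n))
  if (x$model == "one_phase") {
    cat(sprintf("  y_max = %.4f [%.4f, %.4f]\n", x$coefficients[["y_max"]],
                x$ci["y_max", 1], x$ci["y_max", 2]))
    cat(sprintf("  alpha = %.5f /s [%.5f, %.5f]  half-life = %.1f s\n",
                x$coefficients[["alpha"]], x$ci["alpha", 1],
                x$ci["alpha", 2], x$half_life))
  } else {
    print(round(x$coefficients, 5))
    cat(sprintf("  fast half-life = %.1f s\n", x$half_life))
  }
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) object$coefficients

#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) NULL else newdata$t
  cf <- object$coefficients
  if (object$model == "one_phase") {
    f <- function(t) cf[["y_max"]] * (1 - exp(-cf[["alpha"]] * t))
  } else {
    f <- function(t) cf[["A1"]] * (1 - exp(-cf[["alpha1"]] * t)) +
      cf[["A2"]] * (1 - exp(-cf[["alpha2"]] * t))
  }
  if (is.null(t)) stop("supply newdata = data.frame(t = ...)")
  f(t)
}

#' Full FRAP analysis with per-pupa aggregation and group comparison
#'
#' Runs the complete chain on a long-format trace table: per pupa and group,
#' QC gates (failures are warned about and flagged, not dropped unless
#' `drop_qc_failures`), per-ROI correction and normalization, averaging of
#' the normalized curves over the ROIs (technical replicates), a per-pupa
#' recovery fit, a group-level fit on the cross-pupa mean curve, and an
#' unpaired Student's t-test comparing per-pupa plateau (`y_max`) values
#' between two groups. N = pupae are the biological replicates.
#'
#' @param df Long-format data frame (see [frap_trace_set()]) with a grouping
#'   column named by `compare` (default `"orientation"`).
#' @param compare Name of the grouping column.
#' @param model `"one_phase"` or `"two_phase"` for the per-pupa fits.
#' @param literal_i0 Passed to [correct_trace()].
#' @param drop_qc_failures Exclude QC-failing pupa/group trace sets.
#' @return A `frap_comparison`: `pupa_fits` (data frame), `group_fits`
#'   (list of `frap_fit` on the cross-pupa mean curves), `qc` (data frame),
#'   `t_test` (htest or NULL), `mean_curves`.
#' @export
frap_analyze <- function(df, compare = "orientation", model = "one_phase",
                         literal_i0 = FALSE, drop_qc_failures = FALSE) {
  stopifnot(compare %in% names(df))
  df$..group <- df[[compare]]
  sets <- split(df, list(df$pupa_id, df$..group), drop = TRUE)
  fitfun <- if (model == "two_phase") fit_two_phase else fit_one_phase

  qc_rows <- list(); pupa_rows <- list(); curves <- list()
  for (s in sets) {
    ts <- frap_trace_set(s)
    qc <- frap_qc(ts)
    qc_rows[[length(qc_rows) + 1]] <- data.frame(
      pupa_id = ts$pupa_id, group = s$..group[1],
      initial_bleaching_pct = qc$initial_bleaching_pct,
      acquisition_bleaching_pct = qc$acquisition_bleaching_pct,
      pass = qc$pass)
    if (!qc$pass) {
      warning(sprintf("FRAP QC failed for pupa %s (%s): initial %.1f%%, acquisition %.1f%%",
                      ts$pupa_id, s$..group[1], qc$initial_bleaching_pct,
                      qc$acquisition_bleaching_pct))
      if (drop_qc_failures) next
    }
    Ns <- lapply(ts$rois, function(r)
      normalize_trace(correct_trace(r, ts$background, literal_i0)))
    tgrid <- Ns[[1]]$t
    Nmat <- vapply(Ns, function(x) x$N, numeric(length(tgrid)))
    Nbar <- rowMeans(Nmat)
    f <- fitfun(tgrid, Nbar)
    pupa_rows[[length(pupa_rows) + 1]] <- data.frame(
      pupa_id = ts$pupa_id, group = s$..group[1], n_rois = length(ts$rois),
      y_max = f$coefficients[["y_max"]], alpha = f$coefficients[["alpha"]],
      half_life = f$half_life, model = model,
      qc_pass = qc$pass)
    curves[[length(curves) + 1]] <- data.frame(
      pupa_id = ts$pupa_id, group = s$..group[1], t = tgrid, N = Nbar)
  }
  pupa_fits <- do.call(rbind, pupa_rows)
  qc_tab <- do.call(rbind, qc_rows)
  curve_tab <- do.call(rbind, curves)
  if (is.null(pupa_fits))
    return(structure(list(pupa_fits = NULL, group_fits = list(),
                          qc = qc_tab, t_test = NULL, mean_curves = list(),
                          compare = compare),
                     class = "frap_comparison"))

  ## group-level fit on the cross-pupa mean normalized curve
  group_fits <- lapply(split(curve_tab, curve_tab$group), function(g) {
    m <- stats::aggregate(N ~ t, g, mean)
    fitfun(m$t, m$N)
  })
  mean_curves <- lapply(split(curve_tab, curve_tab$group), function(g)
    stats::aggregate(N ~ t, g, mean))

  groups <- unique(pupa_fits$group)
  tt <- NULL
  if (length(groups) == 2) {
    v1 <- pupa_fits$y_max[pupa_fits$group == groups[1]]
    v2 <- pupa_fits$y_max[pupa_fits$group == groups[2]]
    if (length(v1) < 2 || length(v2) < 2)
      stop("comparison refused: need >= 2 pupae per group")
    tt <- tryCatch(stats::t.test(v1, v2, var.equal = TRUE),
                   error = function(e) {
                     ## zero-variance degenerate groups
                     p <- if (isTRUE(all.equal(mean(v1), mean(v2)))) 1 else 0
                     list(statistic = c(t = 0), p.value = p,
                          estimate = c(mean(v1), mean(v2)))
                   })
  }
  structure(list(pupa_fits = pupa_fits, group_fits = group_fits,
                 qc = qc_tab, t_test = tt, mean_curves = mean_curves,
                 compare = compare),
            class = "frap_comparison")
}

#' @export
print.frap_comparison <- function(x, ...) {
  cat("FRAP comparison by", x$compare, "\n")
  for (g in names(x$group_fits)) {
    f <- x$group_fits[[g]]
    n <- sum(x$pupa_fits$group == g)
    cat(sprintf("  %s (N = %d pupae): y_max = %.3f, half-life = %.1f s\n",
                g, n, f$coefficients[["y_max"]], f$half_life))
  }
  if (!is.null(x$t_test))
    cat(sprintf("  unpaired t-test on per-pupa y_max: t = %.3f, p = %.4g\n",
                x$t_test$statistic, x$t_test$p.value))
  invisible(x)
}
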