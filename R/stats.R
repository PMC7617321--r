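#' Two-sample Kolmogorov-Smirnov test on angle distributions
#'
#' Compares two samples of SOP-normalized angles treated as linear data on
#' `[0, 180)` (the origin is fixed by the SOP axis, exactly as the source
#' workflow applies the standard linear two-sample KS test). D is the
#' maximum difference between the two empirical cumulative distributions.
#' Exact p-values are used for small samples without ties
#' (`n1 * n2 <= 1e4`), the asymptotic approximation otherwise. Note that
#' for genuinely circular data this statistic depends on the chosen origin;
#' an origin-free alternative (Kuiper) is deliberately not provided.
#'
#' @param angles1,angles2 Nonempty numeric samples in `[0, 180)`.
#' @return List of class `ks_result`: `D, p_value, n1, n2, exact`.
#' @export
ks_two_sample <- function(angles1, angles2) {
  if (length(angles1) == 0 || length(angles2) == 0)
    stop("both samples must be nonempty")
  n1 <- length(angles1); n2 <- length(angles2)
  has_ties <- anyDuplicated(c(angles1, angles2)) > 0
  exact <- (n1 * n2 <= 1e4) && !has_ties
  kt <- suppressWarnings(stats::ks.test(angles1, angles2, exact = exact))
  structure(list(D = unname(kt$statistic), p_value = kt$p.value,
                 n1 = n1, n2 = n2, exact = exact),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.4g (n1 = %d, n2 = %d, %s p)\n",
              x$D, x$p_value, x$n1, x$n2,
              if (x$exact) "exact" else "asymptotic"))
  invisible(x)
}

#' Compare per-pupa values between groups
#'
#' Two groups are compared with an unpaired Student's t-test; three or more
#' with one-way ANOVA followed by Tukey-Kramer pairwise comparisons
#' (honestly significant difference on possibly unbalanced groups). Raw
#' pairwise p-values (pooled-variance t on the ANOVA mean square) are
#' reported alongside the Tukey-adjusted ones.
#'
#' @param values Numeric vector (e.g. AP:PD ratios per pupa).
#' @param group Group labels, same length.
#' @return A `group_comparison`: `test` ("t_test" or "anova_tukey"),
#'   `groups`, `n`, `statistic`, `p` (global), `pairs` (data frame with
#'   `group1, group2, diff, p_raw, p_adjusted`).
#' @export
compare_groups <- function(values, group) {
  stopifnot(length(values) == length(group))
  group <- factor(group)
  n <- table(group)
  if (any(n < 2))
    stop(sprintf("comparison refused: group(s) %s have fewer than 2 values",
                 paste(names(n)[n < 2], collapse = ", ")))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (nlevels(group) == 2) {
    lv <- levels(group)
    tt <- stats::t.test(values[group == lv[1]], values[group == lv[2]],
                        var.equal = TRUE)
    pairs <- data.frame(group1 = lv[1], group2 = lv[2],
                        diff = mean(values[group == lv[1]]) -
                          mean(values[group == lv[2]]),
                        p_raw = tt$p.value, p_adjusted = tt$p.value)
    return(structure(list(test = "t_test", groups = lv, n = as.vector(n),
                          statistic = unname(tt$statistic), p = tt$p.value,
                          pairs = pairs),
                     class = "group_comparison"))
  }
  fit <- stats::aov(values ~ group)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  mse <- an["Residuals", "Mean Sq"]
  dfres <- an["Residuals", "Df"]
  cmb <- utils::combn(levels(group), 2)
  p_raw <- apply(cmb, 2, function(g) {
    m <- diff(tapply(values, group, mean)[g])
    se <- sqrt(mse * (1 / n[[g[1]]] + 1 / n[[g[2]]]))
    2 * stats::pt(abs(m / se), dfres, lower.tail = FALSE)
  })
  key <- paste(cmb[2, ], cmb[1, ], sep = "-")
  pairs <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                      diff = -tk[key, "diff"],
                      p_raw = p_raw,
                      p_adjusted = tk[key, "p adj"])
  rownames(pairs) <- NULL
  structure(list(test = "anova_tukey", groups = levels(group),
                 n = as.vector(n),
                 statistic = an["group", "F value"],
                 p = an["group", "Pr(>F)"], pairs = pairs),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s across %d groups (n = %s): statistic = %.3f, p = %.4g\n",
              if (x$test == "t_test") "Student's t-test" else
                "One-way ANOVA + Tukey-Kramer",
              length(x$groups), paste(x$n, collapse = "/"),
              x$statistic, x$p))
  if (x$test != "t_test") print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Plot-ready circular histogram table
#'
#' Expands an [weighted_angle_histogram()] result into an 18-row table with
#' normalized weights (summing to 1 when the total weight is positive).
#'
#' @param dist An `angular_distribution`.
#' @return Data frame `bin_start, bin_end, weight, normalized_weight`.
#' @export
circular_histogram_table <- function(dist) {
  stopifnot(inherits(dist, "angular_distribution"))
  tot <- sum(dist$bin_weights)
  data.frame(bin_start = dist$bin_edges[-19],
             bin_end = dist$bin_edges[-1],
             weight = dist$bin_weights,
             normalized_weight = if (tot > 0) dist$bin_weights / tot else
               rep(0, 18))
}
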