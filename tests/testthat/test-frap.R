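## A hand-built trace set: one ROI, simple numbers, shared by formula tests.
manual_trace_set <- function(I_pre = 100, I0 = 30, U_pre = 1.0, U_end = 0.8,
                             bg = 0) {
  sch <- frap_schedule()
  n <- length(sch$post)
  df <- data.frame(
    pupa_id = 1, roi_id = "r1", orientation = "PD",
    timepoint_s = c(sch$pre, sch$post),
    intensity = c(rep(I_pre, 3), seq(I0, I_pre * 0.9, length.out = n)),
    control_intensity = c(rep(U_pre, 3), seq(U_pre, U_end, length.out = n)),
    background = bg)
  frap_trace_set(df)
}

test_that("bleaching percentages follow the ratio formulas", {
  ts <- manual_trace_set(I_pre = 100, I0 = 30)
  expect_equal(initial_bleaching(ts), 70)
  expect_equal(initial_bleaching(manual_trace_set(I0 = 100)), 0)
  expect_equal(initial_bleaching(manual_trace_set(I0 = 0)), 100)
  expect_equal(acquisition_bleaching(manual_trace_set(U_pre = 1, U_end = 0.8)),
               20)
  expect_equal(acquisition_bleaching(manual_trace_set(U_pre = 1, U_end = 1)),
               0)
  expect_equal(acquisition_bleaching(
    manual_trace_set(U_pre = 1.2, U_end = 0.9, bg = 0.2)), 30)
})

test_that("QC gates implement the 50-75% initial and <25% acquisition bounds", {
  pass <- frap_qc(manual_trace_set(I0 = 40, U_end = 0.9))   # 60%, 10%
  expect_true(pass$pass)
  expect_equal(pass$initial_bleaching_pct, 60)
  lo <- frap_qc(manual_trace_set(I0 = 70, U_end = 0.9))     # 30% initial
  expect_false(lo$pass)
  acq <- frap_qc(manual_trace_set(I0 = 40, U_end = 0.7))    # 30% acquisition
  expect_false(acq$pass)
  edge <- frap_qc(manual_trace_set(I0 = 50, U_end = 0.9))   # exactly 50%
  expect_true(edge$pass)
})

test_that("correction cancels shared multiplicative bleaching exactly", {
  sch <- frap_schedule()
  n <- length(sch$post)
  set.seed(5)
  b_n <- cumprod(runif(n, 0.985, 1))          # arbitrary bleaching profile
  R_n <- 40 + 55 * (1 - exp(-0.03 * sch$post))  # true recovery signal
  pre <- 100
  roi <- list(t_pre = sch$pre, I_pre = rep(pre, 3), U_pre = rep(80, 3),
              t = sch$post, I = b_n * R_n, U = b_n * 80)
  A <- correct_trace(roi, background = 0)
  expect_equal(A$A, R_n / pre, tolerance = 1e-12)
  ## adding a constant background to both channels changes nothing
  roi_bg <- roi
  roi_bg$I_pre <- roi$I_pre + 12; roi_bg$U_pre <- roi$U_pre + 12
  roi_bg$I <- roi$I + 12; roi_bg$U <- roi$U + 12
  ## multiplicative decay applies to signal only in this construction,
  ## so use bg applied after decay: I' = b*R + bg
  roi_bg$I <- b_n * R_n + 12; roi_bg$U <- b_n * 80 + 12
  A2 <- correct_trace(roi_bg, background = 12)
  expect_equal(A2$A, A$A, tolerance = 1e-12)
  ## with no acquisition bleaching and no background, A_n = I_n / Ipre
  roi0 <- roi; roi0$U <- rep(80, n)
  expect_equal(correct_trace(roi0, 0)$A, roi0$I / pre, tolerance = 1e-12)
})

test_that("normalization maps bleach depth onto the 0-1 scale", {
  A <- data.frame(t = 0:3, A = c(0.3, 0.3, 0.65, 1))
  N <- normalize_trace(A)
  expect_equal(N$N, c(0, 0, 0.5, 1))
  expect_error(normalize_trace(data.frame(t = 0:1, A = c(1.01, 1.2))),
               "bleach depth")
})

test_that("the whole chain is invariant to intensity units", {
  df <- make_frap(n_pupae = 2, y_max = c(PD = 0.7, AP = 0.7), alpha = 0.02,
                  noise_sd = 0.02, seed = 3)
  run <- function(d) {
    ts <- frap_trace_set(d[d$pupa_id == 1 & d$orientation == "PD", ])
    N <- normalize_trace(correct_trace(ts$rois[[1]], ts$background))
    coef(fit_one_phase(N$t, N$N))
  }
  base <- run(df)
  df2 <- df
  df2$intensity <- df2$intensity * 37.5
  df2$control_intensity <- df2$control_intensity * 37.5
  df2$background <- df2$background * 37.5
  expect_equal(run(df2), base, tolerance = 1e-9)
})

test_that("one-phase fits recover exact parameters and half-life", {
  sch <- frap_schedule()
  N <- 0.8 * (1 - exp(-0.02 * sch$post))
  f <- fit_one_phase(sch$post, N)
  expect_equal(coef(f)[["y_max"]], 0.8, tolerance = 1e-6)
  expect_equal(coef(f)[["alpha"]], 0.02, tolerance = 1e-6)
  expect_equal(f$half_life, log(2) / coef(f)[["alpha"]], tolerance = 1e-12)
  f2 <- fit_one_phase(sch$post, 0.6 * (1 - exp(-0.0231 * sch$post)))
  expect_equal(f2$half_life, 30.0, tolerance = 0.01)
})

test_that("two-phase fits nail exact mixtures and collapse on one-phase data", {
  sch <- frap_schedule()
  N2 <- 0.4 * (1 - exp(-0.1 * sch$post)) + 0.4 * (1 - exp(-0.005 * sch$post))
  f <- fit_two_phase(sch$post, N2)
  cf <- coef(f)
  expect_equal(cf[["A1"]], 0.4, tolerance = 1e-4)
  expect_equal(cf[["alpha1"]], 0.1, tolerance = 1e-4)
  expect_equal(cf[["A2"]], 0.4, tolerance = 1e-4)
  expect_equal(cf[["alpha2"]], 0.005, tolerance = 1e-4)
  ## one-phase data: amplitude collapse or rate coincidence
  N1 <- 0.8 * (1 - exp(-0.02 * sch$post))
  c1 <- coef(fit_two_phase(sch$post, N1))
  collapse <- min(c1[["A1"]], c1[["A2"]]) < 1e-3 ||
    abs(c1[["alpha1"]] - c1[["alpha2"]]) / c1[["alpha1"]] < 0.05
  expect_true(collapse)
  expect_equal(c1[["y_max"]], 0.8, tolerance = 1e-4)
})

test_that("per-pupa aggregation and plateau comparison match textbook t", {
  df <- make_frap(n_pupae = 3, y_max = c(PD = 0.55, AP = 0.85),
                  alpha = 0.02, noise_sd = 0.02, seed = 7)
  cmp <- frap_analyze(df)
  expect_equal(nrow(cmp$pupa_fits), 6)
  v1 <- cmp$pupa_fits$y_max[cmp$pupa_fits$group == "AP"]
  v2 <- cmp$pupa_fits$y_max[cmp$pupa_fits$group == "PD"]
  ## closed-form two-sample pooled t
  sp2 <- (2 * var(v1) + 2 * var(v2)) / 4
  t_manual <- (mean(v1) - mean(v2)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(unname(cmp$t_test$statistic), t_manual, tolerance = 1e-10)
  ## identical groups give p ~ 1 and zero difference
  dfx <- df[df$orientation == "PD", ]
  dfy <- dfx; dfy$orientation <- "AP"
  dfy$roi_id <- paste0(dfy$roi_id, "b")
  same <- frap_analyze(rbind(dfx, dfy))
  expect_equal(same$t_test$p.value, 1)
  ## single-pupa group refused
  one <- df[df$pupa_id == 1, ]
  expect_error(frap_analyze(one), "2 pupae")
})

test_that("QC failures warn and can be excluded from batch analysis", {
  df <- make_frap(n_pupae = 2, init_bleach_pct = 30, noise_sd = 0, seed = 1)
  w <- capture_warnings(res <- frap_analyze(df))
  expect_true(all(grepl("QC failed", w)) && length(w) == 4)
  expect_true(all(!res$qc$pass))
  w2 <- capture_warnings(res2 <- frap_analyze(df, drop_qc_failures = TRUE))
  expect_true(any(grepl("QC failed", w2)))
  expect_null(res2$pupa_fits)
})
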