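test_that("ellipse fitting interpolates exact point sets", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  e <- fit_ellipse(cbind(10 * cos(th), 5 * sin(th)))
  expect_equal(e$major, 20, tolerance = 1e-9)
  expect_equal(e$minor, 10, tolerance = 1e-9)
  expect_lt(axial_diff_test(e$orientation_deg, 0), 1e-6)
  ## circle: equal axes, orientation 0 by convention
  c0 <- fit_ellipse(cbind(5 * cos(th), 5 * sin(th)))
  expect_equal(c0$major, c0$minor, tolerance = 1e-9)
  expect_equal(c0$orientation_deg, 0)
  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10))), "collinear|ellipse")
  expect_error(fit_ellipse(cbind(1:4, c(2, 1, 3, 2))), ">= 5")
})

test_that("ellipse fitting is equivariant under rotation and translation", {
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  P <- cbind(8 * cos(th), 3 * sin(th))
  for (ang in c(20, 65, 140)) {
    r <- -ang * pi / 180  # screen-CCW rotation in y-down coordinates
    R <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
    P2 <- P %*% t(R) + matrix(c(4, -7), nrow(P), 2, byrow = TRUE)
    e <- fit_ellipse(P2)
    expect_equal(e$major, 16, tolerance = 1e-9)
    expect_equal(e$minor, 6, tolerance = 1e-9)
    expect_lt(axial_diff_test(e$orientation_deg, ang), 1e-6)
    expect_equal(unname(e$center), c(4, -7), tolerance = 1e-9)
  }
})

test_that("jittered ellipse points give small mean axis error", {
  set.seed(12)
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  errs <- replicate(200, {
    P <- cbind(12.15 * cos(th), 12.15 * sin(th)) +
      matrix(rnorm(48, 0, 0.05), ncol = 2)
    e <- fit_ellipse(P)
    abs(c(e$major, e$minor) - 24.3)
  })
  expect_lt(mean(errs), 0.05)
})

test_that("axis dynamics fits recover the saturating relaxation exactly", {
  t <- 1:180
  L <- 16 - (16 - 12) * exp(-t / 20)
  d <- fit_axis_dynamics(L, t)
  expect_equal(d$L0, 12, tolerance = 1e-6)
  expect_equal(d$Linf, 16, tolerance = 1e-6)
  expect_equal(d$tau, 20, tolerance = 1e-6)
  expect_false(d$no_recoil)
  flat <- fit_axis_dynamics(rep(14, 30), 1:30)
  expect_true(flat$no_recoil)
  ## noisy recovery within 5% over replicates
  set.seed(4)
  est <- replicate(200, {
    Ln <- L + rnorm(180, 0, 0.1)
    unlist(fit_axis_dynamics(Ln, t)[c("L0", "Linf", "tau")])
  })
  expect_lt(max(abs(rowMeans(est) - c(12, 16, 20)) / c(12, 16, 20)), 0.05)
})

test_that("initial recoil velocity is the OLS slope over frames 1-6", {
  t <- 0:20
  expect_equal(initial_recoil_velocity(10 + 2 * t, t), 2.0)
  expect_equal(initial_recoil_velocity(rep(7, 21), t), 0)
  expect_error(initial_recoil_velocity(1:4, 1:4), "1..6")
  ## exponential sampled at 1 fps matches the closed-form OLS slope
  L <- 20 - 5 * exp(-t / 15)
  tt <- 1:6; ll <- L[t %in% tt]
  manual <- sum((tt - mean(tt)) * (ll - mean(ll))) / sum((tt - mean(tt))^2)
  expect_equal(initial_recoil_velocity(L, t), manual, tolerance = 1e-9)
  ## invariant to constant offsets, linear in stretch
  expect_equal(initial_recoil_velocity(L + 100, t), manual, tolerance = 1e-12)
  expect_equal(initial_recoil_velocity(3 * L, t), 3 * manual,
               tolerance = 1e-12)
})

test_that("noiseless recoil generation round-trips velocities and tau", {
  rc <- make_recoil(n_pupae = 2, v_major = 0.2, v_minor = 0.1, tau = 20,
                    noise_sd = 0, seed = 2)
  ar <- analyze_ablation(rc)
  expect_equal(ar$per_pupa$v_major, rep(0.2, 2), tolerance = 1e-9)
  expect_equal(ar$per_pupa$v_minor, rep(0.1, 2), tolerance = 1e-9)
  expect_equal(ar$per_pupa$anisotropy, rep(2, 2), tolerance = 1e-7)
  expect_equal(ar$per_pupa$major_tau, rep(20, 2), tolerance = 1e-4)
  ## major axis aligned with the requested direction
  s <- ar$series[["1"]]
  late <- s[s$t_s > 50, ]
  expect_lt(max(axial_diff_test(late$orientation_deg, 0)), 1)
})

test_that("axis comparison calls isotropy on equal velocities", {
  rc <- make_recoil(n_pupae = 3, v_major = 0.15, v_minor = 0.15,
                    noise_sd = 0.02, t_max = 10, seed = 4)
  cx <- compare_axes(analyze_ablation(rc, fit_window = 0))
  expect_true(cx$p > 0.05)
  expect_true(cx$isotropic)
  one <- analyze_ablation(rc[rc$pupa_id == 1, ], fit_window = 0)
  expect_error(compare_axes(one), "2 pupae")
})
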