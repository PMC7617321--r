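test_that("division angle is the new-junction angle plus 90, an involution", {
  expect_equal(division_angle(0), 90)
  expect_equal(division_angle(135), 45)
  expect_equal(division_angle(90), 0)
  a <- seq(0, 179.5, by = 0.5)
  expect_equal(division_angle(division_angle(a)), a)
})

test_that("orientation summaries count the AP band and form ratios", {
  s <- summarize_orientations(c(90, 100, 50, 10))
  expect_equal(s$n_AP, 3)
  expect_equal(s$n_PD, 1)
  expect_equal(s$ap_pd_ratio, 3.0)
  s2 <- summarize_orientations(c(0, 170, 44))
  expect_equal(s2$ap_pd_ratio, 0)
  s3 <- summarize_orientations(c(90, 100))
  expect_true(is.na(s3$ap_pd_ratio))  # undefined, not infinite
  expect_equal(s3$n_AP + s3$n_PD, 2)
  ## uniform angles give a ratio near 1 (inside the binomial 99% CI)
  set.seed(6)
  u <- runif(1000, 0, 180)
  r <- summarize_orientations(u)$ap_pd_ratio
  ci <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gt(r, ci[1] / (1000 - ci[1]))
  expect_lt(r, ci[2] / (1000 - ci[2]))
})

test_that("scripted divisions and T1s are recovered from tracking + graphs", {
  fx <- small_timelapse(seed = 5)
  tl <- fx$tl; graphs <- fx$graphs
  dv <- detect_divisions(tl$tracking, graphs)
  tru_d <- tl$truth$divisions
  expect_equal(nrow(dv), nrow(tru_d))
  expect_setequal(dv$mother_lineage, tru_d$mother)
  expect_true(all(dv$flag == ""))
  ## the +90 relation holds exactly on every detected event
  expect_equal(dv$division_angle,
               (dv$new_junction_angle + 90) %% 180)
  ## angles agree with planted ground truth up to pixelation
  m <- match(dv$mother_lineage, tru_d$mother)
  expect_lt(max(axial_diff_test(dv$new_junction_angle,
                                tru_d$new_junction_angle[m])), 15)

  t1 <- detect_t1(tl$tracking, graphs, bond_cutoff = 4)
  tru_t <- tl$truth$t1s
  det <- pair_key(t1$cell_a, t1$cell_b)
  tru <- pair_key(tru_t$lose_a, tru_t$lose_b)
  expect_equal(sort(det), sort(tru))  # precision = recall = 1
  ## gaining pairs match too
  m2 <- match(det, tru)
  expect_equal(pair_key(t1$gain_a, t1$gain_b),
               pair_key(tru_t$gain_a, tru_t$gain_b)[m2])
})

test_that("static tissues and event-free tracking produce no events", {
  ts <- make_tissue(50, mean_cell_diameter_um = 2.5, seed = 2)
  g <- build_junction_graph(ts)
  graphs <- list(`0` = g, `1` = g)
  ids <- sort(unique(ts$label_map[ts$label_map > 0]))
  tr <- tracking_table(data.frame(frame = rep(0:1, each = length(ids)),
                                  cell_id = rep(ids, 2),
                                  lineage_id = rep(ids, 2),
                                  parent_lineage_id = NA))
  expect_equal(nrow(detect_divisions(tr, graphs)), 0)
  expect_equal(nrow(detect_t1(tr, graphs)), 0)
})

test_that("T1 detection is invariant to order-preserving cell relabeling", {
  fx <- small_timelapse(seed = 9)
  tl <- fx$tl; graphs <- fx$graphs
  t1 <- detect_t1(tl$tracking, graphs, bond_cutoff = 4)
  ## relabel: shift all ids by a constant offset
  off <- 10000L
  tr2 <- as.data.frame(tl$tracking)
  tr2$cell_id <- tr2$cell_id + off
  tr2$lineage_id <- tr2$lineage_id + off
  tr2$parent_lineage_id <- tr2$parent_lineage_id + off
  graphs2 <- lapply(graphs, function(g) {
    g$junctions$cell_a <- g$junctions$cell_a + off
    g$junctions$cell_b <- g$junctions$cell_b + off
    g
  })
  t1b <- detect_t1(tracking_table(tr2), graphs2, bond_cutoff = 4)
  expect_equal(nrow(t1b), nrow(t1))
  expect_setequal(pair_key(t1b$cell_a, t1b$cell_b),
                  pair_key(t1$cell_a + off, t1$cell_b + off))
})

test_that("the AP fraction tracks the orientation bias of planted divisions", {
  set.seed(3)
  ap_frac <- function(mu) {
    a <- rvonmises_axial(300, mu, 20)
    s <- summarize_orientations(a)
    s$n_AP / (s$n_AP + s$n_PD)
  }
  expect_gt(ap_frac(90), 0.95)
  expect_lt(ap_frac(0), 0.05)
})
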