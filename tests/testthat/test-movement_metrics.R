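# Step geometry, the four metrics, standardization, and the composite index.

test_that("step geometry matches hand computations", {
  tr <- make_traj(rbind(c(0, 0), c(1000, 0), c(2000, 0)))
  g <- step_geometry(tr, 2)
  expect_equal(c(g$d1, g$d2, g$c, g$turn_deg), c(1000, 1000, 2000, 0))
  expect_equal(c(g$dt1, g$dt2), c(240, 240))

  tr2 <- make_traj(rbind(c(0, 0), c(300, 0), c(300, 400)))
  g2 <- step_geometry(tr2, 2)
  expect_equal(c(g2$d1, g2$d2, g2$c, g2$turn_deg), c(300, 400, 500, 90))

  tr3 <- make_traj(rbind(c(0, 0), c(1000, 0), c(10, 0)))
  g3 <- step_geometry(tr3, 2)
  expect_equal(c(g3$d1, g3$d2, g3$c, g3$turn_deg), c(1000, 990, 10, 180))
})

test_that("geometry is undefined at endpoints and across long gaps", {
  tr <- make_traj(rbind(c(0, 0), c(100, 0), c(200, 0), c(300, 0)),
                  valid = c(TRUE, TRUE, FALSE, TRUE))
  expect_null(step_geometry(tr, 1))            # no t-1
  expect_null(step_geometry(tr, 4))            # no t+1
  expect_null(step_geometry(tr, 3))            # invalid fix itself
  g <- step_geometry(tr, 2)                    # 8-h forward gap: allowed at 2x
  expect_equal(g$dt2, 480)
  expect_null(step_geometry(tr, 2, gap_factor = 1.5))
})

test_that("speed, turning, and straightness evaluate per their formulas", {
  g <- list(d1 = 1200, d2 = 1200, dt1 = 240, dt2 = 240, c = 2400, turn_deg = 0)
  expect_equal(speed_at(g), 5)
  expect_equal(speed_at(list(d1 = 0, d2 = 0, dt1 = 240, dt2 = 240)), 0)
  expect_equal(speed_at(list(d1 = 600, d2 = 0, dt1 = 240, dt2 = 240)), 1.25)

  expect_equal(turn_standard(list(turn_deg = 0)), 0)
  expect_equal(turn_standard(list(turn_deg = 180)), 1)
  expect_equal(turn_standard(list(turn_deg = 90)), 0.5)

  expect_equal(straightness(list(d1 = 500, d2 = 500, c = 1000)), 1)
  expect_equal(straightness(list(d1 = 300, d2 = 400, c = 500)), 1.4)
  expect_equal(straightness(list(d1 = 1000, d2 = 990, c = 10)), 199)
  expect_identical(straightness(list(d1 = 100, d2 = 100, c = 0.5)), Inf)
  expect_identical(straightness(list(d1 = 100, d2 = 100, c = 0)), Inf)
})

test_that("site fidelity handles no-neighbor, single-neighbor and coincident cases", {
  # fixes 10 km apart: no neighbors within 100 m
  tr <- make_traj(rbind(c(0, 0), c(10000, 0), c(20000, 0)))
  expect_equal(site_fidelity(tr, 2), 0)

  # one neighbor at 50 m within the temporal window
  tr2 <- make_traj(rbind(c(0, 0), c(50, 0), c(10000, 0)))
  expect_equal(site_fidelity(tr2, 1), 50 * (1 / 672))
  expect_equal(site_fidelity(tr2, 1), 50 / 672, tolerance = 1e-12)

  # perfectly coincident fixes: mean distance 0 -> fidelity 0
  tr3 <- make_traj(rbind(c(0, 0), c(0, 0), c(0, 0)))
  expect_equal(site_fidelity(tr3, 2), 0)
})

test_that("site fidelity equals the O(n^2) brute-force oracle", {
  sim <- simulate_forager(sim_config(seed = 5, duration_days = 40,
                                     fix_success = 0.9))
  tr <- sim$trajectory
  got <- compute_metrics(tr)$site_fidelity_raw
  expect_equal(got, fidelity_oracle(tr), tolerance = 1e-12)
})

test_that("temporal window and weight denominator behave as configured", {
  # neighbor beyond +/- 8 weeks contributes nothing
  xy <- rbind(c(0, 0), c(10, 0))
  fixes <- data.frame(animal_id = "A1",
                      timestamp = c(t0, t0 + 9 * 7 * 24 * 3600),
                      x = xy[, 1], y = xy[, 2], valid = TRUE)
  tr <- trajectory(fixes)
  expect_equal(site_fidelity(tr, 1), 0)
  # widening the window brings it in
  expect_gt(site_fidelity(tr, 1, window = 10 * 7 * 24 * 60), 0)
})

test_that("adding a neighbor at the mean distance never decreases fidelity", {
  base <- rbind(c(0, 0), c(40, 0), c(80, 0))
  tr <- make_traj(base)
  f0 <- site_fidelity(tr, 1)
  dbar <- mean(c(40, 80))
  tr2 <- make_traj(rbind(base, c(dbar, 0)))
  f1 <- site_fidelity(tr2, 1)
  expect_gte(f1, f0)
})

test_that("scaling constants follow the decided rules", {
  m <- fake_metrics(speed = c(1, 2, 10), ta = c(0, 0, 0),
                    straight = c(1, 1, 1), fid = c(0, 1, 2))
  sc <- compute_scaling(m)
  expect_equal(sc$max_speed, 10)
  expect_equal(sc$max_fidelity, 2)

  m2 <- fake_metrics(speed = rep(1, 100), ta = rep(0, 100),
                     straight = 1:100, fid = rep(0, 100))
  expect_equal(compute_scaling(m2)$straightness_p90, 90.1)

  m3 <- fake_metrics(speed = 3, ta = 0.5, straight = 2, fid = 7)
  sc3 <- compute_scaling(m3)
  expect_equal(c(sc3$max_speed, sc3$straightness_p90, sc3$max_fidelity),
               c(3, 2, 7))

  m4 <- fake_metrics(speed = 1, ta = 0, straight = 1, fid = 0)
  m4$defined <- FALSE
  expect_error(compute_scaling(m4), "no defined")
})

test_that("capped-high straightness sentinels standardize to 1 and stay out of the percentile", {
  m <- fake_metrics(speed = rep(1, 10), ta = rep(0, 10),
                    straight = c(rep(2, 9), Inf), fid = rep(0, 10))
  sc <- compute_scaling(m)
  expect_true(is.finite(sc$straightness_p90))
  idx <- movement_index(m, sc)
  expect_equal(idx$straightness_std[10], 1)
})

test_that("the composite index evaluates and is bounded", {
  sc <- fake_scaling(max_speed = 10, p90 = 5, max_fid = 2)
  # slowest, most tortuous, most faithful: index 4
  m_hi <- fake_metrics(speed = 0, ta = 1, straight = Inf, fid = 2)
  expect_identical(movement_index(m_hi, sc)$index, 4)
  # fast straight novel-area move: index 0
  m_lo <- fake_metrics(speed = 10, ta = 0, straight = 0, fid = 0)
  expect_identical(movement_index(m_lo, sc)$index, 0)
  # all components at 0.5: index 2
  m_mid <- fake_metrics(speed = 5, ta = 0.5, straight = 2.5, fid = 1)
  expect_identical(movement_index(m_mid, sc)$index, 2)
})

test_that("defined records keep every invariant on simulated data", {
  sim <- simulate_forager(sim_config(seed = 2, duration_days = 60))
  m <- compute_metrics(sim$trajectory)
  idx <- movement_index(m)
  def <- m$defined
  expect_true(all(m$straightness_raw[def] >= 1 - 1e-12))
  expect_true(all(m$ta_standard[def] >= 0 & m$ta_standard[def] <= 1))
  for (cc in c("speed_std", "ta_standard", "straightness_std", "fidelity_std"))
    expect_true(all(idx[[cc]][def] >= 0 & idx[[cc]][def] <= 1), label = cc)
  expect_true(all(idx$index[def] >= 0 & idx$index[def] <= 4))
})

test_that("metrics are invariant to rigid motions of the coordinates", {
  sim <- simulate_forager(sim_config(seed = 4, duration_days = 20))
  tr <- sim$trajectory
  m0 <- compute_metrics(tr)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- cbind(tr$x, tr$y) %*% R
  tr2 <- tr
  tr2$x <- xy[, 1] + 12345; tr2$y <- xy[, 2] - 6789
  for (col in c("speed", "ta_standard", "straightness_raw", "site_fidelity_raw"))
    expect_equal(compute_metrics(tr2)[[col]], m0[[col]], tolerance = 1e-9)
})

test_that("doubling the sampling interval halves speed, leaves shape metrics alone", {
  sim <- simulate_forager(sim_config(seed = 6, duration_days = 20))
  tr <- sim$trajectory
  fixes2 <- data.frame(animal_id = tr$animal_id,
                       timestamp = t0 + (tr$seq - 1) * 480 * 60,
                       x = tr$x, y = tr$y, valid = tr$valid)
  tr2 <- trajectory(fixes2, nominal_interval = 480)
  m1 <- compute_metrics(tr)
  m2 <- compute_metrics(tr2, window = 2 * 8 * 7 * 24 * 60)
  expect_equal(m2$speed, m1$speed / 2, tolerance = 1e-12)
  expect_equal(m2$ta_standard, m1$ta_standard, tolerance = 1e-12)
  expect_equal(m2$straightness_raw, m1$straightness_raw, tolerance = 1e-12)
  expect_equal(m2$site_fidelity_raw, m1$site_fidelity_raw, tolerance = 1e-12)
})
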