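test_that("an equilibrium history is preserved to machine accuracy", {
  p <- p_sw(delta = 0.05)
  e2 <- equilibrium_point(p, "E2")
  traj <- dde_solve(p, history = unname(e2), t_end = 50)
  expect_false(traj$diverged)
  expect_lt(max(abs(sweep(traj$states, 2, e2))), 1e-6)
})

test_that("trajectory summaries recover a constructed signal", {
  tt <- seq(0, 100, by = 0.05)
  fake <- structure(list(
    times = tt,
    states = cbind(x = rep(0, length(tt)), y = rep(1, length(tt)),
                   z = 2 + sin(2 * pi * tt / 5)),
    params = ti_params(1, 1, 1, 1), diverged = FALSE),
    class = "ti_trajectory")
  s <- summarize_trajectory(fake)
  expect_identical(s$classification, "oscillatory")
  expect_equal(unname(s$amplitude["z"]), 2, tolerance = 0.01)
  expect_equal(s$period, 5, tolerance = 0.05)

  const <- structure(list(
    times = tt,
    states = cbind(x = rep(0.5, length(tt)), y = rep(1, length(tt)),
                   z = rep(2, length(tt))),
    params = ti_params(1, 1, 1, 1), diverged = FALSE),
    class = "ti_trajectory")
  sc <- summarize_trajectory(const)
  expect_identical(sc$classification, "steady")
  expect_equal(unname(sc$amplitude), c(0, 0, 0))
  expect_error(summarize_trajectory(const, transient_fraction = 0.9999),
               "3 samples")
})

test_that("tumor regression converges to the tumor-free equilibrium", {
  traj <- dde_solve(p_free(0.01), t_end = 300)
  s <- summarize_trajectory(traj)
  expect_identical(s$classification, "steady")
  expect_equal(unname(s$attractor_mean), c(0, 0.5 / 0.6, 0), tolerance = 1e-4)
})

test_that("immune escape is reported as divergence, not an error", {
  traj <- dde_solve(p_esc(0.01), t_end = 60)
  expect_true(traj$diverged)
  expect_identical(summarize_trajectory(traj)$classification, "divergent")
})

test_that("y and z stay nonnegative from nonnegative histories under study conditions", {
  set.seed(707)
  for (i in 1:30) {
    cs <- draw_study_case()
    traj <- dde_solve(cs$params, history = cs$history, t_end = 50)
    expect_gt(traj$min_y, -1e-9)
    expect_gt(traj$min_z, -1e-9)
  }
})

test_that("outside the study regime the lagged kill term can overshoot z through zero", {
  # genuine model behavior (confirmed against an independent DDE solver):
  # with a large a4*delta product the delayed term y(t-D) z(t-D) keeps
  # pushing z after z(t) has collapsed, and z crosses zero
  p <- ti_params(13.52, 0.231, 0.798, 13.96, delta = 0.049)
  traj <- dde_solve(p, history = c(0.235, 0.950, 1.121), t_end = 10,
                    max_step = 0.005)
  expect_lt(traj$min_z, 0)
})

test_that("the method of steps shows at least third-order convergence", {
  p <- p_sw(delta = 0.01)
  ends <- vapply(c(0.01, 0.005, 0.0025), function(ms) {
    tr <- dde_solve(p, history = c(1.76, 7.01, 0.343), t_end = 50,
                    max_step = ms, out_dt = 50)
    tr$states[nrow(tr$states), ]
  }, numeric(3))
  e1 <- sqrt(sum((ends[, 1] - ends[, 2])^2))
  e2 <- sqrt(sum((ends[, 2] - ends[, 3])^2))
  expect_gt(log2(e1 / e2), 3)
})

test_that("the mesh aligns breakpoints with nodes and respects max_step", {
  p <- p_sw(delta = 0.03)
  tr <- dde_solve(p, t_end = 10, max_step = 0.01)
  expect_equal(tr$solver$h * tr$solver$n_lag, 0.03, tolerance = 1e-15)
  expect_lte(tr$solver$h, 0.01 + 1e-15)
})

test_that("the undelayed path integrates through the ODE solver", {
  p <- p_free(0)
  traj <- dde_solve(p, t_end = 100)
  expect_identical(traj$solver$method, "lsoda")
  s <- summarize_trajectory(traj)
  expect_identical(s$classification, "steady")
  expect_equal(unname(s$attractor_mean[2]), 0.5 / 0.6, tolerance = 1e-4)
})
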