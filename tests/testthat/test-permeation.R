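test_that("event machine counts hand-checked traversals", {
  ## monotone inward sweep: one inward event
  ev <- detect_events(make_trace(seq(25, -25, by = -1)), 18, -18, 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "inward")
  expect_gt(ev$t_exit, ev$t_enter)
  ## enter and return to the same side: zero events (warns: never spans both)
  ev2 <- suppressWarnings(
    detect_events(make_trace(c(25, 20, 10, 0, 10, 20, 25)), 18, -18, 2))
  expect_equal(nrow(ev2), 0)
  ## double dip then full traversal: still exactly one event
  z3 <- c(25, 10, 22, 10, 0, -10, -25)
  ev3 <- detect_events(make_trace(z3), 18, -18, 2)
  expect_equal(nrow(ev3), 1)
  ## outward sweep
  ev4 <- detect_events(make_trace(seq(-25, 25, by = 1)), 18, -18, 2)
  expect_equal(ev4$direction, "outward")
})

test_that("time reversal preserves counts and flips directions", {
  set.seed(8)
  z <- cumsum(rnorm(400, mean = -0.4, sd = 2)) + 30
  fwd <- detect_events(make_trace(z), 18, -18, 2)
  rev_ev <- detect_events(make_trace(rev(z)), 18, -18, 2)
  expect_equal(nrow(fwd), nrow(rev_ev))
  expect_equal(sum(fwd$direction == "inward"), sum(rev_ev$direction == "outward"))
  expect_equal(sum(fwd$direction == "outward"), sum(rev_ev$direction == "inward"))
})

test_that("event counts are stable under sub-hysteresis jitter", {
  set.seed(3)
  z <- seq(30, -30, length.out = 300)
  base <- detect_events(make_trace(z), 18, -18, 2)
  for (rep in 1:5) {
    jit <- z + runif(length(z), -0.9, 0.9)  # < hysteresis / 2
    evj <- detect_events(make_trace(jit), 18, -18, 2)
    expect_equal(nrow(evj), nrow(base))
  }
})

test_that("traces that never span the thresholds warn and yield no events", {
  expect_warning(ev <- detect_events(make_trace(seq(5, -5, by = -1)), 18, -18, 2),
                 "never spans")
  expect_equal(nrow(ev), 0)
})

test_that("conductance arithmetic matches the worked example and conventions", {
  est <- estimate_conductance(c(5, 4, 6), duration = 500, voltage = 500)
  expect_equal(est$g_mean, 3.20, tolerance = 0.005)
  expect_equal(est$g_per_replica, c(3.204, 2.563, 3.845), tolerance = 0.001)
  expect_equal(round(est$g_spread, 2), 0.52)
  est_s <- estimate_conductance(c(5, 4, 6), 500, 500,
                                spread_convention = "sample_sd")
  expect_equal(round(est_s$g_spread, 2), 0.64)
  est_e <- estimate_conductance(c(5, 4, 6), 500, 500, spread_convention = "sem")
  expect_equal(round(est_e$g_spread, 2), 0.37)
  ## single event at 1 ns / 100 mV is 1.602 nS
  one <- estimate_conductance(1, duration = 1, voltage = 100)
  expect_equal(one$g_mean, 1602.18, tolerance = 0.01)
  expect_equal(estimate_conductance(0, 100, 500)$g_mean, 0)
  expect_error(estimate_conductance(integer(0), 500, 500), "empty")
})

test_that("conductance scales linearly in N and inversely in T and V", {
  base <- estimate_conductance(4, 100, 200)$g_mean
  expect_equal(estimate_conductance(8, 100, 200)$g_mean, 2 * base)
  expect_equal(estimate_conductance(4, 200, 200)$g_mean, base / 2)
  expect_equal(estimate_conductance(4, 100, 400)$g_mean, base / 2)
})

test_that("ion projection unwraps periodic crossings before projecting", {
  ## ion drifts from +25 to -35 in a 60 A box: wraps once
  z_path <- seq(25, -35, by = -0.5)
  traj <- make_ion_trajectory(z_path, box_z = 60)
  fr <- build_pore_frame(traj$topology)
  traces <- project_ions(traj, fr, species = "elem K")[[1]]
  tr <- traces[[1]]
  expect_lt(max(abs(diff(tr$z))), 30)            # continuous after unwrap
  expect_equal(diff(range(tr$z)), 60, tolerance = 1)
  ## constant xy offset from the axis is preserved
  expect_equal(tr$r_offset, rep(sqrt(0.5^2 + 0.3^2), length(z_path)),
               tolerance = 1e-6)
})

test_that("projection is invariant under rigid translation of the system", {
  z_path <- seq(10, -10, by = -0.5)
  traj <- make_ion_trajectory(z_path, box_z = 200)  # no wrapping
  fr <- build_pore_frame(traj$topology)
  tr0 <- project_ions(traj, fr)[[1]][[1]]
  traj2 <- traj
  traj2$replicas[[1]] <- traj$replicas[[1]] + 7.3
  ## frame rebuilt on the translated topology co-moves
  topo2 <- porekinetics:::set_coords(traj$topology, coords(traj$topology) + 7.3)
  traj2$topology <- topo2
  fr2 <- build_pore_frame(topo2)
  tr2 <- project_ions(traj2, fr2)[[1]][[1]]
  expect_equal(tr2$z, tr0$z, tolerance = 1e-9)
  expect_equal(tr2$r_offset, tr0$r_offset, tolerance = 1e-9)
})

test_that("trace sets pass through identity when no frame is given", {
  sim <- simulate_ion_langevin(langevin_spec(n_ions = 1, duration = 1, seed = 2))
  pr <- project_ions(sim$traces)[[1]]
  expect_equal(pr[[1]]$z, sim$traces[[1]]$z)
  expect_equal(pr[[1]]$r_offset,
               sqrt(sim$traces[[1]]$x^2 + sim$traces[[1]]$y^2))
})

test_that("langevin flux matches the drift expectation within 2 SE over seeds", {
  net <- expected <- numeric(20)
  for (s in 1:20) {
    sp <- langevin_spec(n_ions = 2, duration = 500, dt = 0.002, voltage = -100,
                        membrane_span = c(-49.9, 49.9), domain_length = 100,
                        diffusion_D = 196, seed = 700 + s)
    sim <- simulate_ion_langevin(sp, record_interval = 0.02)
    ev <- detect_events(sim$traces, 18, -18, 2, domain_length = 100)
    net[s] <- (sum(ev$direction == "inward") - sum(ev$direction == "outward")) /
      sp$n_ions
    expected[s] <- abs(sim$expected_crossings_per_ion)
  }
  se <- sd(net) / sqrt(length(net))
  expect_lt(abs(mean(net) - mean(expected)), 2 * se)
})

test_that("trace statistics report dwell, occupancy and axial offsets", {
  ## ion parked at the pause site for 100 samples of 1 ns
  z <- c(seq(30, 10.4, by = -0.2), rep(10, 100), seq(9.8, -30, by = -0.2))
  st <- trace_statistics(make_trace(z), filter_window = c(5, 15),
                         pause_site_z = 10, pause_radius = 2)
  expect_equal(st$max_dwell_ns, 100, tolerance = 3)
  ## two ions inside the filter window in every frame
  t2 <- structure(list(
    structure(data.frame(t = 1:50, z = 8, r_offset = 0.5), ion_id = "a"),
    structure(data.frame(t = 1:50, z = 12, r_offset = 0.5), ion_id = "b")),
    class = "ion_trace_set")
  st2 <- trace_statistics(t2, filter_window = c(5, 15))
  expect_equal(unname(st2$occupancy_fraction["2"]), 1.0)
  ## all on-axis samples fall below any positive cutoff
  expect_equal(st2$offset_below_cutoff_fraction, 1.0)
})
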