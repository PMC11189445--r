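test_that("self-superposition is the identity with zero RMSD", {
  m <- generate_kinked_helix(12)$model
  sup <- superpose_kabsch(m, m, "backbone")
  expect_lt(sup$rmsd, 1e-10)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-10)
})

test_that("a known rotation is recovered exactly", {
  m <- generate_kinked_helix(12)$model
  R <- porekinetics:::rotation_matrix(c(2, -1, 0.5), 1.2)
  m2 <- porekinetics:::set_coords(m, sweep(coords(m) %*% t(R), 2, c(1, 2, 3), "+"))
  sup <- superpose_kabsch(m2, m, "backbone")
  expect_lt(sup$rmsd, 1e-6)
  expect_equal(sup$rotation %*% R, diag(3), tolerance = 1e-8)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-10)
})

test_that("Kabsch RMSD matches the brute-force quaternion minimum", {
  set.seed(12)
  for (case in 1:3) {
    P <- matrix(rnorm(30, sd = 4), 10, 3)
    R <- porekinetics:::rotation_matrix(rnorm(3), runif(1, 0.2, 2.5))
    Q <- sweep(P %*% t(R), 2, c(2, -1, 4), "+") + matrix(rnorm(30, sd = 0.4), 10, 3)
    mp <- molecular_model(data.frame(name = "CA", resname = "ALA", resid = 1:10,
                                     chain = "A", x = P[, 1], y = P[, 2],
                                     z = P[, 3], element = "C"))
    mq <- porekinetics:::set_coords(mp, Q)
    rmsd_kabsch <- superpose_kabsch(mp, mq, "name CA")$rmsd
    rmsd_bf <- rmsd_bruteforce(P, Q)
    expect_lt(abs(rmsd_kabsch - rmsd_bf), 1e-3)
    expect_lte(rmsd_kabsch, rmsd_bf + 1e-9)
  }
})

test_that("superposed RMSD never exceeds the unaligned RMSD", {
  set.seed(9)
  m <- generate_kinked_helix(15)$model
  for (i in 1:5) {
    R <- porekinetics:::rotation_matrix(rnorm(3), runif(1, 0, 3))
    m2 <- porekinetics:::set_coords(m,
      sweep(coords(m) %*% t(R), 2, rnorm(3, sd = 3), "+") +
        matrix(rnorm(3 * nrow(m), sd = 0.5), nrow(m), 3))
    aligned <- superpose_kabsch(m2, m, "backbone")$rmsd
    raw <- sqrt(mean(rowSums((coords(m2) - coords(m))^2)))
    expect_lte(aligned, raw + 1e-9)
  }
})

test_that("pairing mismatches raise an informative error", {
  m <- generate_kinked_helix(12)$model
  m_short <- molecular_model(as.data.frame(m)[m$resid <= 10, ])
  expect_error(superpose_kabsch(m, m_short, "name CA"), "unmatched")
})

test_that("RMSF reproduces the isotropic-jitter closed form", {
  set.seed(2)
  topo <- generate_kinked_helix(12)$model
  n_at <- nrow(topo); n_fr <- 10000; sigma <- 0.4
  arr <- array(rep(coords(topo), each = n_fr), c(n_fr, n_at, 3)) +
    array(rnorm(n_fr * n_at * 3, sd = sigma), c(n_fr, n_at, 3))
  traj <- structure(list(replicas = list(arr), box = list(NULL),
                         frame_interval = 0.1, topology = topo),
                    class = "trajectory_ensemble")
  fp <- fluctuation_profiles(traj, align_expr = NULL, measure_expr = "all")
  expect_equal(mean(fp$rmsf$rmsf), sigma * sqrt(3), tolerance = 0.02)
})

test_that("a static trajectory has zero RMSF and aligned wobble zero RMSD", {
  topo <- generate_kinked_helix(10)$model
  n_at <- nrow(topo)
  arr <- array(rep(coords(topo), each = 5), c(5, n_at, 3))
  traj <- structure(list(replicas = list(arr), box = list(NULL),
                         frame_interval = 1, topology = topo),
                    class = "trajectory_ensemble")
  fp <- fluctuation_profiles(traj, align_expr = NULL, measure_expr = "name CA")
  expect_true(all(fp$rmsf$rmsf < 1e-10))
  ## rigid-body wobble removed by alignment
  set.seed(5)
  arr2 <- arr
  for (f in 1:5) {
    R <- porekinetics:::rotation_matrix(rnorm(3), runif(1, 0, 0.5))
    arr2[f, , ] <- sweep(arr[f, , ] %*% t(R), 2, rnorm(3, sd = 2), "+")
  }
  traj2 <- traj; traj2$replicas <- list(arr2)
  fp2 <- fluctuation_profiles(traj2, align_expr = "backbone",
                              measure_expr = "name CA")
  expect_true(all(fp2$rmsd$rmsd < 1e-8))
})

test_that("helix bend recovery matches the generator ground truth", {
  h0 <- generate_kinked_helix(30)
  expect_lt(helix_axes_and_bend(h0$model, c(1, 15), c(16, 30))$bend_angle, 1)
  for (bend in c(15, 30, 45)) {
    h <- generate_kinked_helix(30, kink_after = 15, bend_deg = bend)
    got <- helix_axes_and_bend(h$model, h$segments$pre, h$segments$post)
    expect_equal(got$bend_angle, bend, tolerance = 2)
    ## symmetric in the segments
    swapped <- helix_axes_and_bend(h$model, h$segments$post, h$segments$pre)
    expect_equal(swapped$bend_angle, got$bend_angle, tolerance = 1e-9)
  }
  expect_error(helix_axes_and_bend(h0$model, c(1, 3), c(16, 30)), ">= 5")
})

test_that("bend angle is invariant under rigid motion and uniform scaling", {
  h <- generate_kinked_helix(30, kink_after = 15, bend_deg = 25)
  a0 <- helix_axes_and_bend(h$model, h$segments$pre, h$segments$post)$bend_angle
  R <- porekinetics:::rotation_matrix(c(1, 0, 2), 0.9)
  m2 <- porekinetics:::set_coords(h$model,
    sweep(coords(h$model) %*% t(R), 2, c(10, -5, 2), "+"))
  expect_equal(helix_axes_and_bend(m2, h$segments$pre, h$segments$post)$bend_angle,
               a0, tolerance = 1e-9)
  m3 <- porekinetics:::set_coords(h$model, coords(h$model) * 2.5)
  expect_equal(helix_axes_and_bend(m3, h$segments$pre, h$segments$post)$bend_angle,
               a0, tolerance = 1e-9)
})

test_that("helicity marks ideal helices helical and strands non-helical", {
  h <- generate_kinked_helix(30)
  hp <- helicity_profile(h$model, c(1, 30))
  expect_true(all(hp$per_residue$helical | hp$per_residue$indeterminate))
  strand <- porekinetics:::build_backbone(rep(-120, 12), rep(130, 12))
  sp <- helicity_profile(strand, c(1, 12))
  expect_true(all(!sp$per_residue$helical))
})

test_that("unwound tails are recovered exactly for tails >= 2", {
  for (tail in c(2, 5, 7)) {
    h <- generate_kinked_helix(30, unwound_tail = tail)
    runs <- helicity_profile(h$model, c(1, 30))$nonhelical_runs
    expect_equal(nrow(runs), 1)
    expect_equal(runs$length, tail)
    expect_equal(runs$end, 30)
    expect_equal(runs$turns, tail / 3.6)
  }
  ## a 7-residue tail is about two helical turns
  h7 <- generate_kinked_helix(30, unwound_tail = 7)
  expect_equal(helicity_profile(h7$model, c(1, 30))$nonhelical_runs$turns,
               1.94, tolerance = 0.01)
})

test_that("labeled displacements are zero for identical models and exact for shifts", {
  m <- generate_kinked_helix(12)$model
  labs <- data.frame(label = c("R4", "R5"), resid = c(5, 8), atom = "CA")
  d0 <- charge_displacement(m, m, labs, align_expr = "resid 1-4 and backbone")
  expect_true(all(d0$distance < 1e-10))
  ## shift applied to the labeled atoms only (alignment anchored elsewhere)
  m2 <- m
  xyz <- coords(m2)
  idx <- which(m2$resid %in% c(5, 8) & m2$name == "CA")
  xyz[idx, 3] <- xyz[idx, 3] + 5
  m2 <- porekinetics:::set_coords(m2, xyz)
  d5 <- charge_displacement(m, m2, labs, align_expr = "resid 1-4 and backbone")
  expect_equal(d5$distance, c(5, 5), tolerance = 1e-6)
  ## missing label yields a per-label marker
  labs2 <- rbind(labs, data.frame(label = "RX", resid = 99, atom = "CA"))
  d <- charge_displacement(m, m2, labs2, align_expr = "resid 1-4 and backbone")
  expect_false(d$found[3])
  expect_true(is.na(d$distance[3]))
})
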