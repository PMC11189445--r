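test_that("uniform samples give a flat density and a flat PMF", {
  set.seed(5)
  tr <- structure(list(structure(
    data.frame(t = 1:50000, z = runif(50000, -10, 10), r_offset = 0),
    ion_id = "u")), class = "ion_trace_set")
  dens <- ion_density_profile(tr, seq(-10, 10, by = 2), radial_cutoff = Inf)
  expect_true(all(dens$count > 0))
  expect_lt(diff(range(dens$count)) / mean(dens$count), 0.1)  # Poisson-flat
  pmf <- pmf_from_density(dens, reference_window = c(-10, 10))
  expect_lt(max(abs(pmf$F)), 0.05)
})

test_that("a point mass lands in a single bin and masks the rest", {
  tr <- make_trace(rep(1.2, 100))
  dens <- ion_density_profile(tr, seq(-5, 5, by = 1), radial_cutoff = Inf)
  expect_equal(sum(dens$count > 0), 1)
  expect_equal(sum(is.na(dens$density)), 9)
})

test_that("a 10:1 density ratio maps to -kT ln 10 = 1.364 kcal/mol", {
  d <- data.frame(z_mid = c(0, 1), density = c(1, 0.1))
  pmf <- pmf_from_density(d, reference_window = c(-0.5, 0.5))
  expect_equal(pmf$F[2], 1.364, tolerance = 1e-3)
})

test_that("the PMF is invariant to rescaling the density", {
  d <- data.frame(z_mid = 0:4, density = c(2, 1, 0.5, 1, 2))
  p1 <- pmf_from_density(d, reference_window = c(-0.5, 0.5))
  d2 <- d; d2$density <- d$density * 37.5
  p2 <- pmf_from_density(d2, reference_window = c(-0.5, 0.5))
  expect_equal(p1$F, p2$F, tolerance = 1e-12)
})

test_that("Boltzmann inversion recovers a 2 kcal/mol double barrier", {
  zg <- seq(-20, 20, by = 0.25)
  u <- 2 * exp(-(zg + 8)^2 / 8) + 2 * exp(-(zg - 8)^2 / 8)
  tr <- sample_boltzmann_z(data.frame(z = zg, u = u), n_samples = 1e6,
                           step_sd = 3, thin = 2, seed = 21)
  dens <- ion_density_profile(tr, seq(-20, 20, by = 0.5), radial_cutoff = Inf)
  pmf <- pmf_from_density(dens, reference_window = c(-20, -16))
  u_ref <- approx(zg, u, pmf$z_mid)$y
  u_ref <- u_ref - mean(u_ref[pmf$z_mid >= -20 & pmf$z_mid <= -16])
  expect_lt(max(abs(pmf$F - u_ref), na.rm = TRUE), 0.1)
  for (site in c(-8, 8)) {
    expect_equal(max(pmf$F[abs(pmf$z_mid - site) < 1]), 2.0, tolerance = 0.1)
  }
})

test_that("the linear tilt correction removes an applied-field ramp", {
  ## density generated from a pure field ramp: corrected PMF is flat
  zg <- seq(-10, 10, by = 1)
  kT <- kT_kcal(298)
  ramp <- voltage_energy_kcal(-100) * (zg - 0) / 20
  d <- data.frame(z_mid = zg, density = exp(-ramp / kT))
  pmf <- pmf_from_density(d, reference_window = c(-1, 1),
                          tilt_correction = "linear", voltage = -100, span = 20)
  expect_lt(max(abs(pmf$F)), 1e-9)
})

test_that("hydration profile counts cylinder waters and flags dry bins", {
  sn <- generate_solvation_snapshot(18, cylinder_radius = 12,
                                    n_first_shell = 6, n_decoys = 12, seed = 6)
  hp <- hydration_profile(sn$model, pore_frame(), cylinder_radius = 12,
                          z_breaks = seq(-16, 16, by = 4))
  expect_equal(sum(hp$mean_waters), 18)  # decoys excluded by the cylinder
  ## empty system: all-zero, all-dry, with a warning
  empty <- molecular_model(data.frame(name = "K", resname = "K", resid = 1,
                                      chain = "I", x = 0, y = 0, z = 0,
                                      element = "K"))
  expect_warning(h0 <- hydration_profile(empty, pore_frame()), "no water")
  expect_true(all(h0$mean_waters == 0))
  expect_true(all(!h0$wet))
})

test_that("coordination counts shell waters and reports waters lost", {
  sn <- generate_solvation_snapshot(20, n_first_shell = 6, shell_radius = 2.8,
                                    seed = 4)
  cn <- coordination_number(sn$model, pore_frame(), "elem K",
                            shell_cutoff = 3.5)
  expect_equal(cn$per_frame$n_waters, 6)
  ## cutoff below the closest water gives zero
  cn0 <- coordination_number(sn$model, pore_frame(), "elem K",
                             shell_cutoff = 2.0)
  expect_equal(cn0$per_frame$n_waters, 0)
  ## waters-lost arithmetic on constructed frames: bulk 6, site 3
  bulk <- generate_solvation_snapshot(12, n_first_shell = 6, ion_z = 15,
                                      seed = 7)
  site <- generate_solvation_snapshot(8, n_first_shell = 3, ion_z = 0, seed = 8)
  cn2 <- coordination_number(list(bulk$model, site$model), pore_frame(),
                             "elem K")
  wl <- waters_lost(cn2, bulk_window = c(10, 20), site_window = c(-5, 5))
  expect_equal(wl$waters_lost, 3)
})

test_that("hydrogen bonds obey the distance and angle criterion", {
  ## ideal linear O-H...O at 2.8 A: one bond, credited to both groups
  don <- data.frame(name = c("OG", "HG"), resname = "SER", resid = 1,
                    chain = "A", x = c(0, 0.96), y = 0, z = 0,
                    element = c("O", "H"))
  acc <- data.frame(name = "O", resname = "HOH", resid = 2, chain = "W",
                    x = 2.8, y = 0, z = 0, element = "O")
  m <- molecular_model(rbind(don, acc))
  hb <- hbond_stats(m, donor_groups = list(ser = "resid 1 and elem O"),
                    acceptor_groups = list(wat = "resid 2"))
  expect_equal(hb$mean_hbonds[hb$group == "ser"], 1)
  expect_equal(hb$mean_hbonds[hb$group == "wat"], 1)
  ## 3.6 A exceeds the default cutoff: no bond
  acc_far <- acc; acc_far$x <- 3.6
  m2 <- molecular_model(rbind(don, acc_far))
  hb2 <- hbond_stats(m2, list(ser = "resid 1 and elem O"),
                     list(wat = "resid 2"))
  expect_true(all(hb2$mean_hbonds == 0))
  ## bent geometry (90 deg) fails the angle criterion
  don_bent <- don; don_bent$x[2] <- 0; don_bent$y[2] <- 0.96
  m3 <- molecular_model(rbind(don_bent, acc))
  hb3 <- hbond_stats(m3, list(ser = "resid 1 and elem O"),
                     list(wat = "resid 2"))
  expect_true(all(hb3$mean_hbonds == 0))
})

test_that("a ring of four mutually donating hydroxyls averages 2.0 per group", {
  ## square of O-H groups, each H aimed at the next O, side 2.8 A
  rows <- list()
  pos <- rbind(c(0, 0), c(2.8, 0), c(2.8, 2.8), c(0, 2.8))
  for (i in 1:4) {
    nxt <- pos[(i %% 4) + 1, ]
    dir <- (nxt - pos[i, ]) / sqrt(sum((nxt - pos[i, ])^2))
    rows[[i]] <- data.frame(
      name = c("OH", "HH"), resname = "TYR", resid = i, chain = "A",
      x = c(pos[i, 1], pos[i, 1] + 0.96 * dir[1]),
      y = c(pos[i, 2], pos[i, 2] + 0.96 * dir[2]),
      z = 0, element = c("O", "H"))
  }
  m <- molecular_model(do.call(rbind, rows))
  grp <- as.list(sprintf("resid %d and elem O", 1:4))
  names(grp) <- sprintf("y%d", 1:4)
  hb <- hbond_stats(m, donor_groups = grp, acceptor_groups = grp)
  expect_equal(hb$mean_hbonds, rep(2, 4))
})

test_that("donors without hydrogens fall back to distance-only with warning", {
  don <- data.frame(name = "OG", resname = "SER", resid = 1, chain = "A",
                    x = 0, y = 0, z = 0, element = "O")
  acc <- data.frame(name = "O", resname = "HOH", resid = 2, chain = "W",
                    x = 2.8, y = 0, z = 0, element = "O")
  m <- molecular_model(rbind(don, acc))
  expect_warning(hb <- hbond_stats(m, list(ser = "resid 1"),
                                   list(wat = "resid 2")), "distance-only")
  expect_equal(hb$mean_hbonds[hb$group == "ser"], 1)
})
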