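test_that("PDB reading preserves identities and collapses altlocs", {
  path <- write_tiny_pdb()
  m <- read_structure(path)
  ## 5 records, but the TYR CA altloc pair collapses to the B conformer
  expect_equal(nrow(m), 4)
  expect_equal(sort(unique(m$resid)), c(10, 11))
  ca11 <- m[m$resid == 11 & m$name == "CA", ]
  expect_equal(ca11$occupancy, 0.60)
  expect_equal(ca11$x, 9.480, tolerance = 1e-6)
})

test_that("structure write -> read round-trips coordinates (PDB and mmCIF)", {
  m <- generate_ring_pore(ring_pore_spec(z_planes = c(0, 3), ring_radius = 5,
                                         atoms_per_ring = 12))$model
  pdb <- tempfile(fileext = ".pdb")
  cif <- tempfile(fileext = ".cif")
  write_structure(m, pdb)
  write_structure_cif(m, cif)
  m_pdb <- read_structure(pdb)
  m_cif <- read_structure(cif)
  expect_equal(nrow(m_pdb), nrow(m))
  expect_equal(nrow(m_cif), nrow(m))
  expect_lt(max(abs(coords(m_pdb) - coords(m))), 1e-3)
  expect_lt(max(abs(coords(m_cif) - coords(m_pdb))), 1e-3)
  expect_equal(m_cif$resid, m_pdb$resid)
})

test_that("empty or unreadable structures raise errors", {
  empty <- tempfile(fileext = ".pdb")
  writeLines(c("TITLE none", "END"), empty)
  expect_error(read_structure(empty))
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("selection grammar resolves ranges, keywords and chains", {
  m <- make_toy_channel()
  sel <- select(m, "resid 394-398 and heavy")
  expect_equal(sort(unique(m$chain[sel$indices])), c("A", "B", "C", "D"))
  expect_true(all(m$resid[sel$indices] %in% 394:398))
  ## order-stable and idempotent
  expect_identical(sel$indices, select(m, "resid 394-398 and heavy")$indices)
  expect_identical(sel$indices, sort(sel$indices))
  ## chain filter + union
  s2 <- select(m, "chain A and (resid 394 or resid 395)")
  expect_true(all(m$chain[s2$indices] == "A"))
  expect_equal(sort(unique(m$resid[s2$indices])), c(394, 395))
  ## degenerate range warns (and the empty result warns again)
  expect_warning(expect_warning(s3 <- select(m, "resid 10-5"), "matches no"),
                 "degenerate")
  expect_length(s3$indices, 0)
  ## unknown chain warns
  expect_warning(expect_warning(select(m, "chain Z"), "matches no"),
                 "not in model")
  ## syntax error names the position
  expect_error(select(m, "resid 394-398 and"), "unexpectedly")
  expect_error(select(m, "frobnicate"), "unknown selection token")
})

test_that("name/backbone selections exclude hydrogens and side chains", {
  h <- generate_kinked_helix(10)$model
  s <- select(h, "name CA and resid 3-6")
  expect_equal(length(s$indices), 4)
  expect_true(all(h$name[s$indices] == "CA"))
  bb <- select(h, "backbone")
  expect_equal(length(bb$indices), nrow(h))  # backbone-only fixture
})

test_that("pore frame anchors the gate at z = 0 and points to the filter", {
  m <- make_toy_channel()
  fr <- build_pore_frame(m, "resid 394-398 and heavy", "resid 358-361 and heavy")
  expect_equal(fr$axis, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr$origin[3], 0, tolerance = 1e-9)
  ## the filter centroid projects to positive z
  fsel <- fr$filter_selection$indices
  expect_gt(mean(project_to_frame(coords(m, fsel), fr)$z), 0)
})

test_that("pore frame is equivariant under rigid-body transforms", {
  m <- make_toy_channel()
  fr0 <- build_pore_frame(m)
  R <- porekinetics:::rotation_matrix(c(1, 1, 0), 0.8)
  shift <- c(5, -3, 7)
  m2 <- porekinetics:::set_coords(m, sweep(coords(m) %*% t(R), 2, shift, "+"))
  fr2 <- build_pore_frame(m2)
  expect_equal(fr2$axis, drop(R %*% fr0$axis), tolerance = 1e-9)
  expect_equal(fr2$origin, drop(R %*% fr0$origin) + shift, tolerance = 1e-9)
})

test_that("coincident gate and filter centroids are rejected", {
  m <- make_toy_channel()
  expect_error(build_pore_frame(m, "resid 394", "resid 394"), "degenerate")
})

test_that("GRO trajectories round-trip within format precision", {
  set.seed(4)
  frames <- lapply(1:3, function(i) matrix(runif(15, 0, 50), 5, 3))
  path <- write_gro_frames(frames)
  topo <- molecular_model(data.frame(
    name = "OW", resname = "SOL", resid = 1:5, chain = "W",
    x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
    element = "O"))
  traj <- read_trajectory(path, topo, frame_interval = 0.5)
  expect_equal(dim(traj$replicas[[1]]), c(3, 5, 3))
  for (i in 1:3)
    expect_lt(max(abs(traj$replicas[[1]][i, , ] - frames[[i]])), 0.006)
  expect_equal(traj$box[[1]][1, ], c(100, 100, 100))
})

test_that("atom-count mismatches between replicas are rejected", {
  frames <- list(matrix(runif(15, 0, 50), 5, 3))
  path <- write_gro_frames(frames)
  topo4 <- molecular_model(data.frame(
    name = "OW", resname = "SOL", resid = 1:4, chain = "W",
    x = 1:4, y = 1:4, z = 1:4, element = "O"))
  expect_error(read_trajectory(path, topo4), "atom-count mismatch")
})

test_that("ion-trace TSV dialect round-trips and validates its header", {
  sp <- langevin_spec(n_ions = 2, duration = 1, dt = 0.002, seed = 5)
  sim <- simulate_ion_langevin(sp, record_interval = 0.02)
  path <- tempfile(fileext = ".tsv")
  write_ion_traces(sim$traces, path)
  back <- read_ion_traces(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$z, sim$traces[[1]]$z, tolerance = 1e-6)
  expect_equal(back[[1]]$t, sim$traces[[1]]$t, tolerance = 1e-9)
  ## bad header is refused
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("time\tion\tx\ty\tz", "0\tA\t0\t0\t0"), bad)
  expect_error(read_ion_traces(bad), "header")
  ## read_trajectory dispatches TSV to trace reading
  expect_s3_class(read_trajectory(path), "ion_trace_set")
})
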