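## Shared fixture builders.  Everything is generated in code; no binary
## data ships with the tests.

## A tiny hand-written PDB (5 atoms, 2 residues, one with altlocs).
tiny_pdb_text <- function() {
  c("TITLE     tiny fixture",
    "ATOM      1  N   ALA A  10      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A  10      11.639   6.071  -5.147  1.00 10.00           C",
    "ATOM      3  C   ALA A  10      10.729   6.768  -4.123  1.00 10.00           C",
    "ATOM      4  CA ATYR A  11       9.580   7.451  -4.473  0.40 10.00           C",
    "ATOM      5  CA BTYR A  11       9.480   7.351  -4.373  0.60 10.00           C",
    "END")
}

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_text(), path)
  path
}

## Four-chain toy channel: gate rings (resid 394-398) and filter rings
## (resid 358-361) stacked along z, one chain per quadrant label.  Gate
## COM sits at z = 0 by construction; filter centroid at positive z.
make_toy_channel <- function() {
  ring <- function(resid, z, chain, r = 5, n = 6, name_prefix = "C") {
    th <- 2 * pi * (seq_len(n) - 1) / n + as.integer(charToRaw(chain)) / 50
    data.frame(name = sprintf("%s%02d", name_prefix, seq_len(n)),
               resname = "ALA", resid = resid, chain = chain,
               x = r * cos(th), y = r * sin(th), z = z,
               element = "C", stringsAsFactors = FALSE)
  }
  rows <- list()
  for (ch in c("A", "B", "C", "D")) {
    for (k in 0:4) rows[[length(rows) + 1]] <- ring(394 + k, -4 + 2 * k, ch)
    for (k in 0:3) rows[[length(rows) + 1]] <- ring(358 + k, 20 + 2 * k, ch, r = 3)
  }
  molecular_model(do.call(rbind, rows), title = "toy channel")
}

## Trajectory ensemble with one K ion moving along z through a periodic
## box, wrapped; topology = toy channel + the ion.
make_ion_trajectory <- function(z_path, box_z = 60) {
  chan <- make_toy_channel()
  ion <- data.frame(name = "K", resname = "K", resid = 1L, chain = "I",
                    x = 0.5, y = -0.3, z = z_path[1], element = "K",
                    stringsAsFactors = FALSE)
  topo <- molecular_model(rbind(as.data.frame(chan)[names(ion)], ion))
  n_fr <- length(z_path)
  n_at <- nrow(topo)
  arr <- array(rep(coords(topo), each = n_fr), c(n_fr, n_at, 3))
  zw <- ((z_path + box_z / 2) %% box_z) - box_z / 2   # wrapped into [-L/2, L/2)
  arr[, n_at, 3] <- zw
  structure(list(replicas = list(arr),
                 box = list(matrix(box_z, n_fr, 3)),
                 frame_interval = 0.1, topology = topo),
            class = "trajectory_ensemble")
}

## Hand-built ion trace (pore-frame coordinates) for the event machine.
make_trace <- function(z, t = seq_along(z), id = "K001", r_offset = 0) {
  tr <- data.frame(t = t, z = z, r_offset = r_offset)
  attr(tr, "ion_id") <- id
  structure(list(tr), class = "ion_trace_set")
}

## Brute-force rigid-superposition RMSD: exhaustive quaternion grid plus a
## local Nelder-Mead polish on the axis-angle parameters.  Independent of
## the SVD route used by superpose_kabsch.
rmsd_bruteforce <- function(P, Q, n_grid = 24) {
  rot_from_aa <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    a <- v / th
    K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(v) {
    R <- rot_from_aa(v)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- Inf; best_v <- c(0, 0, 0)
  ## grid over axis directions x angles
  for (i in seq_len(n_grid)) {
    u <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
    nu <- sqrt(sum(u^2)); if (nu < 1e-6) next
    for (th in seq(0, pi, length.out = n_grid)) {
      v <- u / nu * th
      f <- obj(v)
      if (f < best) { best <- f; best_v <- v }
    }
  }
  op <- optim(best_v, obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-14))
  op$value
}

## Multi-frame GRO writer (nm) for trajectory round-trip tests.
write_gro_frames <- function(coords_list, path = tempfile(fileext = ".gro"),
                             box = c(10, 10, 10)) {
  lines <- character()
  for (fr in coords_list) {
    nm <- fr / 10
    lines <- c(lines, "frame", sprintf("%5d", nrow(fr)),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       seq_len(nrow(fr)), "SOL", "OW", seq_len(nrow(fr)),
                       nm[, 1], nm[, 2], nm[, 3]),
               sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  }
  writeLines(lines, path)
  path
}
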