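#' Ring-pore specification
#'
#' Describes a pseudo-atom pore built from stacked rings of spheres, used
#' as a profiler fixture with an analytically known inscribed-sphere
#' radius profile.
#'
#' @param z_planes Strictly increasing ring plane positions, Angstrom.
#' @param ring_radius Ring radius at each plane (recycled), Angstrom; must
#'   exceed `atom_radius`.
#' @param atoms_per_ring Atoms per ring, at least 12 (sparser rings make
#'   the dense-ring radius formula unreliable).
#' @param atom_radius Sphere radius of each pseudo-atom, Angstrom.
#' @param element Element symbol for the pseudo-atoms.
#' @return A `ring_pore_spec` list.
#' @export
ring_pore_spec <- function(z_planes, ring_radius, atoms_per_ring = 24,
                           atom_radius = 1.5, element = "C") {
  z_planes <- as.numeric(z_planes)
  ring_radius <- rep_len(as.numeric(ring_radius), length(z_planes))
  if (length(z_planes) > 1 && any(diff(z_planes) <= 0))
    stop("z_planes must be strictly increasing")
  if (any(ring_radius <= atom_radius))
    stop("ring_radius must exceed atom_radius everywhere")
  if (atoms_per_ring < 12)
    stop("atoms_per_ring must be >= 12 for a dense ring")
  structure(list(z_planes = z_planes, ring_radius = ring_radius,
                 atoms_per_ring = as.integer(atoms_per_ring),
                 atom_radius = atom_radius, element = element),
            class = "ring_pore_spec")
}

#' Generate a ring-built pseudo-atom pore
#'
#' Places `atoms_per_ring` spheres uniformly on each ring (rings staggered
#' by half an atom spacing).  Because every atom of a ring lies at distance
#' `sqrt(R_k^2 + (z - z_k)^2)` from any axial point `(0, 0, z)`, the
#' inscribed radius with the centre constrained to the axis is exactly
#'
#'   `r(z) = min_k sqrt(R_k^2 + (z - z_k)^2) - atom_radius`,
#'
#' which the returned `analytic_profile` function evaluates.  At a ring
#' plane this reduces to `R_k - atom_radius`.
#'
#' @param spec A [ring_pore_spec()].
#' @param resid_base Residue number given to the first ring (rings number
#'   consecutively; useful for labelling a ring as a gate residue).
#' @return List with `model` (a [molecular_model()]) and
#'   `analytic_profile` (function of z, Angstrom).
#' @export
generate_ring_pore <- function(spec, resid_base = 1L) {
  stopifnot(inherits(spec, "ring_pore_spec"))
  n <- spec$atoms_per_ring
  rows <- list()
  for (k in seq_along(spec$z_planes)) {
    th <- 2 * pi * (seq_len(n) - 1) / n + (k %% 2) * pi / n
    rows[[k]] <- data.frame(
      name = sprintf("C%02d", seq_len(n)),
      resname = "RNG", resid = resid_base + k - 1L, chain = "A",
      x = spec$ring_radius[k] * cos(th),
      y = spec$ring_radius[k] * sin(th),
      z = spec$z_planes[k],
      element = spec$element, stringsAsFactors = FALSE)
  }
  model <- molecular_model(do.call(rbind, rows), title = "ring pore fixture")
  model$vdw_radius <- spec$atom_radius  # ground-truth radius, not a set lookup
  zs <- spec$z_planes; Rs <- spec$ring_radius; ar <- spec$atom_radius
  analytic <- function(z) {
    vapply(z, function(zz) min(sqrt(Rs^2 + (zz - zs)^2)) - ar, numeric(1))
  }
  list(model = model, analytic_profile = analytic)
}

#' Langevin ion-trace specification
#'
#' Parameters of the overdamped Brownian-dynamics generator that emulates
#' cations drifting through a membrane span under a constant applied
#' field.  Defaults mirror an applied-field permeation study design:
#' -500 mV across a ~36 Angstrom span, 500 ns duration, 298 K, bulk
#' potassium diffusion coefficient 196 Angstrom^2/ns (a documented
#' stand-in, not a fitted value).
#'
#' The integrator requires `dt <= 0.01 * span_width^2 / diffusion_D`.
#'
#' @param n_ions Number of independent ions.
#' @param duration Simulated time, ns.
#' @param dt Integration step, ns.
#' @param diffusion_D Diffusion coefficient, Angstrom^2/ns.
#' @param voltage Applied voltage, mV (signed; negative drives a +1 ion
#'   toward -z, the intracellular side).
#' @param membrane_span `c(z_lo, z_hi)` of the field region, Angstrom.
#' @param pmf_shape Optional data frame `z`, `u` (kcal/mol) defining a
#'   piecewise-linear potential; `NULL` for a flat landscape.
#' @param domain_length Periodic z-domain length, Angstrom; must exceed the
#'   span width.
#' @param temperature Kelvin.
#' @param seed Integer RNG seed.
#' @return A `langevin_spec` list.
#' @export
langevin_spec <- function(n_ions = 8, duration = 500, dt = 0.002,
                          diffusion_D = 196, voltage = -500,
                          membrane_span = c(-18, 18), pmf_shape = NULL,
                          domain_length = 140, temperature = 298, seed = 1) {
  span_w <- diff(membrane_span)
  if (span_w <= 0) stop("membrane_span must be ordered (z_lo < z_hi)")
  if (domain_length <= span_w) stop("domain_length must exceed the membrane span")
  dt_max <- 0.01 * span_w^2 / diffusion_D
  if (dt > dt_max) {
    stop(sprintf("dt = %g ns violates stability; use dt <= %.4g ns", dt, dt_max))
  }
  structure(list(n_ions = as.integer(n_ions), duration = duration, dt = dt,
                 diffusion_D = diffusion_D, voltage = voltage,
                 membrane_span = membrane_span, pmf_shape = pmf_shape,
                 domain_length = domain_length, temperature = temperature,
                 seed = as.integer(seed)),
            class = "langevin_spec")
}

#' Simulate ion traces by overdamped Langevin dynamics
#'
#' One-dimensional Brownian dynamics
#' `z <- z + (D F(z)/kT) dt + sqrt(2 D dt) N(0,1)` on a periodic z-domain.
#' `F(z)` is the applied-field force `qV/span` inside the membrane span
#' (zero outside) minus the gradient of the optional piecewise-linear
#' potential.  Unwrapped coordinates are retained so permeation events can
#' be counted without aliasing; x and y carry small Gaussian jitter for
#' radial-offset checks.
#'
#' For a flat landscape the expected net crossings per ion equal
#' (drift velocity averaged over the domain) x duration / domain_length,
#' with in-span drift `D q V / (kT span)`; this drift-based expectation is
#' returned alongside the traces (signed; negative = inward).
#'
#' @param spec A [langevin_spec()].
#' @param record_interval Time between stored samples, ns.
#' @return List with `traces` (an `ion_trace_set` of unwrapped z),
#'   `expected_crossings_per_ion` (signed), `spec`, and `wrapped` z
#'   matrix.
#' @export
simulate_ion_langevin <- function(spec, record_interval = 0.02) {
  stopifnot(inherits(spec, "langevin_spec"))
  kT <- kT_kcal(spec$temperature)
  span <- spec$membrane_span
  span_w <- diff(span)
  f_field <- voltage_energy_kcal(spec$voltage) / span_w  # kcal/mol/Angstrom
  L <- spec$domain_length
  zc <- mean(span)
  domain_lo <- zc - L / 2
  every <- max(1L, round(record_interval / spec$dt))
  n_steps <- round(spec$duration / spec$dt)
  if (is.null(spec$pmf_shape)) {
    u_z <- numeric(0); u_v <- numeric(0)
  } else {
    u_z <- spec$pmf_shape$z; u_v <- spec$pmf_shape$u
  }
  set.seed(spec$seed)
  z0 <- runif(spec$n_ions, domain_lo, domain_lo + L)
  zmat <- langevin_z_cpp(z0, n_steps, spec$dt, spec$diffusion_D, kT,
                         f_field, span[1], span[2], u_z, u_v,
                         domain_lo, L, every)
  t <- seq(0, by = spec$dt * every, length.out = nrow(zmat))
  traces <- lapply(seq_len(spec$n_ions), function(i) {
    tr <- data.frame(t = t,
                     x = rnorm(length(t), sd = 0.5),
                     y = rnorm(length(t), sd = 0.5),
                     z = zmat[, i])
    attr(tr, "ion_id") <- sprintf("K%03d", i)
    tr
  })
  wrapped <- (zmat - domain_lo) %% L + domain_lo
  drift_in_span <- spec$diffusion_D * f_field / kT        # Angstrom/ns
  mean_drift <- drift_in_span * span_w / L                # averaged over domain
  expected <- mean_drift * spec$duration / L
  list(traces = structure(traces, class = "ion_trace_set"),
       expected_crossings_per_ion = expected,
       spec = spec, wrapped = wrapped)
}

#' Generate a kinked, partially unwound ideal helix
#'
#' Builds an ideal alpha-helix backbone (N, CA, C, O; phi = -57, psi = -47,
#' omega = 180, standard bond geometry, 1.5 Angstrom rise and 100
#' degrees/residue twist) with residues after `kink_after` rigidly rotated
#' by `bend_deg` about an axis perpendicular to the pre-kink helix axis
#' through CA(`kink_after`), and the final `unwound_tail` residues built in
#' an extended conformation (phi = -120, psi = 130).
#'
#' @param n_res Number of residues.
#' @param kink_after Residue index after which the bend is applied
#'   (0 or `NULL` for no kink).
#' @param bend_deg Bend angle in degrees, 0..90.
#' @param unwound_tail Number of C-terminal residues in extended
#'   conformation (0 <= tail < n_res).
#' @return List with `model`, `bend_deg`, `kink_after`, `unwound_tail`,
#'   and `segments` (pre/post residue ranges suitable for
#'   [helix_axes_and_bend()]).
#' @export
generate_kinked_helix <- function(n_res, kink_after = 0, bend_deg = 0,
                                  unwound_tail = 0) {
  stopifnot(n_res >= 8, unwound_tail >= 0, unwound_tail < n_res,
            bend_deg >= 0, bend_deg <= 90)
  n_hel <- n_res - unwound_tail
  phi <- c(rep(-57, n_hel), rep(-120, unwound_tail))
  psi <- c(rep(-47, n_hel), rep(130, unwound_tail))
  model <- build_backbone(phi, psi)
  if (!is.null(kink_after) && kink_after > 0 && bend_deg > 0) {
    stopifnot(kink_after > 2, kink_after < n_res - 1)
    xyz <- coords(model)
    ca_idx <- which(model$name == "CA")
    pivot <- xyz[ca_idx[kink_after], ]
    pre_axis <- helix_pca_axis(xyz[ca_idx[1:kink_after], , drop = FALSE])
    perp <- c(-pre_axis[2], pre_axis[1], 0)
    if (sqrt(sum(perp^2)) < 1e-6) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    R <- rotation_matrix(perp, bend_deg * pi / 180)
    move <- which(model$resid > kink_after |
                  (model$resid == kink_after & model$name %in% c("C", "O")))
    xyz[move, ] <- sweep(sweep(xyz[move, , drop = FALSE], 2, pivot) %*% t(R),
                         2, pivot, "+")
    model <- set_coords(model, xyz)
  }
  pre <- c(1, max(1, (if (kink_after > 0) kink_after else n_hel) - 1))
  post_start <- if (kink_after > 0) kink_after + 2 else pre[2] + 1
  list(model = model, bend_deg = bend_deg, kink_after = kink_after,
       unwound_tail = unwound_tail,
       segments = list(pre = pre, post = c(post_start, n_hel)))
}

## Backbone construction by natural-extension (NeRF) placement with
## standard bond lengths/angles: N-CA 1.458, CA-C 1.525, C-N 1.329,
## C=O 1.231 Angstrom; angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7,
## CA-C-O 120.8 degrees; omega fixed at 180.
build_backbone <- function(phi, psi) {
  n_res <- length(phi)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8
  pos <- matrix(NA_real_, 3 * n_res, 3)  # N, CA, C per residue
  pos[1, ] <- c(0, 0, 0)
  pos[2, ] <- c(b_NCA, 0, 0)
  pos[3, ] <- pos[2, ] + b_CAC * c(cos(pi * (180 - a_NCAC) / 180),
                                   sin(pi * (180 - a_NCAC) / 180), 0)
  for (i in 2:n_res) {
    r <- 3 * (i - 1)
    pos[r + 1, ] <- place_atom(pos[r - 2, ], pos[r - 1, ], pos[r, ],
                               b_CN, a_CACN, psi[i - 1])
    pos[r + 2, ] <- place_atom(pos[r - 1, ], pos[r, ], pos[r + 1, ],
                               b_NCA, a_CNCA, 180)
    pos[r + 3, ] <- place_atom(pos[r, ], pos[r + 1, ], pos[r + 2, ],
                               b_CAC, a_NCAC, phi[i])
  }
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    r <- 3 * (i - 1)
    o_ref <- if (i < n_res) pos[r + 4, ] else
      place_atom(pos[r + 1, ], pos[r + 2, ], pos[r + 3, ], b_CN, a_CACN, psi[i])
    o <- place_o(pos[r + 2, ], pos[r + 3, ], o_ref, b_CO, a_CACO)
    rows[[i]] <- data.frame(
      name = c("N", "CA", "C", "O"), resname = "ALA", resid = i, chain = "A",
      x = c(pos[r + 1, 1], pos[r + 2, 1], pos[r + 3, 1], o[1]),
      y = c(pos[r + 1, 2], pos[r + 2, 2], pos[r + 3, 2], o[2]),
      z = c(pos[r + 1, 3], pos[r + 2, 3], pos[r + 3, 3], o[3]),
      element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
  }
  molecular_model(do.call(rbind, rows), title = "ideal helix")
}

## NeRF: place D given A-B-C, bond |CD|, angle B-C-D (deg), dihedral
## A-B-C-D (deg).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), -sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Carbonyl O: in the CA-C-Nnext plane, opposite Nnext.
place_o <- function(ca, c, n_next, bond, angle) {
  place_atom(n_next, ca, c, bond, angle, 180)
}

## Helix axis from CA coordinates.  For a regular helix the axial rise is
## linear in the residue index, so second differences of the CA positions
## p[i+2] - 2 p[i+1] + p[i] lie exactly in the plane perpendicular to the
## axis; the axis is the direction of least variance of those vectors.
## This is insensitive to partial turns, which bias a raw PCA of the CA
## cloud by several degrees.  Falls back to PCA when the second
## differences are (near-)collinear, e.g. for extended chains.  Oriented
## N-terminus to C-terminus.
helix_pca_axis <- function(ca_xyz) {
  n <- nrow(ca_xyz)
  ax <- NULL
  if (n >= 5) {
    s <- diff(ca_xyz, differences = 2)
    ev <- eigen(crossprod(s), symmetric = TRUE)
    ## need the perpendicular plane to be properly spanned
    if (ev$values[2] > 1e-6 * ev$values[1]) ax <- ev$vectors[, 3]
  }
  if (is.null(ax)) ax <- prcomp(ca_xyz, center = TRUE)$rotation[, 1]
  ax <- ax / sqrt(sum(ax^2))
  if (sum(ax * (ca_xyz[n, ] - ca_xyz[1, ])) < 0) ax <- -ax
  ax
}

rotation_matrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate a solvation snapshot with known water counts
#'
#' Places one potassium ion on the pore axis, exactly `n_first_shell`
#' water oxygens on a sphere of radius `shell_radius` around it
#' (deterministic Fibonacci placement - no clashes), the remaining
#' `n_waters_in_cylinder - n_first_shell` waters inside the axial cylinder
#' but outside the first shell, and `n_decoys` waters outside the
#' cylinder.
#'
#' @param n_waters_in_cylinder Total waters inside the cylinder (including
#'   the first shell).
#' @param cylinder_radius Axial cylinder radius, Angstrom (12 by default,
#'   the usual pore-hydration cutoff).
#' @param n_first_shell Waters on the coordination shell.
#' @param shell_radius First-shell radius, Angstrom (2.8 typical for K-O).
#' @param n_decoys Waters placed outside the cylinder.
#' @param ion_z Axial position of the ion.
#' @param z_half_range Waters are placed within `ion_z +- z_half_range`.
#' @param seed RNG seed.
#' @return List with `model` and the ground-truth counts.
#' @export
generate_solvation_snapshot <- function(n_waters_in_cylinder, cylinder_radius = 12,
                                        n_first_shell = 6, shell_radius = 2.8,
                                        n_decoys = 10, ion_z = 0,
                                        z_half_range = 15, seed = 1) {
  if (shell_radius >= cylinder_radius)
    stop("shell_radius must be smaller than cylinder_radius")
  if (n_first_shell > n_waters_in_cylinder)
    stop("n_first_shell cannot exceed n_waters_in_cylinder")
  n_bulk <- n_waters_in_cylinder - n_first_shell
  avail_vol <- pi * cylinder_radius^2 * 2 * z_half_range
  if (n_bulk > avail_vol / 8)
    stop("infeasible packing: too many waters for the cylinder volume")
  set.seed(seed)
  rows <- list()
  rows[[1]] <- data.frame(name = "K", resname = "K", resid = 1L, chain = "I",
                          x = 0, y = 0, z = ion_z, element = "K",
                          stringsAsFactors = FALSE)
  rid <- 2L
  if (n_first_shell > 0) {
    ga <- pi * (3 - sqrt(5))
    k <- seq_len(n_first_shell)
    zz <- 1 - 2 * (k - 0.5) / n_first_shell
    rr <- sqrt(pmax(0, 1 - zz^2))
    for (j in k) {
      rows[[length(rows) + 1]] <- water_row(rid,
        shell_radius * rr[j] * cos(ga * j),
        shell_radius * rr[j] * sin(ga * j),
        ion_z + shell_radius * zz[j])
      rid <- rid + 1L
    }
  }
  place_in <- function(n, ok_fun) {
    placed <- 0
    while (placed < n) {
      x <- runif(1, -cylinder_radius, cylinder_radius)
      y <- runif(1, -cylinder_radius, cylinder_radius)
      z <- runif(1, ion_z - z_half_range, ion_z + z_half_range)
      if (!ok_fun(x, y, z)) next
      rows[[length(rows) + 1]] <<- water_row(rid, x, y, z)
      rid <<- rid + 1L
      placed <- placed + 1
    }
  }
  min_sep <- max(shell_radius + 0.8, 4.0)  # keep bulk waters out of the shell
  place_in(n_bulk, function(x, y, z) {
    sqrt(x^2 + y^2) <= cylinder_radius - 0.1 &&
      sqrt(x^2 + y^2 + (z - ion_z)^2) > min_sep
  })
  placed <- 0
  while (placed < n_decoys) {
    th <- runif(1, 0, 2 * pi)
    rr <- runif(1, cylinder_radius + 0.5, cylinder_radius + 6)
    z <- runif(1, ion_z - z_half_range, ion_z + z_half_range)
    rows[[length(rows) + 1]] <- water_row(rid, rr * cos(th), rr * sin(th), z)
    rid <- rid + 1L
    placed <- placed + 1
  }
  model <- molecular_model(do.call(rbind, rows), title = "solvation snapshot")
  list(model = model, n_in_cylinder = n_waters_in_cylinder,
       n_first_shell = n_first_shell, n_decoys = n_decoys, ion_z = ion_z)
}

water_row <- function(resid, x, y, z) {
  data.frame(name = "O", resname = "HOH", resid = resid, chain = "W",
             x = x, y = y, z = z, element = "O", stringsAsFactors = FALSE)
}

#' Generate Boltzmann-shaped activation-curve data
#'
#' `G/Gmax = 1 / (1 + exp((V - v_half)/k))` plus Gaussian noise, clipped
#' to [-0.05, 1.05].
#'
#' @param v_half Half-activation voltage, mV.
#' @param slope_k Slope factor, mV (> 0).
#' @param voltages Voltage grid, mV (default -20 to -110 in 10 mV
#'   decrements, the standard tail-current protocol).
#' @param noise_sd Gaussian noise SD (fraction of Gmax).
#' @param n_sweeps Recorded sweeps (metadata only).
#' @param seed RNG seed.
#' @return A `gv_curve`: data frame `voltage`, `g_norm` with attributes
#'   `v_half`, `slope_k`, `n_sweeps`.
#' @export
generate_gv_data <- function(v_half, slope_k, voltages = seq(-20, -110, by = -10),
                             noise_sd = 0, n_sweeps = 1, seed = 1) {
  stopifnot(slope_k > 0)
  set.seed(seed)
  g <- 1 / (1 + exp((voltages - v_half) / slope_k))
  if (noise_sd > 0) g <- g + rnorm(length(g), sd = noise_sd)
  g <- pmin(1.05, pmax(-0.05, g))
  structure(data.frame(voltage = voltages, g_norm = g),
            class = c("gv_curve", "data.frame"),
            v_half = v_half, slope_k = slope_k, n_sweeps = n_sweeps)
}
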