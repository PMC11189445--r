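#' Axial ion density from traces
#'
#' Counts in-cylinder ion samples per z-bin, normalized by bin volume and
#' by the total number of in-cylinder samples.  Bins with zero counts are
#' masked (NA), never imputed.
#'
#' @param traces An `ion_trace_set` (pore frame).
#' @param z_breaks Uniform bin edges, Angstrom.
#' @param radial_cutoff Samples with `r_offset` beyond this are ignored,
#'   Angstrom (Inf keeps everything, e.g. for 1-D generators).
#' @return An `ion_density`: data frame `z_mid`, `count`, `density` with
#'   attribute `radial_cutoff`.
#' @export
ion_density_profile <- function(traces, z_breaks, radial_cutoff = 12) {
  dz <- diff(z_breaks)
  if (any(abs(dz - dz[1]) > 1e-9)) stop("z_breaks must be uniform")
  zs <- unlist(lapply(traces, `[[`, "z"))
  ro <- unlist(lapply(traces, function(tr) {
    if (is.null(tr$r_offset)) rep(0, nrow(tr)) else tr$r_offset
  }))
  keep <- ro <= radial_cutoff & zs >= z_breaks[1] & zs <= z_breaks[length(z_breaks)]
  if (!any(keep)) {
    warning("no in-cylinder samples; density fully masked")
    cnt <- rep(0L, length(z_breaks) - 1)
  } else {
    cnt <- as.integer(table(cut(zs[keep], z_breaks, include.lowest = TRUE)))
  }
  vol <- pi * min(radial_cutoff, .Machine$double.xmax)^2 * dz[1]
  if (!is.finite(vol)) vol <- dz[1]
  dens <- ifelse(cnt > 0, cnt / (sum(cnt) * vol), NA_real_)
  structure(data.frame(z_mid = head(z_breaks, -1) + dz[1] / 2,
                       count = cnt, density = dens),
            class = c("ion_density", "data.frame"),
            radial_cutoff = radial_cutoff)
}

#' Free-energy profile by Boltzmann inversion
#'
#' `F(z) = -kT ln(rho(z) / rho_ref)` with the reference density averaged
#' over the unmasked bins of `reference_window`; F is shifted so its mean
#' over the reference window is zero.  Because the reference cancels any
#' multiplicative constant, `pmf_from_density(c * density)` equals
#' `pmf_from_density(density)` for any c > 0.  An optional linear
#' correction subtracts the applied-field ramp `qV (z - z_ref)/span`
#' before referencing (a field-tilted inversion is not an equilibrium
#' free energy; the default applies no correction, matching the common
#' direct inversion of applied-field data).
#'
#' @param density An [ion_density_profile()] result (or data frame with
#'   `z_mid` and `density`).
#' @param kT Thermal energy, kcal/mol (default 298 K).
#' @param reference_window `c(z_lo, z_hi)` defining the F = 0 region.
#' @param tilt_correction `"none"` or `"linear"`.
#' @param voltage,span Voltage (mV) and membrane span (Angstrom) for the
#'   linear correction.
#' @return A `free_energy_profile`: data frame `z_mid`, `F` (kcal/mol,
#'   NA where unsampled) with attributes `kT`, `reference_window`,
#'   `tilt_corrected`.
#' @export
pmf_from_density <- function(density, kT = kT_kcal(298), reference_window,
                             tilt_correction = c("none", "linear"),
                             voltage = NULL, span = NULL) {
  tilt_correction <- match.arg(tilt_correction)
  rho <- density$density
  z <- density$z_mid
  if (all(is.na(rho))) stop("density is fully masked; cannot invert")
  FF <- -kT * log(rho)
  if (tilt_correction == "linear") {
    if (is.null(voltage) || is.null(span))
      stop("linear tilt correction needs voltage and span")
    z_ref <- mean(reference_window)
    FF <- FF - voltage_energy_kcal(voltage) * (z - z_ref) / span
  }
  ref <- which(z >= reference_window[1] & z <= reference_window[2] & !is.na(FF))
  if (!length(ref)) stop("reference window contains no sampled bins")
  FF <- FF - mean(FF[ref])
  structure(data.frame(z_mid = z, F = FF),
            class = c("free_energy_profile", "data.frame"),
            kT = kT, reference_window = reference_window,
            tilt_corrected = tilt_correction == "linear")
}

#' @export
plot.free_energy_profile <- function(x, ...) {
  graphics::plot(x$z_mid, x$F, type = "l", xlab = "z (A)",
                 ylab = "F (kcal/mol)", ...)
  invisible(x)
}

#' Draw axial positions from a Boltzmann distribution
#'
#' Random-walk Metropolis sampling of `exp(-U(z)/kT)` on a bounded
#' interval with reflecting boundaries; `U` is a piecewise-linear table.
#' Serves as an independent ground-truth sampler for validating
#' [pmf_from_density()].
#'
#' @param u_table Data frame `z`, `u` (kcal/mol).
#' @param n_samples Number of retained samples.
#' @param kT Thermal energy, kcal/mol.
#' @param z_range Sampling interval (defaults to the table range).
#' @param step_sd Proposal SD, Angstrom.
#' @param burn_in,thin Chain controls.
#' @param seed RNG seed.
#' @return An `ion_trace_set` with one trace of the sampled z.
#' @export
sample_boltzmann_z <- function(u_table, n_samples, kT = kT_kcal(298),
                               z_range = range(u_table$z), step_sd = 2,
                               burn_in = 1000, thin = 1, seed = 1) {
  set.seed(seed)
  z <- metropolis_z_cpp(n_samples, burn_in, thin, step_sd,
                        z_range[1], z_range[2],
                        u_table$z, u_table$u, kT, mean(z_range))
  tr <- data.frame(t = seq_along(z), z = z, r_offset = 0)
  attr(tr, "ion_id") <- "mcmc"
  structure(list(tr), class = "ion_trace_set")
}

#' Mean water count along the pore axis
#'
#' Counts water oxygens (residue names HOH/WAT/TIP3/SOL/SPC...) inside an
#' axial cylinder per z-bin, averaged over frames.  Bins with a mean
#' count below 1 are flagged dry, expressing transient wetting/dewetting.
#'
#' @param frames A [molecular_model()] or list of models (snapshots).
#' @param frame A `pore_frame`.
#' @param cylinder_radius Cylinder radius, Angstrom (default 12).
#' @param z_breaks Bin edges, Angstrom.
#' @return A `hydration_profile`: data frame `z_mid`, `mean_waters`,
#'   `wet` with attribute `cylinder_radius`.
#' @export
hydration_profile <- function(frames, frame, cylinder_radius = 12,
                              z_breaks = seq(-20, 20, by = 2)) {
  if (inherits(frames, "molecular_model")) frames <- list(frames)
  n_bins <- length(z_breaks) - 1
  counts <- matrix(0, length(frames), n_bins)
  any_water <- FALSE
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    wo <- which(is_water(m) & toupper(m$element) == "O")
    if (!length(wo)) next
    any_water <- TRUE
    pr <- project_to_frame(coords(m, wo), frame)
    keep <- pr$r_offset <= cylinder_radius &
      pr$z >= z_breaks[1] & pr$z <= z_breaks[n_bins + 1]
    if (any(keep)) {
      counts[f, ] <- as.integer(table(cut(pr$z[keep], z_breaks,
                                          include.lowest = TRUE)))
    }
  }
  if (!any_water) warning("no water molecules found in any frame")
  mw <- colMeans(counts)
  structure(data.frame(z_mid = head(z_breaks, -1) + diff(z_breaks) / 2,
                       mean_waters = mw, wet = mw >= 1),
            class = c("hydration_profile", "data.frame"),
            cylinder_radius = cylinder_radius)
}

#' First-shell water coordination of an ion
#'
#' Counts water oxygens within `shell_cutoff` of each selected ion per
#' frame (3.5 Angstrom default, near the first K-O RDF minimum), and
#' aggregates the mean count versus the ion's axial position.
#'
#' @param frames A model or list of models.
#' @param frame A `pore_frame` (for the axial coordinate; may be `NULL`).
#' @param ion_expr Selection expression for the ion(s).
#' @param shell_cutoff Shell radius, Angstrom.
#' @param z_breaks Bin edges for the axial aggregation.
#' @return List with `per_frame` (data frame `frame`, `ion_id`, `z`,
#'   `n_waters`) and `by_z` (data frame `z_mid`, `mean_coordination`).
#' @export
coordination_number <- function(frames, frame = NULL, ion_expr = "elem K",
                                shell_cutoff = 3.5,
                                z_breaks = seq(-20, 20, by = 2)) {
  if (inherits(frames, "molecular_model")) frames <- list(frames)
  rows <- list()
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    ions <- suppressWarnings(select(m, ion_expr)$indices)
    if (!length(ions)) next
    wo <- which(is_water(m) & toupper(m$element) == "O")
    wxyz <- coords(m, wo)
    for (ai in ions) {
      p <- coords(m, ai)
      nw <- if (length(wo)) sum(sqrt(colSums((t(wxyz) - drop(p))^2)) <= shell_cutoff)
            else 0L
      zval <- if (is.null(frame)) p[3] else project_to_frame(p, frame)$z
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, ion_id = sprintf("%s%d", m$chain[ai], m$resid[ai]),
        z = zval, n_waters = nw, stringsAsFactors = FALSE)
    }
  }
  per_frame <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), ion_id = character(), z = numeric(),
               n_waters = integer())
  bin <- cut(per_frame$z, z_breaks, include.lowest = TRUE)
  by_z <- data.frame(z_mid = head(z_breaks, -1) + diff(z_breaks) / 2,
                     mean_coordination = as.numeric(
                       tapply(per_frame$n_waters, bin, mean)[levels(bin)]))
  list(per_frame = per_frame, by_z = by_z)
}

#' Waters lost at a site relative to bulk
#'
#' Convenience difference of mean coordination between a bulk window and
#' a site window along z.
#'
#' @param coord A [coordination_number()] result.
#' @param bulk_window,site_window `c(z_lo, z_hi)` windows, Angstrom.
#' @return Named list `bulk_mean`, `site_mean`, `waters_lost`.
#' @export
waters_lost <- function(coord, bulk_window, site_window) {
  pf <- coord$per_frame
  bm <- mean(pf$n_waters[pf$z >= bulk_window[1] & pf$z <= bulk_window[2]])
  sm <- mean(pf$n_waters[pf$z >= site_window[1] & pf$z <= site_window[2]])
  list(bulk_mean = bm, site_mean = sm, waters_lost = bm - sm)
}

#' Geometric hydrogen-bond statistics per group
#'
#' A hydrogen bond exists when the donor-acceptor heavy-atom distance is
#' at most `d_cutoff` and, when the donor hydrogen is present, the
#' D-H...A angle is at least `angle_cutoff`.  Hydrogens are located as
#' H atoms of the donor's residue within 1.25 Angstrom of the donor heavy
#' atom.  When a donor has no resolvable hydrogen the distance criterion
#' alone is applied, with a warning (cryo-EM models lack hydrogens).
#'
#' Each bond is credited to both partner groups, so four hydroxyls in a
#' ring each donating to the next average 2.0 bonds per group (1 donated
#' + 1 accepted).
#'
#' @param frames A model or list of models.
#' @param donor_groups Named list of selection expressions; selected heavy
#'   atoms act as donors.
#' @param acceptor_groups Named list of selection expressions; selected
#'   heavy atoms act as acceptors.
#' @param d_cutoff Heavy-atom distance cutoff, Angstrom (default 3.5).
#' @param angle_cutoff D-H...A angle cutoff, degrees (default 150).
#' @return Data frame `group`, `mean_hbonds` (bonds per frame credited to
#'   the group).
#' @export
hbond_stats <- function(frames, donor_groups, acceptor_groups,
                        d_cutoff = 3.5, angle_cutoff = 150) {
  if (inherits(frames, "molecular_model")) frames <- list(frames)
  groups <- union(names(donor_groups), names(acceptor_groups))
  tot <- setNames(numeric(length(groups)), groups)
  warned <- FALSE
  for (m in frames) {
    don <- lapply(donor_groups, function(e) suppressWarnings(select(m, e)$indices))
    acc <- lapply(acceptor_groups, function(e) suppressWarnings(select(m, e)$indices))
    hyd <- which(toupper(m$element) == "H")
    xyz <- coords(m)
    for (gd in names(don)) for (di in don[[gd]]) {
      ## donor hydrogens: same residue, within covalent range
      dh <- hyd[m$chain[hyd] == m$chain[di] & m$resid[hyd] == m$resid[di]]
      if (length(dh)) {
        dh <- dh[sqrt(rowSums((xyz[dh, , drop = FALSE] -
                               matrix(xyz[di, ], length(dh), 3, byrow = TRUE))^2)) <= 1.25]
      }
      for (ga in names(acc)) for (ai in acc[[ga]]) {
        if (ai == di) next
        dda <- sqrt(sum((xyz[di, ] - xyz[ai, ])^2))
        if (dda > d_cutoff) next
        ok <- if (length(dh)) {
          any(vapply(dh, function(h) {
            v1 <- xyz[di, ] - xyz[h, ]; v2 <- xyz[ai, ] - xyz[h, ]
            ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
            ang >= angle_cutoff
          }, logical(1)))
        } else {
          if (!warned) {
            warning("donor without hydrogen: using distance-only criterion")
            warned <- TRUE
          }
          TRUE
        }
        if (ok) {
          tot[gd] <- tot[gd] + 1  # credited to the donor's group
          tot[ga] <- tot[ga] + 1  # and to the acceptor's group
        }
      }
    }
  }
  data.frame(group = groups, mean_hbonds = as.numeric(tot[groups]) / length(frames),
             stringsAsFactors = FALSE)
}
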