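#' Van der Waals radius sets for pore profiling
#'
#' `radius_set("simple")` is the classic simple set used for
#' inscribed-sphere pore profiling (C 1.85, N 1.75, O 1.65, S 2.00,
#' P 2.10, H 1.00 Angstrom).  `radius_set("amber")` is an
#' Amber-force-field-flavoured alternative (Rmin/2 values: C 1.908,
#' N 1.824, O 1.661, S 2.00, P 2.10, H 0.60).  Per-atom-name overrides
#' take precedence over elements.  The set name is recorded in profile
#' metadata so the convention is always visible in output.
#'
#' @param name `"simple"` or `"amber"`.
#' @param by_atom_name Optional named vector of per-atom-name overrides
#'   (Angstrom).
#' @return A `radius_set` list with `by_element`, `by_atom_name`, `name`.
#' @export
radius_set <- function(name = c("simple", "amber"), by_atom_name = NULL) {
  name <- match.arg(name)
  by_element <- switch(name,
    simple = c(C = 1.85, N = 1.75, O = 1.65, S = 2.00, P = 2.10, H = 1.00),
    amber  = c(C = 1.908, N = 1.824, O = 1.661, S = 2.00, P = 2.10, H = 0.60))
  stopifnot(all(by_element > 0.2 & by_element < 3.0))
  if (!is.null(by_atom_name))
    stopifnot(all(by_atom_name > 0.2 & by_atom_name < 3.0))
  structure(list(by_element = by_element, by_atom_name = by_atom_name,
                 name = name), class = "radius_set")
}

#' Assign van der Waals radii to a model
#'
#' Populates the `vdw_radius` column from a [radius_set()]; atom-name
#' overrides win over element radii.  Atoms whose element is not covered
#' raise an error naming the offenders.
#'
#' @param model A [molecular_model()].
#' @param set A [radius_set()].
#' @param exclude Optional selection expression for atoms to drop before
#'   profiling (e.g. `"water"`); `NULL` keeps everything.
#' @return The model with radii assigned (and exclusions removed).
#' @export
assign_radii <- function(model, set = radius_set("simple"), exclude = NULL) {
  stopifnot(inherits(set, "radius_set"))
  if (!is.null(exclude)) {
    drop_idx <- suppressWarnings(select(model, exclude)$indices)
    if (length(drop_idx)) {
      keep <- setdiff(seq_len(nrow(model)), drop_idx)
      if (!length(keep)) stop("exclusion removed every atom")
      model <- molecular_model(as.data.frame(model)[keep, ],
                               title = attr(model, "title"),
                               source_format = attr(model, "source_format"))
    }
  }
  r <- set$by_element[toupper(model$element)]
  if (!is.null(set$by_atom_name)) {
    ov <- set$by_atom_name[toupper(model$name)]
    r[!is.na(ov)] <- ov[!is.na(ov)]
  }
  if (anyNA(r)) {
    bad <- which(is.na(r))
    stop("no radius for atom(s): ",
         paste(sprintf("%s/%s %s%d %s", model$element[bad], model$name[bad],
                       model$chain[bad], model$resid[bad], model$resname[bad])[
                         seq_len(min(5, length(bad)))], collapse = "; "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  model$vdw_radius <- unname(r)
  attr(model, "radius_set") <- set$name
  model
}

#' Inscribed-sphere pore-radius profile
#'
#' At each z-slice along the pore axis the profiler maximizes, over centre
#' positions in the slice plane, the radius of the largest sphere touching
#' no atom: `r(z) = max_c min_i (|c - atom_i| - vdw_i)`.  The maximization
#' uses simulated annealing seeded from the previous slice's centre (the
#' first slice starts on the frame axis), marching outward from the gate
#' plane (z = 0) in both directions - the same strategy as the classic
#' channel-profiling programs.  Slices with no atoms within
#' `atom_cutoff` of the plane are reported capped at `max_radius` and
#' flagged unconverged (bulk solvent).
#'
#' @param model A [molecular_model()] with radii assigned
#'   (see [assign_radii()]).
#' @param frame A [build_pore_frame()] result.
#' @param z_range `c(lo, hi)` of axial coordinates to profile, Angstrom.
#' @param step Slice spacing, Angstrom (default 0.25).
#' @param anneal List with `n_steps`, `start_T`, `cool_rate`, `seed`.
#' @param atom_cutoff Atoms within this axial distance of a slice are
#'   considered, Angstrom.
#' @param max_radius Radius cap for bulk slices, Angstrom.
#' @param max_shift Maximum in-plane distance the probe centre may move
#'   from the previous slice's centre, Angstrom; enforces the continuity
#'   of the centre path and keeps the probe inside the lumen.
#' @return A `pore_profile`: data frame `z`, `radius`, `cx`, `cy`,
#'   `converged` with metadata attributes (`radius_set`, `step`, `anneal`).
#' @export
compute_profile <- function(model, frame, z_range = NULL, step = 0.25,
                            anneal = list(n_steps = 2000, start_T = 1.0,
                                          cool_rate = 0.995, seed = 0),
                            atom_cutoff = 15, max_radius = 15,
                            max_shift = 2.5) {
  if (all(is.na(model$vdw_radius))) stop("assign radii first (assign_radii)")
  an <- utils::modifyList(list(n_steps = 2000, start_T = 1.0,
                               cool_rate = 0.995, seed = 0), anneal)
  ## transform atoms into the pore frame once
  basis <- frame_basis(frame)
  rel <- sweep(coords(model), 2, frame$origin)
  pz <- drop(rel %*% frame$axis)
  px <- drop(rel %*% basis[1, ])
  py <- drop(rel %*% basis[2, ])
  vdw <- model$vdw_radius
  if (is.null(z_range)) z_range <- range(pz)
  z_up <- seq(0, z_range[2], by = step)
  z_dn <- seq(0 - step, z_range[1], by = -step)
  set.seed(an$seed)
  march <- function(zs) {
    out <- matrix(NA_real_, length(zs), 4)
    cx <- 0; cy <- 0
    for (j in seq_along(zs)) {
      zj <- zs[j]
      near <- abs(pz - zj) <= atom_cutoff
      if (!any(near)) {
        out[j, ] <- c(zj, max_radius, cx, cy)
        next
      }
      res <- anneal_slice_cpp(px[near], py[near], pz[near], vdw[near],
                              zj, cx, cy, an$n_steps, an$start_T,
                              an$cool_rate, max_radius, max_shift)
      cx <- res[1]; cy <- res[2]
      out[j, ] <- c(zj, res[3], cx, cy)
    }
    out
  }
  up <- march(z_up)
  dn <- march(z_dn)
  tab <- rbind(dn[rev(seq_len(nrow(dn))), , drop = FALSE], up)
  prof <- data.frame(z = tab[, 1], radius = pmin(tab[, 2], max_radius),
                     cx = tab[, 3], cy = tab[, 4],
                     converged = tab[, 2] < max_radius - 1e-9)
  structure(prof, class = c("pore_profile", "data.frame"),
            radius_set = attr(model, "radius_set"), step = step, anneal = an,
            frame = frame)
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("pore_profile: %d slices, z %.1f..%.1f, step %.2f, radius set %s\n",
              nrow(x), min(x$z), max(x$z), attr(x, "step"),
              attr(x, "radius_set") %||% "per-atom"))
  i <- which.min(x$radius)
  cat(sprintf(" minimum radius %.2f A (diameter %.2f A) at z = %.2f A\n",
              x$radius[i], 2 * x$radius[i], x$z[i]))
  invisible(x)
}

#' @export
plot.pore_profile <- function(x, ...) {
  graphics::plot(x$z, x$radius, type = "l", xlab = "z (A)",
                 ylab = "pore radius (A)", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Brute-force grid evaluation of the inscribed-sphere radius at one slice
#'
#' Independent of the annealing path: evaluates
#' `min_i (|c - atom_i| - vdw_i)` on a square grid of candidate centres
#' and returns the maximum.  Used as a certificate/reference for
#' [compute_profile()].
#'
#' @inheritParams compute_profile
#' @param z Slice position, Angstrom.
#' @param grid_extent Half-width of the centre search square, Angstrom.
#' @param grid_step Grid spacing, Angstrom (0.05 default).
#' @return List with `radius`, `cx`, `cy`.
#' @export
profile_grid_search <- function(model, frame, z, grid_extent = 3,
                                grid_step = 0.05, atom_cutoff = 15) {
  basis <- frame_basis(frame)
  rel <- sweep(coords(model), 2, frame$origin)
  pz <- drop(rel %*% frame$axis)
  near <- abs(pz - z) <= atom_cutoff
  px <- drop(rel[near, , drop = FALSE] %*% basis[1, ])
  py <- drop(rel[near, , drop = FALSE] %*% basis[2, ])
  dz2 <- (pz[near] - z)^2
  vdw <- model$vdw_radius[near]
  g <- seq(-grid_extent, grid_extent, by = grid_step)
  best <- -Inf; bx <- 0; by <- 0
  for (cx in g) {
    ## vectorized over cy (rows) x atoms (columns) for each cx
    dx2 <- (cx - px)^2
    m <- sqrt(outer(rep(1, length(g)), dx2 + dz2) +
              outer(g, py, function(a, b) (a - b)^2))
    f <- apply(sweep(m, 2, vdw), 1, min)
    j <- which.max(f)
    if (f[j] > best) { best <- f[j]; bx <- cx; by <- g[j] }
  }
  list(radius = best, cx = bx, cy = by)
}

#' Gate diameters at named residues
#'
#' For each requested residue the side-chain heavy atoms (all heavy atoms
#' minus backbone N, CA, C, O; CA for glycine) are projected into the pore
#' frame; the reported diameter is twice the profile radius at the nearest
#' local constriction within `window` of the residue's axial position
#' (minimum over the window if no interior local minimum exists).
#' Diameter means twice the inscribed-sphere radius - the
#' solvent-accessible pathway convention, not an atom-centre distance.
#'
#' @param profile A [compute_profile()] result.
#' @param model The profiled [molecular_model()].
#' @param frame The [build_pore_frame()] used for the profile.
#' @param residues Integer residue numbers.
#' @param window Axial matching half-window, Angstrom (default 2).
#' @return Data frame `resid`, `z`, `diameter`, `found`.
#' @export
gate_metrics <- function(profile, model, frame, residues, window = 2) {
  out <- data.frame(resid = residues, z = NA_real_, diameter = NA_real_,
                    found = FALSE)
  for (i in seq_along(residues)) {
    sel <- which(model$resid == residues[i] & toupper(model$element) != "H")
    if (!length(sel)) next
    sc <- sel[!(toupper(model$name[sel]) %in% c("N", "CA", "C", "O", "OXT"))]
    if (!length(sc)) sc <- sel[toupper(model$name[sel]) == "CA"]
    zres <- mean(project_to_frame(coords(model, sc), frame)$z)
    win <- which(abs(profile$z - zres) <= window & profile$converged)
    if (!length(win)) next
    r <- profile$radius
    ## interior local minima inside the window
    loc <- win[win > 1 & win < nrow(profile)]
    loc <- loc[r[loc] <= r[loc - 1] & r[loc] <= r[loc + 1]]
    j <- if (length(loc)) loc[which.min(abs(profile$z[loc] - zres))]
         else win[which.min(r[win])]
    out$z[i] <- zres
    out$diameter[i] <- 2 * r[j]
    out$found[i] <- TRUE
  }
  out
}
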