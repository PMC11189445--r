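#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid superposition of `mobile` onto `reference` over a
#' paired atom selection, by the Kabsch/SVD construction with uniform
#' weights and a proper rotation (det +1).  Atoms are paired by
#' (chain, resid, name); a pairing mismatch is an error listing the
#' unmatched atoms.
#'
#' @param mobile,reference [molecular_model()] objects.
#' @param selection_expr Selection resolved in both models.
#' @return A `superposition_result`: `rotation` (3x3), `translation`
#'   (3-vector; the fit maps mobile x to `rotation %*% x + translation`),
#'   `rmsd` (Angstrom, over the selection after transform),
#'   `selection_used`.
#' @export
superpose_kabsch <- function(mobile, reference, selection_expr = "name CA") {
  sm <- select(mobile, selection_expr)
  sr <- select(reference, selection_expr)
  km <- paste(mobile$chain[sm$indices], mobile$resid[sm$indices],
              mobile$name[sm$indices])
  kr <- paste(reference$chain[sr$indices], reference$resid[sr$indices],
              reference$name[sr$indices])
  common <- intersect(km, kr)
  if (!length(common)) stop("selection pairs no atoms between the models")
  if (length(common) < length(km) || length(common) < length(kr)) {
    um <- c(setdiff(km, kr), setdiff(kr, km))
    stop("atom pairing mismatch; unmatched: ",
         paste(head(um, 6), collapse = "; "),
         if (length(um) > 6) sprintf(" (and %d more)", length(um) - 6) else "")
  }
  P <- coords(mobile, sm$indices[match(common, km)])
  Q <- coords(reference, sr$indices[match(common, kr)])
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cq - drop(R %*% cp)
  Pt <- sweep(P %*% t(R), 2, tvec, "+")
  rmsd <- sqrt(mean(rowSums((Pt - Q)^2)))
  structure(list(rotation = R, translation = tvec, rmsd = rmsd,
                 selection_used = sm, n_pairs = length(common)),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition over %d pairs: rmsd %.4f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition to a model
#'
#' @param model A [molecular_model()].
#' @param sup A [superpose_kabsch()] result.
#' @return The transformed model.
#' @export
apply_superposition <- function(model, sup) {
  xyz <- coords(model) %*% t(sup$rotation)
  set_coords(model, sweep(xyz, 2, sup$translation, "+"))
}

#' RMSD series and RMSF profiles of a trajectory
#'
#' Every frame is rigidly aligned to the reference (the topology
#' coordinates) over `align_expr` - by default the transmembrane backbone
#' ranges commonly used for channel trajectories - and then
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` is computed per measured atom over
#' all frames of all replicas.  The RMSD series (per replica, over the
#' measured selection, vs the reference) is returned alongside.  Setting
#' `align_expr = NULL` skips alignment (useful when frames are already
#' aligned, or for closed-form checks on synthetic jitter).
#'
#' When the model has several symmetry-equivalent chains the per-atom
#' RMSF is additionally averaged across chains by (resid, name).
#'
#' @param traj A `trajectory_ensemble`.
#' @param align_expr Alignment selection, or `NULL` for none.
#' @param measure_expr Selection over which RMSD/RMSF are measured.
#' @return List with `rmsd` (data frame `replica`, `t`, `rmsd`), `rmsf`
#'   (data frame `chain`, `resid`, `name`, `rmsf`), `rmsf_chain_averaged`
#'   (data frame `resid`, `name`, `rmsf`, `n_chains`).
#' @export
fluctuation_profiles <- function(traj,
                                 align_expr = paste("backbone and resid",
                                   "140-166,173-195,209-242,253-287,297-324,369-401"),
                                 measure_expr = "name CA") {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  topo <- traj$topology
  meas <- select(topo, measure_expr)$indices
  if (!length(meas)) stop("measure selection matches no atoms")
  align_idx <- if (is.null(align_expr)) NULL else select(topo, align_expr)$indices
  ref_xyz <- coords(topo)
  n_total <- sum(vapply(traj$replicas, function(r) dim(r)[1], integer(1)))
  if (n_total < 2) warning("single-frame input: RMSF is identically zero")
  aligned <- array(NA_real_, c(n_total, length(meas), 3))
  rmsd_rows <- list()
  fcount <- 0
  for (r in seq_along(traj$replicas)) {
    arr <- traj$replicas[[r]]
    n_fr <- dim(arr)[1]
    rmsd_vec <- numeric(n_fr)
    for (f in seq_len(n_fr)) {
      xyz <- arr[f, , ]
      if (!is.null(align_idx)) {
        xyz <- kabsch_align(xyz, ref_xyz, align_idx)
      }
      mx <- xyz[meas, , drop = FALSE]
      rmsd_vec[f] <- sqrt(mean(rowSums((mx - ref_xyz[meas, , drop = FALSE])^2)))
      fcount <- fcount + 1
      aligned[fcount, , ] <- mx
    }
    rmsd_rows[[r]] <- data.frame(
      replica = r, t = seq(0, by = traj$frame_interval, length.out = n_fr),
      rmsd = rmsd_vec)
  }
  ## two-pass mean/variance (a one-pass sum of squares loses precision)
  mean_x <- apply(aligned, c(2, 3), mean)
  dev2 <- (aligned - rep(mean_x, each = n_total))^2
  msf <- apply(dev2, 2, sum) / n_total
  rmsf <- data.frame(chain = topo$chain[meas], resid = topo$resid[meas],
                     name = topo$name[meas], rmsf = sqrt(msf),
                     stringsAsFactors = FALSE)
  key <- paste(rmsf$resid, rmsf$name)
  avg <- do.call(rbind, lapply(split(rmsf, key), function(d) {
    data.frame(resid = d$resid[1], name = d$name[1], rmsf = mean(d$rmsf),
               n_chains = nrow(d), stringsAsFactors = FALSE)
  }))
  avg <- avg[order(avg$resid, avg$name), ]
  rownames(avg) <- NULL
  list(rmsd = do.call(rbind, rmsd_rows), rmsf = rmsf,
       rmsf_chain_averaged = avg)
}

## Rigid alignment of a coordinate matrix onto a reference over an index set.
kabsch_align <- function(xyz, ref_xyz, idx) {
  P <- xyz[idx, , drop = FALSE]; Q <- ref_xyz[idx, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(xyz, 2, cp) %*% t(R), 2, cq, "+")
}

#' Helix axes and bend angle between two segments
#'
#' Each segment's axis is the first principal component of its CA
#' coordinates, oriented N-terminus to C-terminus; the bend is the angle
#' between the two axes.  The angle is invariant under global rigid
#' transforms and uniform scaling, and symmetric in the two segments.
#'
#' @param model A [molecular_model()].
#' @param segment_a,segment_b `c(first_resid, last_resid)` ranges; each
#'   needs at least 5 CA atoms.
#' @param chain Chain to analyse (default: first chain in the model).
#' @return A `helix_geometry`: list with `axis_a`, `axis_b` (unit
#'   vectors), `bend_angle` (degrees), the segments and chain.
#' @export
helix_axes_and_bend <- function(model, segment_a, segment_b,
                                chain = model$chain[1]) {
  axis_of <- function(seg) {
    idx <- which(model$chain == chain & toupper(model$name) == "CA" &
                 model$resid >= seg[1] & model$resid <= seg[2])
    if (length(idx) < 5)
      stop(sprintf("segment %d-%d has %d CA atoms; need >= 5 for a stable axis",
                   seg[1], seg[2], length(idx)))
    idx <- idx[order(model$resid[idx])]
    helix_pca_axis(coords(model, idx))
  }
  aa <- axis_of(segment_a)
  ab <- axis_of(segment_b)
  ang <- acos(min(1, max(-1, sum(aa * ab)))) * 180 / pi
  structure(list(segment_a = segment_a, segment_b = segment_b,
                 axis_a = aa, axis_b = ab, bend_angle = ang, chain = chain),
            class = "helix_geometry")
}

#' @export
print.helix_geometry <- function(x, ...) {
  cat(sprintf("helix bend: %.1f deg between resid %d-%d and %d-%d (chain %s)\n",
              x$bend_angle, x$segment_a[1], x$segment_a[2],
              x$segment_b[1], x$segment_b[2], x$chain))
  invisible(x)
}

#' Per-residue helicity and unwound runs
#'
#' Residue i is called helical iff it participates in an alpha
#' hydrogen bond - O(i)...N(i+4) or O(i-4)...N(i) within 3.5 Angstrom -
#' AND phi(i) lies in [-100, -30] AND psi(i) lies in [-80, -5] degrees.
#' Residues lacking both i+-4 partners, or a dihedral (chain termini),
#' are judged on the remaining criteria.  This is a documented
#' convention, configurable via the cutoffs.  Contiguous
#' non-helical runs are reported with their length in helical turns
#' (run / 3.6 residues per turn).
#'
#' @param model A [molecular_model()] with backbone N, CA, C, O.
#' @param residue_range `c(first, last)` author residue numbers.
#' @param chain Chain identifier (default: first chain).
#' @param on4_cutoff O(i)-N(i+4) distance cutoff, Angstrom.
#' @param phi_range,psi_range Allowed dihedral windows, degrees.
#' @return List with `per_residue` (data frame `resid`, `helical`,
#'   `indeterminate`) and `nonhelical_runs` (data frame `start`, `end`,
#'   `length`, `turns`).
#' @export
helicity_profile <- function(model, residue_range, chain = model$chain[1],
                             on4_cutoff = 3.5, phi_range = c(-100, -30),
                             psi_range = c(-80, -5)) {
  resids <- seq(residue_range[1], residue_range[2])
  bb <- function(resid, name) {
    i <- which(model$chain == chain & model$resid == resid &
               toupper(model$name) == name)
    if (length(i) == 1) coords(model, i)[1, ] else NULL
  }
  helical <- logical(length(resids))
  indet <- logical(length(resids))
  for (k in seq_along(resids)) {
    ri <- resids[k]
    N <- bb(ri, "N"); CA <- bb(ri, "CA"); C <- bb(ri, "C"); O <- bb(ri, "O")
    if (is.null(N) || is.null(CA) || is.null(C)) {
      indet[k] <- TRUE
      next
    }
    crit <- logical(0)
    N4 <- bb(ri + 4, "N")
    O4 <- bb(ri - 4, "O")
    hb <- logical(0)
    if (!is.null(O) && !is.null(N4))
      hb <- c(hb, sqrt(sum((O - N4)^2)) <= on4_cutoff)
    if (!is.null(O4))
      hb <- c(hb, sqrt(sum((O4 - N)^2)) <= on4_cutoff)
    if (length(hb)) crit <- c(crit, any(hb))
    Cprev <- bb(ri - 1, "C")
    if (!is.null(Cprev)) {
      phi <- dihedral(Cprev, N, CA, C)
      crit <- c(crit, phi >= phi_range[1] && phi <= phi_range[2])
    }
    Nnext <- bb(ri + 1, "N")
    if (!is.null(Nnext)) {
      psi <- dihedral(N, CA, C, Nnext)
      crit <- c(crit, psi >= psi_range[1] && psi <= psi_range[2])
    }
    if (!length(crit)) indet[k] <- TRUE else helical[k] <- all(crit)
  }
  per_res <- data.frame(resid = resids, helical = helical,
                        indeterminate = indet)
  nh <- !helical & !indet
  runs <- rle(nh)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sel <- which(runs$values)
  run_tab <- data.frame(start = resids[starts[sel]], end = resids[ends[sel]],
                        length = runs$lengths[sel],
                        turns = runs$lengths[sel] / 3.6)
  list(per_residue = per_res, nonhelical_runs = run_tab)
}

## Signed dihedral angle in degrees for points p1-p2-p3-p4.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Displacement of labeled atoms between two states
#'
#' Superposes `model_b` onto `model_a` over a stated selection (e.g. the
#' S1-S2 helices when tracking voltage-sensor charges) and reports each
#' labeled atom's displacement vector and magnitude in the frame of
#' `model_a`.  Labels missing from either model get an NA row rather than
#' failing the whole comparison.
#'
#' @param model_a,model_b [molecular_model()] objects (reference and
#'   displaced states).
#' @param labels Data frame with columns `label`, `resid`, `atom` and
#'   optionally `chain`.
#' @param align_expr Superposition selection expression.
#' @return Data frame `label`, `dx`, `dy`, `dz`, `distance`, `found`.
#' @export
charge_displacement <- function(model_a, model_b, labels,
                                align_expr = "name CA") {
  sup <- superpose_kabsch(model_b, model_a, align_expr)
  b_aligned <- apply_superposition(model_b, sup)
  find_atom <- function(m, resid, atom, chain) {
    i <- which(m$resid == resid & toupper(m$name) == toupper(atom) &
               (if (is.null(chain) || is.na(chain)) TRUE else m$chain == chain))
    if (length(i)) i[1] else NA_integer_
  }
  out <- data.frame(label = labels$label, dx = NA_real_, dy = NA_real_,
                    dz = NA_real_, distance = NA_real_, found = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(labels))) {
    ch <- if ("chain" %in% names(labels)) labels$chain[i] else NULL
    ia <- find_atom(model_a, labels$resid[i], labels$atom[i], ch)
    ib <- find_atom(b_aligned, labels$resid[i], labels$atom[i], ch)
    if (is.na(ia) || is.na(ib)) next
    d <- coords(b_aligned, ib)[1, ] - coords(model_a, ia)[1, ]
    out[i, c("dx", "dy", "dz")] <- d
    out$distance[i] <- sqrt(sum(d^2))
    out$found[i] <- TRUE
  }
  out
}
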