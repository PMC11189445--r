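#' Build the pore-aligned reference frame
#'
#' The frame anchors Z = 0 at the mass-weighted centroid of the
#' bundle-crossing lower gate (default residues 394-398, heavy atoms) and
#' points +z toward the selectivity filter (default residues 358-361), i.e.
#' toward the extracellular side.  For near-symmetric models the principal
#' axis of the combined gate+filter selection is computed as a cross-check;
#' if it deviates from the centroid-difference axis by more than 5 degrees
#' a warning is raised.
#'
#' Masses are standard atomic masses; hydrogens are excluded by the default
#' expressions (deposited cryo-EM models lack them).
#'
#' @param model A [molecular_model()].
#' @param gate_expr Selection expression for the lower gate
#'   (Z = 0 anchor).
#' @param filter_expr Selection expression for the selectivity filter
#'   (defines +z).
#' @return A `pore_frame`: list with `origin` (3-vector, Angstrom), `axis`
#'   (unit 3-vector), `gate_selection`, `filter_selection`,
#'   `principal_axis_deviation_deg`.
#' @export
build_pore_frame <- function(model,
                             gate_expr = "resid 394-398 and heavy",
                             filter_expr = "resid 358-361 and heavy") {
  gate <- select(model, gate_expr)
  filt <- select(model, filter_expr)
  if (!length(gate$indices)) stop("gate selection is empty: ", gate_expr)
  if (!length(filt$indices)) stop("filter selection is empty: ", filter_expr)
  g_com <- mass_centroid(model, gate$indices)
  f_com <- mass_centroid(model, filt$indices)
  d <- f_com - g_com
  nd <- sqrt(sum(d^2))
  if (nd < 1) stop("degenerate pore axis: gate and filter centroids ",
                   sprintf("%.2f", nd), " Angstrom apart (< 1)")
  axis <- d / nd
  ## principal-axis cross-check on the combined selection
  both <- coords(model, c(gate$indices, filt$indices))
  pc <- prcomp(both, center = TRUE)$rotation[, 1]
  if (sum(pc * axis) < 0) pc <- -pc
  dev <- acos(min(1, max(-1, sum(pc * axis)))) * 180 / pi
  if (dev > 5)
    warning(sprintf("pore axis deviates %.1f deg from principal axis of gate+filter", dev))
  structure(list(origin = unname(g_com), axis = unname(axis),
                 gate_selection = gate, filter_selection = filt,
                 principal_axis_deviation_deg = dev),
            class = "pore_frame")
}

#' Construct a pore frame directly
#'
#' Builds a `pore_frame` from an explicit origin and axis, without atom
#' selections - convenient for synthetic fixtures whose geometry is known
#' by construction.
#'
#' @param origin 3-vector, Angstrom (the Z = 0 anchor).
#' @param axis 3-vector pointing toward the extracellular side
#'   (normalized internally).
#' @return A `pore_frame`.
#' @export
pore_frame <- function(origin = c(0, 0, 0), axis = c(0, 0, 1)) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("axis must be non-zero")
  structure(list(origin = as.numeric(origin), axis = as.numeric(axis) / n,
                 gate_selection = NULL, filter_selection = NULL,
                 principal_axis_deviation_deg = NA_real_),
            class = "pore_frame")
}

#' @export
print.pore_frame <- function(x, ...) {
  cat(sprintf("pore_frame: origin (%.2f, %.2f, %.2f), axis (%.3f, %.3f, %.3f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

mass_centroid <- function(model, indices) {
  w <- atomic_mass(model$element[indices])
  xyz <- coords(model, indices)
  colSums(xyz * w) / sum(w)
}

## Orthonormal in-plane basis perpendicular to the frame axis.
frame_basis <- function(frame) {
  a <- frame$axis
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  rbind(e1, e2)
}

#' Project coordinates into a pore frame
#'
#' @param xyz n x 3 matrix of Cartesian coordinates.
#' @param frame A `pore_frame`.
#' @return Data frame with `z` (axial, Angstrom) and `r_offset`
#'   (perpendicular distance from the pore axis).
#' @export
project_to_frame <- function(xyz, frame) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  rel <- sweep(xyz, 2, frame$origin)
  z <- drop(rel %*% frame$axis)
  perp <- rel - outer(z, frame$axis)
  data.frame(z = z, r_offset = sqrt(rowSums(perp^2)))
}
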