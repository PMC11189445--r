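#' Read a multi-frame trajectory
#'
#' Accepts DCD files (binary, via the standard decoder), multi-model PDB
#' files, multi-frame GRO files (nm converted to Angstrom), or the
#' plain-text ion-trace TSV dialect (see [read_ion_traces()]).  Each path
#' becomes one replica; formats may be mixed across replicas but atom
#' counts may not.  If every path is an ion-trace TSV the function returns
#' an [ion trace set][read_ion_traces] instead (topology-free analysis).
#'
#' @param paths Character vector of trajectory files, one per replica.
#' @param topology A [molecular_model()] giving atom identities, or `NULL`
#'   for TSV input.
#' @param frame_interval Time between stored frames, ns.
#' @return A `trajectory_ensemble`: list with `replicas` (each an
#'   `n_frames x n_atoms x 3` array, Angstrom), `box` (per-replica
#'   `n_frames x 3` orthorhombic lengths or `NULL`), `frame_interval`,
#'   `topology`.
#' @export
read_trajectory <- function(paths, topology = NULL, frame_interval = 1) {
  stopifnot(length(paths) >= 1, frame_interval > 0)
  ext <- tolower(tools::file_ext(paths))
  if (all(ext %in% c("tsv", "txt"))) {
    sets <- lapply(paths, read_ion_traces)
    return(if (length(sets) == 1) sets[[1]] else
           structure(sets, class = "ion_trace_replicas"))
  }
  if (is.null(topology)) stop("topology model required for coordinate trajectories")
  n_atoms <- nrow(topology)
  reps <- vector("list", length(paths))
  boxes <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    fr <- read_frames_one(paths[i], ext[i])
    if (dim(fr$coords)[2] != n_atoms) {
      stop(sprintf("atom-count mismatch in %s: %d frames x %d atoms, topology has %d",
                   paths[i], dim(fr$coords)[1], dim(fr$coords)[2], n_atoms))
    }
    reps[[i]] <- fr$coords
    boxes[[i]] <- fr$box
  }
  structure(list(replicas = reps, box = boxes,
                 frame_interval = frame_interval, topology = topology),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$replicas, function(r) dim(r)[1], integer(1))
  cat(sprintf("trajectory_ensemble: %d replica(s), frames %s, %d atoms, dt %g ns\n",
              length(x$replicas), paste(nf, collapse = "/"),
              dim(x$replicas[[1]])[2], x$frame_interval))
  invisible(x)
}

read_frames_one <- function(path, ext) {
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    n_fr <- nrow(xyz)
    coords <- array(NA_real_, c(n_fr, ncol(xyz) / 3, 3))
    for (k in 1:3) coords[, , k] <- xyz[, seq(k, ncol(xyz), by = 3), drop = FALSE]
    list(coords = coords, box = NULL)
  } else if (ext == "gro") {
    read_gro_frames(path)
  } else {  # multi-model PDB
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    n_fr <- nrow(xyz)
    coords <- array(NA_real_, c(n_fr, ncol(xyz) / 3, 3))
    for (k in 1:3) coords[, , k] <- xyz[, seq(k, ncol(xyz), by = 3), drop = FALSE]
    list(coords = coords, box = NULL)
  }
}

## Fixed-width GRO reader; positions are nm in the file, returned in Angstrom.
read_gro_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); boxes <- list(); i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(n)) stop("GRO parse error at line ", i + 1, " of ", path)
    at <- lines[(i + 2):(i + 1 + n)]
    x <- as.numeric(substr(at, 21, 28))
    y <- as.numeric(substr(at, 29, 36))
    z <- as.numeric(substr(at, 37, 44))
    frames[[length(frames) + 1]] <- cbind(x, y, z) * 10
    bx <- scan(text = lines[i + 2 + n], what = numeric(), quiet = TRUE)
    boxes[[length(boxes) + 1]] <- bx[1:3] * 10
    i <- i + 3 + n
  }
  coords <- array(NA_real_, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  list(coords = coords, box = do.call(rbind, boxes))
}

#' Read ion traces from the TSV dialect
#'
#' The dialect is tab-separated with header
#' `time_ns<TAB>ion_id<TAB>x<TAB>y<TAB>z`, one row per ion per frame,
#' sorted by (time_ns, ion_id), coordinates in Angstrom with at least six
#' significant digits.
#'
#' @param path TSV file path.
#' @return An `ion_trace_set`: list of per-ion data frames with columns
#'   `t`, `x`, `y`, `z`, each carrying attribute `ion_id`.
#' @export
read_ion_traces <- function(path) {
  tab <- read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("time_ns", "ion_id", "x", "y", "z")
  if (!identical(names(tab)[1:5], need)) {
    stop("ion-trace TSV header must be exactly: ", paste(need, collapse = "\\t"),
         " (got: ", paste(names(tab), collapse = ", "), ")")
  }
  traces <- lapply(split(tab, tab$ion_id), function(d) {
    d <- d[order(d$time_ns), ]
    tr <- data.frame(t = d$time_ns, x = d$x, y = d$y, z = d$z)
    attr(tr, "ion_id") <- as.character(d$ion_id[1])
    tr
  })
  structure(traces, class = "ion_trace_set")
}

#' Write ion traces in the TSV dialect
#'
#' @param traces An `ion_trace_set` (or list of data frames with `t`, `x`,
#'   `y`, `z` and attribute `ion_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ion_traces <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(time_ns = tr$t, ion_id = attr(tr, "ion_id"),
               x = tr$x, y = tr$y, z = tr$z, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$time_ns, rows$ion_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_ns\tion_id\tx\ty\tz", con)
  writeLines(sprintf("%.9g\t%s\t%.9g\t%.9g\t%.9g",
                     rows$time_ns, rows$ion_id, rows$x, rows$y, rows$z), con)
  invisible(path)
}
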