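#' Construct a molecular model
#'
#' A `molecular_model` is a data frame of atom records with one row per
#' atom and columns `serial`, `name`, `element`, `resname`, `resid`,
#' `chain`, `x`, `y`, `z`, `occupancy`, `bfactor`, `vdw_radius`.  Residue
#' numbers follow the author numbering of the source file and are never
#' renumbered.  Elements missing from the source are inferred from atom
#' names.
#'
#' @param atoms Data frame with at least `name`, `resname`, `resid`,
#'   `chain`, `x`, `y`, `z`.  `serial`, `element`, `occupancy`, `bfactor`
#'   and `vdw_radius` are filled with defaults when absent.
#' @param title Optional title string.
#' @param source_format One of `"PDB"`, `"mmCIF"`, `"synthetic"`.
#' @return A `molecular_model` object.
#' @export
molecular_model <- function(atoms, title = "", source_format = "synthetic") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("name", "resname", "resid", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$element) || all(is.na(atoms$element)) || all(atoms$element == "")) {
    atoms$element <- infer_element(atoms$name)
  } else {
    blank <- is.na(atoms$element) | atoms$element == ""
    atoms$element[blank] <- infer_element(atoms$name[blank])
  }
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$bfactor)) atoms$bfactor <- 0
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- NA_real_
  atoms <- atoms[, c("serial", "name", "element", "resname", "resid", "chain",
                     "x", "y", "z", "occupancy", "bfactor", "vdw_radius")]
  atoms$resid <- as.integer(atoms$resid)
  atoms$chain <- as.character(atoms$chain)
  atoms$name <- as.character(atoms$name)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key)) {
    warning("duplicate (chain, resid, name) triples in model: ",
            paste(head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  structure(atoms, class = c("molecular_model", "data.frame"),
            title = title, source_format = source_format)
}

#' @export
print.molecular_model <- function(x, ...) {
  cat(sprintf("molecular_model: %d atoms, %d chain(s) [%s], source %s\n",
              nrow(x), length(unique(x$chain)),
              paste(sort(unique(x$chain)), collapse = ","),
              attr(x, "source_format")))
  ttl <- attr(x, "title")
  if (nzchar(ttl)) cat(" title:", ttl, "\n")
  rng <- range(x$resid)
  cat(sprintf(" residues %d..%d; elements: %s\n", rng[1], rng[2],
              paste(sort(unique(x$element)), collapse = " ")))
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param model A `molecular_model`.
#' @param indices Optional atom indices.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(model, indices = NULL) {
  m <- as.matrix(as.data.frame(model)[, c("x", "y", "z")])
  if (!is.null(indices)) m <- m[indices, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model))
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

## PDB-convention element inference: strip digits/primes, leading digit
## (e.g. "1HG1") means hydrogen; two-letter elements only for common ions.
infer_element <- function(name) {
  nm <- toupper(trimws(name))
  el <- character(length(nm))
  for (i in seq_along(nm)) {
    s <- nm[i]
    if (grepl("^[0-9]", s)) { el[i] <- "H"; next }
    s2 <- gsub("[0-9']", "", s)
    if (s2 %in% c("NA", "CL", "MG", "ZN", "FE", "MN", "BR", "SE")) { el[i] <- s2; next }
    if (s2 == "K") { el[i] <- "K"; next }
    el[i] <- substr(s2, 1, 1)
  }
  el[el == ""] <- "X"
  el
}

.water_resnames <- c("HOH", "WAT", "TIP", "TIP3", "TIP3P", "SOL", "SPC", "H2O")
.protein_resnames <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                       "HIS", "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET",
                       "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

is_water <- function(model) toupper(model$resname) %in% .water_resnames

#' Write a model as PDB
#'
#' @param model A `molecular_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- as.data.frame(model)
  rec <- ifelse(toupper(a$resname) %in% c(.protein_resnames, "RNG"), "ATOM  ", "HETATM")
  ## PDB name column: element right-justified in cols 13-14 for 1-letter names
  nm4 <- vapply(seq_len(nrow(a)), function(i) {
    n <- a$name[i]
    if (nchar(n) < 4 && nchar(a$element[i]) == 1) sprintf(" %-3s", n) else sprintf("%-4s", n)
  }, character(1))
  lines <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial %% 100000L, nm4, substr(a$resname, 1, 3),
                   substr(a$chain, 1, 1), a$resid %% 10000L,
                   a$x, a$y, a$z, a$occupancy, a$bfactor,
                   formatC(a$element, width = 2, flag = " "))
  writeLines(c(sprintf("TITLE     %s", attr(model, "title")), lines, "END"), path)
  invisible(path)
}

#' Write a model as minimal mmCIF
#'
#' Emits a single `atom_site` loop sufficient for round-tripping
#' coordinates, identities and author residue numbering.
#'
#' @inheritParams write_structure
#' @export
write_structure_cif <- function(model, path) {
  a <- as.data.frame(model)
  hdr <- c("data_model", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_seq_id",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.auth_seq_id", "_atom_site.auth_asym_id")
  rec <- ifelse(toupper(a$resname) %in% c(.protein_resnames, "RNG"), "ATOM", "HETATM")
  rows <- sprintf("%s %d %s %s %s %s %d %.3f %.3f %.3f %.2f %.2f %d %s",
                  rec, a$serial, a$element, a$name, a$resname, a$chain, a$resid,
                  a$x, a$y, a$z, a$occupancy, a$bfactor, a$resid, a$chain)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
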