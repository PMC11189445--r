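#' Read a structure file into a molecular model
#'
#' Reads PDB (`ATOM`/`HETATM` records) or mmCIF (`atom_site` loop) files.
#' Alternate locations are collapsed to the highest-occupancy conformer
#' (ties keep the first listed).  Waters and ligands are retained; use
#' [select()] or the `exclude` argument of [assign_radii()] to drop them.
#' Author residue numbering is preserved exactly.
#'
#' @param path Path to a structure file.
#' @param format `"PDB"`, `"mmCIF"` or `"auto"` (by file extension).
#' @return A [molecular_model()].
#' @export
read_structure <- function(path, format = c("auto", "PDB", "mmCIF")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmCIF" else "PDB"
  }
  atoms <- if (format == "mmCIF") parse_cif_atoms(path) else parse_pdb_atoms(path)
  if (nrow(atoms) == 0) stop("no atoms parsed from ", path, " (empty model)")
  atoms <- collapse_altloc(atoms)
  molecular_model(atoms, title = basename(path), source_format = format)
}

parse_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  data.frame(
    serial = as.integer(a$eleno), name = trimws(a$elety),
    element = trimws(ifelse(is.na(a$elesy), "", a$elesy)),
    resname = trimws(a$resid), resid = as.integer(a$resno),
    chain = ifelse(is.na(a$chain), "A", a$chain),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    bfactor = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE)
}

## Minimal mmCIF atom_site reader.  Handles the common whitespace-delimited
## loop layout (as written by most deposition pipelines and by
## write_structure_cif); quoted fields without embedded spaces only.
parse_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  for (ls in loop_starts) {
    i <- ls + 1
    tags <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (!any(grepl("^_atom_site\\.", tags))) next
    rows <- list()
    while (i <= length(lines)) {
      ln <- lines[i]
      if (grepl("^\\s*(#|loop_|_|data_)", ln) || !nzchar(trimws(ln))) break
      rows[[length(rows) + 1]] <- scan(text = ln, what = "character", quiet = TRUE)
      i <- i + 1
    }
    if (!length(rows)) stop("mmCIF atom_site loop in ", path, " has no data rows")
    nf <- lengths(rows)
    if (any(nf != length(tags))) {
      stop("mmCIF parse error in ", path, ": row ",
           which(nf != length(tags))[1], " has ", nf[nf != length(tags)][1],
           " fields, expected ", length(tags))
    }
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(tab) <- sub("^_atom_site\\.", "", tags)
    gv <- function(nm, default = NA) if (nm %in% names(tab)) tab[[nm]] else default
    resid <- suppressWarnings(as.integer(gv("auth_seq_id")))
    if (all(is.na(resid))) resid <- suppressWarnings(as.integer(gv("label_seq_id")))
    chain <- gv("auth_asym_id"); if (all(is.na(chain))) chain <- gv("label_asym_id")
    occ <- suppressWarnings(as.numeric(gv("occupancy", "1")))
    bf <- suppressWarnings(as.numeric(gv("B_iso_or_equiv", "0")))
    alt <- gv("label_alt_id", "")
    alt[alt %in% c(".", "?")] <- ""
    return(data.frame(
      serial = suppressWarnings(as.integer(gv("id", seq_len(nrow(tab))))),
      name = gv("label_atom_id"), element = gv("type_symbol"),
      resname = gv("label_comp_id"), resid = resid, chain = chain,
      altloc = alt,
      x = as.numeric(gv("Cartn_x")), y = as.numeric(gv("Cartn_y")),
      z = as.numeric(gv("Cartn_z")),
      occupancy = ifelse(is.na(occ), 1, occ), bfactor = ifelse(is.na(bf), 0, bf),
      stringsAsFactors = FALSE))
  }
  stop("no atom_site loop found in ", path)
}

## Keep the highest-occupancy altloc per (chain, resid, name); ties keep the
## first listed conformer.  Deterministic by construction.
collapse_altloc <- function(atoms) {
  if (is.null(atoms$altloc)) return(atoms)
  has_alt <- atoms$altloc != ""
  if (!any(has_alt)) { atoms$altloc <- NULL; return(atoms) }
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) <= 1) next
    best <- idx[which.max(atoms$occupancy[idx])]  # which.max: first on ties
    keep[setdiff(idx, best)] <- FALSE
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  atoms
}
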