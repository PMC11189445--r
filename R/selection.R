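#' Resolve an atom selection expression
#'
#' A small selection grammar over atom records.  Primaries:
#'
#' * `resid 394-398`, `resid 12`, `resid 1,3,5-9` — author residue numbers
#' * `chain A` or `chain A B`
#' * `name CA` or `name CA CB OG`
#' * `resname TYR HOH`, `elem K O`
#' * keywords: `heavy` (no hydrogens), `hydrogen`, `backbone` (N, CA, C, O),
#'   `ca`, `protein`, `water`, `all`
#'
#' combined with `and`, `or`, `not` and parentheses; `and` binds tighter
#' than `or`.  Resolution is deterministic and order-preserving: indices
#' come back in file order, and resolving the same expression twice on the
#' same model yields identical indices.
#'
#' Degenerate residue ranges (e.g. `resid 10-5`) and chains absent from the
#' model yield an empty sub-selection with a warning; empty final
#' selections are allowed but flagged with a warning.
#'
#' @param model A [molecular_model()].
#' @param expression Selection string.
#' @return A `selection` object: list with `expression` and `indices`.
#' @examples
#' m <- generate_ring_pore(ring_pore_spec(z_planes = 0, ring_radius = 5))$model
#' sel <- select(m, "resid 1 and heavy")
#' @export
select <- function(model, expression) {
  stopifnot(inherits(model, "molecular_model"))
  toks <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$expr <- expression
  mask <- parse_or(st, model)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("selection syntax error near token %d ('%s') in \"%s\"",
                 st$pos, st$toks[st$pos], expression))
  }
  idx <- which(mask)
  if (!length(idx)) warning("selection \"", expression, "\" matches no atoms")
  structure(list(expression = expression, indices = idx), class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("selection \"%s\": %d atoms\n", x$expression, length(x$indices)))
  invisible(x)
}

tokenize_selection <- function(expression) {
  s <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; st$toks[st$pos - 1L] }

parse_or <- function(st, model) {
  m <- parse_and(st, model)
  while (!is.na(peek(st)) && tolower(peek(st)) == "or") {
    advance(st)
    m <- m | parse_and(st, model)
  }
  m
}

parse_and <- function(st, model) {
  m <- parse_term(st, model)
  while (!is.na(peek(st)) && tolower(peek(st)) == "and") {
    advance(st)
    m <- m & parse_term(st, model)
  }
  m
}

.sel_keywords <- c("and", "or", "not", "(", ")", "resid", "chain", "name",
                   "resname", "elem", "element", "heavy", "hydrogen",
                   "backbone", "ca", "protein", "water", "all")

parse_term <- function(st, model) {
  tok <- peek(st)
  if (is.na(tok)) stop("selection ended unexpectedly in \"", st$expr, "\"")
  lt <- tolower(tok)
  if (lt == "not") { advance(st); return(!parse_term(st, model)) }
  if (tok == "(") {
    advance(st)
    m <- parse_or(st, model)
    if (is.na(peek(st)) || peek(st) != ")")
      stop(sprintf("missing ')' at token %d in \"%s\"", st$pos, st$expr))
    advance(st)
    return(m)
  }
  advance(st)
  n <- nrow(model)
  switch(lt,
    resid = {
      vals <- consume_values(st)
      if (!length(vals)) stop("'resid' needs at least one number/range in \"", st$expr, "\"")
      resid_mask(model, vals)
    },
    chain = {
      vals <- consume_values(st)
      if (!length(vals)) stop("'chain' needs at least one identifier")
      unknown <- setdiff(vals, unique(model$chain))
      if (length(unknown))
        warning("chain(s) not in model: ", paste(unknown, collapse = ", "))
      model$chain %in% vals
    },
    name = {
      vals <- toupper(consume_values(st))
      if (!length(vals)) stop("'name' needs at least one atom name")
      toupper(model$name) %in% vals
    },
    resname = {
      vals <- toupper(consume_values(st))
      toupper(model$resname) %in% vals
    },
    elem = ,
    element = {
      vals <- toupper(consume_values(st))
      toupper(model$element) %in% vals
    },
    heavy = toupper(model$element) != "H",
    hydrogen = toupper(model$element) == "H",
    backbone = toupper(model$name) %in% c("N", "CA", "C", "O", "OXT"),
    ca = toupper(model$name) == "CA",
    protein = toupper(model$resname) %in% .protein_resnames,
    water = is_water(model),
    all = rep(TRUE, n),
    stop(sprintf("unknown selection token '%s' at position %d in \"%s\"",
                 tok, st$pos - 1L, st$expr))
  )
}

## Greedily consume value tokens, splitting on commas.  Only operators and
## primary heads end a value list, so bare keywords that are also valid
## atom names (e.g. "name CA") remain usable as values.
.sel_stoppers <- c("and", "or", "not", "(", ")", "resid", "chain", "name",
                   "resname", "elem", "element")

consume_values <- function(st) {
  vals <- character()
  while (!is.na(peek(st)) && !(tolower(peek(st)) %in% .sel_stoppers)) {
    vals <- c(vals, strsplit(advance(st), ",")[[1]])
  }
  vals[nzchar(vals)]
}

resid_mask <- function(model, vals) {
  mask <- rep(FALSE, nrow(model))
  for (v in vals) {
    if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^-?[0-9]+-[0-9]+$", v)) {
      parts <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
      lo <- as.integer(parts[2]); hi <- as.integer(parts[3])
      if (lo > hi) {
        warning(sprintf("degenerate resid range %d-%d selects nothing", lo, hi))
        next
      }
      mask <- mask | (model$resid >= lo & model$resid <= hi)
    } else if (grepl("^-?[0-9]+$", v)) {
      mask <- mask | (model$resid == as.integer(v))
    } else {
      stop("bad resid token '", v, "'")
    }
  }
  mask
}
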