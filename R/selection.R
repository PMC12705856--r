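#' Select atoms with a small selection language
#'
#' The grammar supports the primitives `chain <id>`, `resnum <a>`,
#' `resnum <a>:<b>` (inclusive, negative numbers allowed), `resname <name>`
#' and `name <atom>`, combined with `and`, `or`, `not` and parentheses.
#' `not` binds tightest, then `and`, then `or`.
#'
#' @param x a `gyre_structure` or `gyre_ensemble`.
#' @param expression selection text, e.g. `"chain J and name N1"`,
#'   `"resnum -39:39 and name P"`.
#' @return An object of the same kind containing only the matching atoms,
#'   in their original order. Ensemble selection applies to every frame
#'   identically.
#' @examples
#' s <- make_superhelix_duplex(superhelix_params(n_bp = 11))$structure
#' select_atoms(s, "chain I and name C1'")
#' @export
select_atoms <- function(x, expression) UseMethod("select_atoms")

#' @export
select_atoms.gyre_structure <- function(x, expression) {
  keep <- selection_mask(x$atoms, expression)
  if (!any(keep))
    gd_abort("gyredyn_empty_selection",
             sprintf("selection '%s' matches no atoms", expression))
  x$atoms <- x$atoms[keep, , drop = FALSE]
  rownames(x$atoms) <- NULL
  x
}

#' @export
select_atoms.gyre_ensemble <- function(x, expression) {
  keep <- selection_mask(x$topology$atoms, expression)
  if (!any(keep))
    gd_abort("gyredyn_empty_selection",
             sprintf("selection '%s' matches no atoms", expression))
  cols <- rep(which(keep) * 3L, each = 3L) + c(-2L, -1L, 0L)
  x$topology$atoms <- x$topology$atoms[keep, , drop = FALSE]
  rownames(x$topology$atoms) <- NULL
  x$xyz <- x$xyz[, cols, drop = FALSE]
  x
}

# Logical mask over an atom table for a selection expression.
selection_mask <- function(atoms, expression) {
  toks <- selection_tokens(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, atoms)
  if (st$pos <= length(st$toks))
    gd_abort("gyredyn_selection_syntax",
             sprintf("trailing tokens in selection near '%s'", st$toks[st$pos]))
  mask
}

selection_tokens <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L || !nzchar(trimws(expression)))
    gd_abort("gyredyn_selection_syntax", "selection must be a non-empty string")
  spaced <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  if (!length(toks)) gd_abort("gyredyn_selection_syntax", "empty selection")
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; st$toks[st$pos - 1L] }

parse_or <- function(st, atoms) {
  m <- parse_and(st, atoms)
  while (!is.na(peek(st)) && peek(st) == "or") {
    advance(st)
    m <- m | parse_and(st, atoms)
  }
  m
}

parse_and <- function(st, atoms) {
  m <- parse_factor(st, atoms)
  while (!is.na(peek(st)) && peek(st) == "and") {
    advance(st)
    m <- m & parse_factor(st, atoms)
  }
  m
}

parse_factor <- function(st, atoms) {
  tok <- peek(st)
  if (is.na(tok))
    gd_abort("gyredyn_selection_syntax", "unexpected end of selection")
  if (tok == "not") {
    advance(st)
    return(!parse_factor(st, atoms))
  }
  if (tok == "(") {
    advance(st)
    m <- parse_or(st, atoms)
    if (is.na(peek(st)) || peek(st) != ")")
      gd_abort("gyredyn_selection_syntax", "missing closing parenthesis")
    advance(st)
    return(m)
  }
  parse_primitive(st, atoms)
}

parse_primitive <- function(st, atoms) {
  key <- advance(st)
  if (!key %in% c("chain", "resnum", "resname", "name"))
    gd_abort("gyredyn_selection_syntax",
             sprintf("expected a selection keyword, got '%s'", key))
  val <- peek(st)
  if (is.na(val) || val %in% c("and", "or", "not", "(", ")"))
    gd_abort("gyredyn_selection_syntax",
             sprintf("keyword '%s' needs an argument", key))
  advance(st)
  switch(key,
    chain   = atoms$chain == val,
    resname = atoms$resid == val,
    name    = atoms$elety == val,
    resnum  = {
      # "a" or "a:b", either bound possibly negative
      m <- regmatches(val, regexec("^(-?[0-9]+)(:(-?[0-9]+))?$", val))[[1]]
      if (!length(m))
        gd_abort("gyredyn_selection_syntax",
                 sprintf("bad resnum argument '%s'", val))
      a <- as.integer(m[2L])
      b <- if (nzchar(m[4L])) as.integer(m[4L]) else a
      atoms$resno >= min(a, b) & atoms$resno <= max(a, b)
    })
}
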