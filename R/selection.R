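#' @title Atom selection grammar
#'
#' @description Selections are small textual predicates over atoms, e.g.
#' `"chain B and resnum 113-536"`, `"hetero and resname SF4"`,
#' `"not (elem FE or elem NI)"`. The grammar (EBNF):
#'
#' ```
#' expr     = and_expr { "or" and_expr } ;
#' and_expr = not_expr { "and" not_expr } ;
#' not_expr = "not" not_expr | "(" expr ")" | term ;
#' term     = "chain" idlist | "resname" idlist | "name" idlist
#'          | "elem" idlist  | "resnum" rangelist
#'          | "hetero" | "protein" | "hydrogen" | "all" | "none" ;
#' idlist    = id { "," id } ;
#' rangelist = range { "," range } ;  range = int [ "-" int ] ;
#' ```
#'
#' Matching of identifiers is case-insensitive. `protein` is shorthand for
#' `not hetero`. Applying a selection twice yields the same atom set
#' (selections are idempotent predicates).
#'
#' @name selection
NULL

tokenize_selection <- function(expr) {
  pat <- "\\(|\\)|[A-Za-z_'][A-Za-z0-9_']*|-?[0-9]+(--?[0-9]+)?|,|\\S"
  m <- gregexpr(pat, expr, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(tok = character(), pos = integer()))
  data.frame(tok = regmatches(expr, list(m))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

sel_error <- function(msg, pos) {
  stop(sprintf("selection-grammar error at position %d: %s", pos, msg),
       call. = FALSE)
}

# Recursive-descent parser producing a predicate closure: atoms-df -> logical
parse_selection <- function(expr) {
  toks <- tokenize_selection(expr)
  i <- 1L
  peek <- function() if (i <= nrow(toks)) toks$tok[i] else NA_character_
  pos <- function() if (i <= nrow(toks)) toks$pos[i] else nchar(expr) + 1L
  advance <- function() { t <- peek(); i <<- i + 1L; t }
  kw <- function(t) !is.na(t) && tolower(t) %in%
    c("and", "or", "not", "chain", "resname", "resnum", "name", "elem",
      "hetero", "protein", "hydrogen", "all", "none")

  parse_idlist <- function(what) {
    ids <- character()
    repeat {
      t <- peek()
      if (is.na(t) || t %in% c("(", ")", ",") || kw(t))
        sel_error(paste0("expected ", what, " value"), pos())
      ids <- c(ids, toupper(advance()))
      if (identical(peek(), ",")) advance() else break
    }
    ids
  }
  parse_rangelist <- function() {
    lo <- integer(); hi <- integer()
    repeat {
      t <- peek()
      if (is.na(t) || !grepl("^-?[0-9]+(--?[0-9]+)?$", t))
        sel_error("expected residue number or range", pos())
      advance()
      if (grepl("^-?[0-9]+--?[0-9]+$", t)) {
        parts <- regmatches(t, regexec("^(-?[0-9]+)-(-?[0-9]+)$", t))[[1]]
        lo <- c(lo, as.integer(parts[2])); hi <- c(hi, as.integer(parts[3]))
      } else {
        v <- as.integer(t); lo <- c(lo, v); hi <- c(hi, v)
      }
      if (identical(peek(), ",")) advance() else break
    }
    list(lo = lo, hi = hi)
  }

  parse_term <- function() {
    t <- peek()
    if (is.na(t)) sel_error("unexpected end of expression", pos())
    low <- tolower(t)
    if (low == "(") {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")")) sel_error("expected ')'", pos())
      advance()
      return(e)
    }
    if (low == "not") { advance(); e <- parse_term(); return(function(a) !e(a)) }
    advance()
    switch(low,
      chain   = { ids <- parse_idlist("chain");
                  function(a) toupper(a$chain_id) %in% ids },
      resname = { ids <- parse_idlist("residue name");
                  function(a) toupper(a$residue_name) %in% ids },
      name    = { ids <- parse_idlist("atom name");
                  function(a) toupper(a$atom_name) %in% ids },
      elem    = { ids <- parse_idlist("element");
                  function(a) toupper(a$element) %in% ids },
      resnum  = { r <- parse_rangelist();
                  function(a) {
                    hit <- rep(FALSE, nrow(a))
                    for (k in seq_along(r$lo))
                      hit <- hit | (a$residue_number >= r$lo[k] &
                                    a$residue_number <= r$hi[k])
                    hit
                  } },
      hetero   = function(a) a$is_hetero,
      protein  = function(a) !a$is_hetero,
      hydrogen = function(a) toupper(a$element) %in% c("H", "D"),
      all      = function(a) rep(TRUE, nrow(a)),
      none     = function(a) rep(FALSE, nrow(a)),
      sel_error(paste0("unknown term '", t, "'"), toks$pos[i - 1L])
    )
  }
  parse_or <- function() {
    e <- parse_and()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      e <- local({ L <- e; R <- parse_and(); function(a) L(a) | R(a) })
    }
    e
  }
  parse_and <- function() {
    e <- parse_term()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      e <- local({ L <- e; R <- parse_term(); function(a) L(a) & R(a) })
    }
    e
  }

  e <- parse_or()
  if (!is.na(peek())) sel_error(paste0("unexpected token '", peek(), "'"), pos())
  e
}

#' Select atoms from a Structure
#'
#' Applies a selection expression (see [selection] for the grammar) and
#' returns the matching atoms in source order.
#'
#' @param s a [Structure].
#' @param expr selection expression string.
#' @param model model index to restrict to (default 1; `NULL` keeps all
#'   models).
#' @return data frame of matching atom rows.
#' @export
select_atoms <- function(s, expr, model = 1L) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  if (!is.null(model)) a <- a[a$model_index == model, , drop = FALSE]
  pred <- parse_selection(expr)
  hit <- pred(a)
  if (length(hit) != nrow(a) || !is.logical(hit))
    stop("internal selection error: predicate did not vectorize")
  out <- a[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subset a Structure by a selection expression
#'
#' Like [select_atoms()] but returns a new [Structure] (all models filtered
#' with the same predicate).
#' @inheritParams select_atoms
#' @return a [Structure].
#' @export
subset_structure <- function(s, expr) {
  pred <- parse_selection(expr)
  a <- s$atoms
  structure_from_atoms(a[pred(a), , drop = FALSE], metadata = s$metadata)
}
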