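# Boolean gene-selection predicate over species sets.
#
# Grammar (case-insensitive keywords):
#   expr   := term ("or" term)*
#   term   := factor ("and" factor)*
#   factor := "not" factor | "(" expr ")" | atom
#   atom   := ("present_in" | "absent_in") "(" SET_NAME ["," INT] ")"
# An omitted k defaults to the set's declared defaultK.  The AST is
# interpreted directly; no code generation.

.tokenizePredicate <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  toks <- list()
  for (ln in seq_along(lines)) {
    s <- lines[ln]
    col <- 1L
    while (nzchar(s)) {
      ws <- regmatches(s, regexpr("^\\s+", s))
      if (length(ws)) {
        col <- col + nchar(ws)
        s <- substring(s, nchar(ws) + 1L)
        next
      }
      m <- regmatches(s, regexpr("^([A-Za-z_][A-Za-z0-9_]*|[0-9]+|[(),])",
                                 s))
      if (!length(m))
        stop(sprintf("predicate syntax error at line %d, column %d: %s",
                     ln, col, "unexpected character '" %+%
                       substring(s, 1, 1) %+% "'"))
      toks[[length(toks) + 1L]] <- list(text = m, line = ln, col = col)
      col <- col + nchar(m)
      s <- substring(s, nchar(m) + 1L)
    }
  }
  toks
}

`%+%` <- function(a, b) paste0(a, b)

#' Parse a gene-selection predicate
#'
#' Parses the Boolean predicate text used to select genes over species sets.
#' Atoms are `present_in(SET, k)` and `absent_in(SET, k)`, meaning "present
#' (absent) in at least k species of SET"; `k` may be omitted, in which case
#' the set's `defaultK` applies.  Connectives are `and`, `or`, `not` (case
#' insensitive), with parentheses for grouping.  Unknown set names and
#' thresholds exceeding the set size are rejected at parse time with the
#' offending line and column.
#'
#' @param text Predicate source (possibly multi-line).
#' @param sets Named list of [SpeciesSet][speciesSet()] objects declaring
#'   the legal set names.
#' @return A predicate AST: nested lists with `type` in `and`/`or`/`not`/
#'   `atom`; atoms carry `op` (`present`/`absent`), `set` and `k`.
#' @examples
#' sets <- list(UP = speciesSet("UP", c("a", "b", "c"), 1),
#'              LOW = speciesSet("LOW", c("d", "e"), 2))
#' ast <- parsePredicate("absent_in(UP, 2) and present_in(LOW)", sets)
#' unparsePredicate(ast)
#' @seealso [evaluatePredicate()], [unparsePredicate()]
#' @export
parsePredicate <- function(text, sets) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  toks <- .tokenizePredicate(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  err <- function(tok, what) {
    if (is.null(tok))
      stop("predicate syntax error at end of input: ", what)
    stop(sprintf("predicate syntax error at line %d, column %d: %s",
                 tok$line, tok$col, what))
  }
  advance <- function() { tok <- peek(); pos <<- pos + 1L; tok }
  expect <- function(lit) {
    tok <- advance()
    if (is.null(tok) || tok$text != lit)
      err(tok, paste0("expected '", lit, "'"))
    tok
  }
  kw <- function(tok) tolower(tok$text)

  parseAtom <- function(tok) {
    op <- if (kw(tok) == "present_in") "present" else "absent"
    expect("(")
    nameTok <- advance()
    if (is.null(nameTok) ||
        !grepl("^[A-Za-z_][A-Za-z0-9_]*$", nameTok$text))
      err(nameTok, "expected a species-set name")
    setName <- nameTok$text
    if (!setName %in% names(sets))
      err(nameTok, paste0("unknown species set '", setName, "'"))
    set <- sets[[setName]]
    k <- set@defaultK
    nxt <- peek()
    if (!is.null(nxt) && nxt$text == ",") {
      advance()
      kTok <- advance()
      if (is.null(kTok) || !grepl("^[0-9]+$", kTok$text))
        err(kTok, "expected an integer threshold k")
      k <- as.integer(kTok$text)
      if (k > length(set@members))
        err(kTok, sprintf("k = %d exceeds |%s| = %d", k, setName,
                          length(set@members)))
    }
    expect(")")
    list(type = "atom", op = op, set = setName, k = k)
  }

  parseFactor <- function() {
    tok <- advance()
    if (is.null(tok)) err(tok, "expected a factor")
    k <- kw(tok)
    if (k == "not")
      return(list(type = "not", child = parseFactor()))
    if (tok$text == "(") {
      node <- parseExpr()
      expect(")")
      return(node)
    }
    if (k %in% c("present_in", "absent_in"))
      return(parseAtom(tok))
    err(tok, paste0("unexpected token '", tok$text, "'"))
  }

  parseTerm <- function() {
    children <- list(parseFactor())
    while (!is.null(peek()) && kw(peek()) == "and") {
      advance()
      children[[length(children) + 1L]] <- parseFactor()
    }
    if (length(children) == 1L) children[[1L]]
    else list(type = "and", children = children)
  }

  parseExpr <- function() {
    children <- list(parseTerm())
    while (!is.null(peek()) && kw(peek()) == "or") {
      advance()
      children[[length(children) + 1L]] <- parseTerm()
    }
    if (length(children) == 1L) children[[1L]]
    else list(type = "or", children = children)
  }

  ast <- parseExpr()
  if (!is.null(peek()))
    err(peek(), paste0("trailing input '", peek()$text, "'"))
  ast
}

#' Render a predicate AST back to text
#'
#' `parsePredicate(unparsePredicate(ast), sets)` reproduces `ast` exactly.
#'
#' @param ast A predicate AST from [parsePredicate()].
#' @return A single predicate string.
#' @export
unparsePredicate <- function(ast) {
  switch(ast$type,
    atom = sprintf("%s_in(%s, %d)", ast$op, ast$set, ast$k),
    "not" = paste0("not ", .parenthesize(ast$child, c("and", "or"))),
    "and" = paste(vapply(ast$children, .parenthesize, character(1),
                         wrap = c("and", "or")), collapse = " and "),
    "or" = paste(vapply(ast$children, .parenthesize, character(1),
                        wrap = "or"), collapse = " or "),
    stop("unknown AST node type: ", ast$type))
}

.parenthesize <- function(node, wrap) {
  s <- unparsePredicate(node)
  if (node$type %in% wrap) paste0("(", s, ")") else s
}

# resolve a status with the two-valued policy if requested
.effectiveStatus <- function(status, strictTwoValued) {
  if (strictTwoValued) ifelse(status == "unevaluable", "absent", status)
  else status
}

.setStatuses <- function(gene, set, calls) {
  if (is.list(calls) && !is.null(calls$status)) calls <- calls$status
  if (!gene %in% rownames(calls))
    stop("no presence calls recorded for gene '", gene, "'")
  miss <- setdiff(set@members, colnames(calls))
  if (length(miss))
    stop("missing presence call(s) for gene '", gene, "' in species: ",
         paste(miss, collapse = ", "))
  calls[gene, set@members]
}

#' Set-level presence and absence conditions
#'
#' `presentInSet()` is true when the gene is `present` in at least `k`
#' member species of `set`; `absentInSet()` when its status is `absent` in
#' at least `k` members.  Under the default three-valued policy an
#' `unevaluable` call counts toward neither side; `strictTwoValued = TRUE`
#' collapses `unevaluable` to `absent`, mimicking a two-valued screen.
#'
#' @param gene Reference gene identifier (a rowname of the call matrix).
#' @param set A [SpeciesSet][speciesSet()].
#' @param k Minimum species count; defaults to the set's `defaultK`.
#' @param calls A status matrix (genes x species, values
#'   present/absent/unevaluable) or the list returned by
#'   [presenceMatrix()].
#' @param strictTwoValued Collapse `unevaluable` to `absent`.
#' @return A single logical.
#' @export
presentInSet <- function(gene, set, k = set@defaultK, calls,
                         strictTwoValued = FALSE) {
  st <- .effectiveStatus(.setStatuses(gene, set, calls), strictTwoValued)
  sum(st == "present") >= k
}

#' @rdname presentInSet
#' @export
absentInSet <- function(gene, set, k = set@defaultK, calls,
                        strictTwoValued = FALSE) {
  st <- .effectiveStatus(.setStatuses(gene, set, calls), strictTwoValued)
  sum(st == "absent") >= k
}

#' Evaluate a gene-selection predicate for one gene
#'
#' Standard Boolean semantics over the per-species presence calls; the
#' predicate is pure, so evaluation order cannot change the result.
#'
#' @inheritParams presentInSet
#' @param ast Predicate AST from [parsePredicate()].
#' @param sets Named list of [SpeciesSet][speciesSet()] objects (the same
#'   ones the predicate was parsed against).
#' @return A single logical.
#' @export
evaluatePredicate <- function(gene, ast, calls, sets,
                              strictTwoValued = FALSE) {
  lookup <- function(node) {
    set <- sets[[node$set]]
    if (is.null(set)) stop("predicate references undeclared set '",
                           node$set, "'")
    if (node$op == "present")
      presentInSet(gene, set, node$k, calls, strictTwoValued)
    else
      absentInSet(gene, set, node$k, calls, strictTwoValued)
  }
  .evalAST(ast, lookup)
}

# evaluator over an atom-resolution callback; shared with screenGenes(),
# where atoms may read from per-set call matrices
.evalAST <- function(ast, atomFn) {
  switch(ast$type,
    atom = atomFn(ast),
    "not" = !.evalAST(ast$child, atomFn),
    "and" = {
      for (ch in ast$children) if (!.evalAST(ch, atomFn)) return(FALSE)
      TRUE
    },
    "or" = {
      for (ch in ast$children) if (.evalAST(ch, atomFn)) return(TRUE)
      FALSE
    },
    stop("unknown AST node type: ", ast$type))
}

# all set names referenced by a predicate
.astSets <- function(ast) {
  switch(ast$type,
    atom = ast$set,
    "not" = .astSets(ast$child),
    unique(unlist(lapply(ast$children, .astSets))))
}
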