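## Gene-protein-reaction (GPR) rules
##
## A rule is a boolean expression over gene ids with AND/OR connectives,
## e.g. "(g1 and g2) or g3". Isozymes are OR'd, complex subunits AND'ed.
## The empty rule means "no gene association": the reaction is never
## disabled by gene knockouts. Rules are parsed once into nested lists:
## a leaf is a gene id string; an internal node is list(op = "and"|"or",
## args = list(...)).

.gpr_tokenize <- function(rule) {
  rule <- gsub("&&|&", " and ", rule)
  rule <- gsub("\\|\\||\\|", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  tokens <- strsplit(trimws(rule), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

#' Parse a gene rule string into an expression tree
#'
#' @param rule Rule string such as `"(g1 and g2) or g3"`; `""` or `NA` give
#'   the empty rule (`NULL`). `and`/`or` are case-insensitive; `&`/`|`
#'   synonyms are accepted. `or` binds looser than `and`, as in boolean
#'   algebra.
#' @return A rule tree (`NULL`, a gene id string, or a nested
#'   `list(op=, args=)`).
#' @export
parse_gpr <- function(rule) {
  if (length(rule) != 1L) stop("parse_gpr() takes a single string")
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- .gpr_tokenize(rule)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NA_character_
  advance <- function() { pos <<- pos + 1L; tokens[[pos - 1L]] }

  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    tok <- peek()
    if (is.na(tok)) stop("malformed gene rule: '", rule, "' (unexpected end)")
    if (tok == "(") {
      advance()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")") {
        stop("malformed gene rule: '", rule, "' (missing ')')")
      }
      advance()
      return(node)
    }
    if (tok == ")" || tolower(tok) %in% c("and", "or")) {
      stop("malformed gene rule: '", rule, "' (unexpected '", tok, "')")
    }
    advance()
  }

  tree <- parse_or()
  if (pos <= length(tokens)) {
    stop("malformed gene rule: '", rule, "' (trailing tokens)")
  }
  tree
}

#' Gene ids appearing in a rule
#'
#' @param rule Rule string or parsed tree.
#' @return Character vector of distinct gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(rule) {
  tree <- if (is.character(rule) || (!is.list(rule) && length(rule) == 1L && is.na(rule))) {
    parse_gpr(rule)
  } else {
    rule
  }
  walk <- function(node) {
    if (is.null(node)) return(character())
    if (is.character(node)) return(node)
    unlist(lapply(node$args, walk))
  }
  unique(walk(tree))
}

#' Format a rule tree as a canonical rule string
#'
#' Lower-cases the connectives and parenthesizes every non-leaf argument, so
#' equivalent rules entering from any dialect serialize identically.
#'
#' @param tree Parsed rule tree (or a rule string, normalized via parsing).
#' @return Canonical rule string (`""` for the empty rule).
#' @export
format_gpr <- function(tree) {
  if (is.character(tree) && !is.list(tree) && length(tree) == 1L &&
      !is.na(tree) && !(tree %in% c("and", "or"))) {
    ## could be a bare gene id or a rule string; parsing handles both
    tree <- parse_gpr(tree)
  }
  if (is.null(tree)) return("")
  fmt <- function(node) {
    if (is.character(node)) return(node)
    parts <- vapply(node$args, function(a) {
      if (is.character(a)) fmt(a) else paste0("(", fmt(a), ")")
    }, character(1))
    paste(parts, collapse = paste0(" ", node$op, " "))
  }
  fmt(tree)
}

#' Evaluate a gene rule under a knockout set
#'
#' Knocked-out genes are `FALSE`, all others `TRUE`; the empty rule is always
#' `TRUE` (a reaction with no gene association is unaffected by knockouts).
#'
#' @param rule Rule string or parsed tree.
#' @param knocked_out Character vector of gene ids deleted.
#' @return Logical: does the reaction retain enzymatic support?
#' @examples
#' evaluate_gene_rule("g1 or g2", "g1")   # TRUE, isozyme remains
#' evaluate_gene_rule("g1 and g2", "g1")  # FALSE, complex broken
#' @export
evaluate_gene_rule <- function(rule, knocked_out = character()) {
  tree <- if (is.character(rule)) parse_gpr(rule) else rule
  ev <- function(node) {
    if (is.null(node)) return(TRUE)
    if (is.character(node)) return(!(node %in% knocked_out))
    vals <- vapply(node$args, ev, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  ev(tree)
}
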