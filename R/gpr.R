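#' @useDynLib fluxcost, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# GPR expressions are nested lists: leaves are list(type = "gene", gene = id),
# internal nodes list(type = "and"|"or", children = list(...)) with >= 2
# children. All nodes carry class "gpr_expr".

gpr_node <- function(type, children) {
  if (length(children) == 1L) return(children[[1L]])
  structure(list(type = type, children = children), class = "gpr_expr")
}

gpr_leaf <- function(gene) {
  structure(list(type = "gene", gene = gene), class = "gpr_expr")
}

#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses boolean gene-association strings as used in SBML-FBC and COBRA
#' models: gene identifiers combined with `and` / `or` (case-insensitive;
#' `&`/`&&` and `|`/`||` are accepted) and parentheses. Unparenthesized `and`
#' binds tighter than `or`, the SBML-FBC convention. Gene identifiers are
#' opaque case-sensitive strings.
#'
#' @param text GPR string; must be non-empty.
#' @param reaction optional reaction id, used to make parse errors traceable.
#' @return a `gpr_expr` tree.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(text, reaction = NULL) {
  where <- if (is.null(reaction)) "" else paste0(" in GPR of reaction '", reaction, "'")
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("empty GPR string", where)
  }
  txt <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(txt), "\\s+")[[1L]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  is_op <- function(tk, op) {
    !is.na(tk) && ((op == "and" && tolower(tk) %in% c("and", "&", "&&")) ||
                   (op == "or"  && tolower(tk) %in% c("or", "|", "||")))
  }
  parse_or <- function() {
    kids <- list(parse_and())
    while (is_op(peek(), "or")) {
      advance()
      kids[[length(kids) + 1L]] <- parse_and()
    }
    gpr_node("or", kids)
  }
  parse_and <- function() {
    kids <- list(parse_atom())
    while (is_op(peek(), "and")) {
      advance()
      kids[[length(kids) + 1L]] <- parse_atom()
    }
    gpr_node("and", kids)
  }
  parse_atom <- function() {
    tk <- peek()
    if (is.na(tk)) stop("unexpected end of GPR expression", where)
    if (tk == "(") {
      advance()
      inner <- parse_or()
      if (!identical(peek(), ")")) stop("unbalanced parentheses", where)
      advance()
      return(inner)
    }
    if (tk == ")" || is_op(tk, "and") || is_op(tk, "or")) {
      stop("empty operand near '", tk, "'", where)
    }
    advance()
    gpr_leaf(tk)
  }
  out <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens in GPR near '", peek(), "'", where)
  out
}

#' Serialize a GPR expression
#'
#' Writes lowercase `and`/`or` with full parenthesization of internal nodes,
#' so that `parse_gpr(serialize_gpr(x))` is truth-table equivalent to `x`.
#'
#' @param expr a `gpr_expr`.
#' @return a single string.
#' @export
serialize_gpr <- function(expr) {
  if (expr$type == "gene") return(expr$gene)
  inner <- vapply(expr$children, serialize_gpr, character(1))
  paste0("(", paste(inner, collapse = paste0(" ", expr$type, " ")), ")")
}

#' @export
print.gpr_expr <- function(x, ...) {
  cat("<GPR> ", serialize_gpr(x), "\n", sep = "")
  invisible(x)
}

#' Genes appearing in a GPR expression
#'
#' @param expr a `gpr_expr`.
#' @return character vector of unique gene identifiers (leaf order).
#' @export
gpr_genes <- function(expr) {
  if (expr$type == "gene") return(expr$gene)
  unique(unlist(lapply(expr$children, gpr_genes)))
}

#' Evaluate a GPR under a gene-presence assignment
#'
#' Standard boolean semantics: an `and` node is true when all children are
#' true, an `or` node when any child is. Genes not listed in `present` are
#' absent (false) — this is how gene deletions propagate down to reactions.
#'
#' @param expr a `gpr_expr`.
#' @param present character vector of present (non-deleted) genes.
#' @return logical scalar.
#' @export
evaluate_gpr <- function(expr, present) {
  if (expr$type == "gene") return(expr$gene %in% present)
  vals <- vapply(expr$children, evaluate_gpr, logical(1), present = present)
  if (expr$type == "and") all(vals) else any(vals)
}

#' Is a gene a necessary prerequisite for a reaction?
#'
#' TRUE when deleting only this gene (all other genes present) turns the GPR
#' false — the condition under which an FBA knockout constrains the reaction
#' to zero flux.
#'
#' @param expr a `gpr_expr`.
#' @param gene gene identifier.
#' @return logical scalar.
#' @export
gene_is_necessary <- function(expr, gene) {
  !evaluate_gpr(expr, setdiff(gpr_genes(expr), gene))
}

#' Is a gene associated with (responsible for) a reaction?
#'
#' TRUE when the gene appears anywhere in the reaction's GPR expression,
#' regardless of redundancy. This membership test defines which reactions
#' contribute to a gene's function-loss cost.
#'
#' @param expr a `gpr_expr`.
#' @param gene gene identifier.
#' @return logical scalar.
#' @export
gene_is_associated <- function(expr, gene) {
  gene %in% gpr_genes(expr)
}

#' Isoenzyme set of a GPR expression
#'
#' The genes individually sufficient to satisfy the GPR (the expression
#' evaluates true with only that gene present). When at least two genes are
#' individually sufficient they form an isoenzyme set; a lone sufficient gene
#' is not an isoenzyme, and the empty set is returned.
#'
#' @param expr a `gpr_expr`.
#' @return character vector (possibly empty).
#' @examples
#' isoenzyme_set(parse_gpr("g1 or g2"))   # c("g1", "g2")
#' isoenzyme_set(parse_gpr("g1 and g2"))  # character(0)
#' @export
isoenzyme_set <- function(expr) {
  gs <- gpr_genes(expr)
  suff <- gs[vapply(gs, function(g) evaluate_gpr(expr, g), logical(1))]
  if (length(suff) >= 2L) suff else character(0)
}

#' Rewrite a GPR under the non-redundant isoenzyme assumption
#'
#' Replaces every `or` node with an `and` node, recursively, leaving the tree
#' shape and leaves unchanged. Under the rewritten rule every member of an
#' isoenzyme set is required for catalysis, so deleting any one member knocks
#' the reaction out.
#'
#' @param expr a `gpr_expr`.
#' @return a `gpr_expr` with no `or` nodes.
#' @export
or_to_and <- function(expr) {
  if (expr$type == "gene") return(expr)
  structure(list(type = "and", children = lapply(expr$children, or_to_and)),
            class = "gpr_expr")
}
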