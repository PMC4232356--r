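# Gene-protein-reaction (GPR) Boolean rules.
#
# Rules are strings over gene ids with case-insensitive AND / OR and
# parentheses. AND encodes enzyme complexes (all subunits needed -> min of
# expression), OR encodes isozymes (any suffices -> max). Without
# parentheses AND binds tighter than OR, the SBML-fbc convention.

#' Parse a GPR rule into an expression tree
#'
#' Recursive-descent parser: `expr := term (OR term)*`,
#' `term := factor (AND factor)*`, `factor := gene | "(" expr ")"`.
#'
#' @param rule GPR string, e.g. `"(A and B) or C"`. Empty or all-whitespace
#'   rules return `NULL` (no gene association).
#' @return A nested list: leaves are `list(gene = <id>)`, inner nodes
#'   `list(op = "and"/"or", args = list(...))`; `NULL` for an empty rule.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$rule <- rule
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks$type))
    gpr_error(st, "unexpected token")
  tree
}

gpr_tokenize <- function(rule) {
  pattern <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pattern, rule)[[1]]
  vals <- regmatches(rule, list(m))[[1]]
  type <- ifelse(vals == "(", "lparen",
          ifelse(vals == ")", "rparen",
          ifelse(tolower(vals) == "and", "and",
          ifelse(tolower(vals) == "or", "or", "gene"))))
  list(value = vals, type = type, pos = as.integer(m))
}

gpr_error <- function(st, msg) {
  pos <- if (st$pos <= length(st$toks$pos)) st$toks$pos[st$pos]
         else nchar(st$rule) + 1L
  stop("GPR parse error at position ", pos, " in '", st$rule, "': ", msg,
       call. = FALSE)
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks$type)) return(NA_character_)
  st$toks$type[st$pos]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (identical(gpr_peek(st), "or")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_factor(st))
  while (identical(gpr_peek(st), "and")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_factor(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_factor <- function(st) {
  tp <- gpr_peek(st)
  if (is.na(tp)) gpr_error(st, "dangling operator or empty expression")
  if (tp == "gene") {
    g <- st$toks$value[st$pos]; st$pos <- st$pos + 1L
    return(list(gene = g))
  }
  if (tp == "lparen") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), "rparen"))
      gpr_error(st, "unbalanced parentheses")
    st$pos <- st$pos + 1L
    return(inner)
  }
  gpr_error(st, paste0("unexpected '", st$toks$value[st$pos], "'"))
}

#' Evaluate a GPR tree against an expression profile
#'
#' AND nodes take the minimum of their children's values, OR nodes the
#' maximum. By default a gene without measurement is simply left out of the
#' min/max, so partial data stays usable; a rule whose leaves are all
#' unmeasured evaluates to `NA`. With `missing_poisons_and = TRUE` an AND
#' node with any unmeasured child is itself `NA` (a complex cannot form
#' without evidence for every subunit).
#'
#' @param tree result of [parse_gpr()] (may be `NULL`).
#' @param profile named numeric vector of non-negative expression levels.
#' @param missing_poisons_and see above.
#' @return A single expression level, or `NA` when no leaf has data.
#' @export
evaluate_gpr <- function(tree, profile, missing_poisons_and = FALSE) {
  if (is.null(tree)) return(NA_real_)
  if (!is.null(tree$gene)) {
    v <- unname(profile[tree$gene])
    return(if (length(v) == 0L || is.na(v)) NA_real_ else v)
  }
  vals <- vapply(tree$args, evaluate_gpr, 0,
                 profile = profile,
                 missing_poisons_and = missing_poisons_and)
  if (tree$op == "and") {
    if (missing_poisons_and && anyNA(vals)) return(NA_real_)
    if (all(is.na(vals))) return(NA_real_)
    return(min(vals, na.rm = TRUE))
  }
  if (all(is.na(vals))) return(NA_real_)
  max(vals, na.rm = TRUE)
}

#' Genes referenced by a model's GPR rules
#' @param model a `metabolic_model`.
#' @return Sorted character vector of gene ids.
#' @export
model_genes <- function(model) {
  leaves <- function(tree) {
    if (is.null(tree)) return(character(0))
    if (!is.null(tree$gene)) return(tree$gene)
    unlist(lapply(tree$args, leaves))
  }
  sort(unique(unlist(lapply(model$reactions,
                            function(r) leaves(parse_gpr(r$gpr))))))
}
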