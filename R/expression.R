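# Mapping absolute gene-expression profiles onto reactions and converting
# them to objective weights.

#' Read an expression profile from TSV
#'
#' Two columns, `gene_id <tab> value`; a header line is detected and
#' skipped when the second field is non-numeric. Values must be
#' non-negative; duplicate gene ids are an error.
#'
#' @param path file path.
#' @return Named numeric vector of expression levels.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 2L)
    stop("expression TSV must have exactly two columns, got ", ncol(tab))
  if (nrow(tab) > 0 && is.na(suppressWarnings(as.numeric(tab[1, 2]))))
    tab <- tab[-1, , drop = FALSE]
  vals <- as.numeric(tab[[2]])
  if (anyNA(vals)) stop("non-numeric expression value in '", path, "'")
  if (anyDuplicated(tab[[1]]))
    stop("duplicate gene ids in '", path, "': ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  if (any(vals < 0)) stop("negative expression values in '", path, "'")
  stats::setNames(vals, tab[[1]])
}

#' Map gene expression onto reactions through GPR rules
#'
#' Evaluates every reaction's GPR against the profile (AND = min, OR = max)
#' and then divides all mapped values by their maximum, so the resulting
#' per-reaction levels g lie in \[0, 1\]. Reactions without a GPR, or whose
#' rule has no measured gene, are `NA` ("missing"); downstream they receive
#' the neutral weight.
#'
#' @param model a `metabolic_model`.
#' @param profile named numeric vector of non-negative expression values.
#' @param missing_poisons_and passed to [evaluate_gpr()].
#' @return Object of class `reaction_expression`: a named numeric vector of
#'   normalized levels over all reactions (`NA` = missing), with the
#'   pre-normalization values in `attr(, "raw")`.
#' @export
map_expression <- function(model, profile, missing_poisons_and = FALSE) {
  if (any(profile < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  raw <- vapply(model$reactions, function(rxn) {
    evaluate_gpr(parse_gpr(rxn$gpr), profile,
                 missing_poisons_and = missing_poisons_and)
  }, 0)
  names(raw) <- reaction_ids(model)
  if (all(is.na(raw)))
    warning("no reaction received expression data; all levels are missing")
  mx <- suppressWarnings(max(raw, na.rm = TRUE))
  g <- if (is.finite(mx) && mx > 0) raw / mx else raw
  structure(g, raw = raw, class = "reaction_expression")
}

#' @export
print.reaction_expression <- function(x, ...) {
  cat("Reaction expression levels:", sum(!is.na(x)), "mapped,",
      sum(is.na(x)), "missing (of", length(x), "reactions)\n")
  invisible(x)
}

#' Convert reaction expression levels to objective weights
#'
#' In `efmin` mode the weight decreases linearly in expression,
#' `w = 1 - g`, so every reaction except a fully expressed one (g = 1) is
#' penalized; reactions with no data get the neutral weight 1. In `gimme`
#' mode only reactions expressed below the cutoff are penalized,
#' `w = max(g_cutoff - g, 0)`, and missing reactions get `g_cutoff`.
#'
#' @param rexpr a `reaction_expression` (or named numeric in \[0, 1\] with
#'   `NA` for missing).
#' @param mode `"efmin"` or `"gimme"`.
#' @param g_cutoff expression cutoff in (0, 1\], used only in `gimme` mode
#'   (default 0.05).
#' @return Named numeric weight vector over all reactions, with the mode
#'   and cutoff stored as attributes.
#' @export
compute_weights <- function(rexpr, mode = c("efmin", "gimme"),
                            g_cutoff = 0.05) {
  mode <- match.arg(mode)
  g <- as.numeric(rexpr)
  names(g) <- names(rexpr)
  if (any(g < -1e-12 | g > 1 + 1e-12, na.rm = TRUE))
    stop("expression levels must be normalized to [0, 1]; see map_expression()")
  if (mode == "efmin") {
    w <- 1 - g
    w[is.na(w)] <- 1
  } else {
    if (!is.numeric(g_cutoff) || length(g_cutoff) != 1L ||
        g_cutoff <= 0 || g_cutoff > 1)
      stop("g_cutoff must be a single value in (0, 1]")
    w <- pmax(g_cutoff - g, 0)
    w[is.na(w)] <- g_cutoff
  }
  structure(w, mode = mode,
            cutoff = if (mode == "gimme") g_cutoff else 1)
}

#' Write mapped expression and weights as TSV
#'
#' @param rexpr a `reaction_expression`.
#' @param weights weight vector from [compute_weights()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reaction_expression <- function(rexpr, weights, path) {
  tab <- data.frame(reaction_id = names(rexpr),
                    g = as.numeric(rexpr),
                    w = as.numeric(weights[names(rexpr)]))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
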