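# Rank-based meta-statistics for method-by-condition correlation tables.
#
# Two questions, two tests. (1) Within one table, do the methods differ at
# all? Pool every correlation, convert to percentile scores by ascending
# rank / N (mid-ranks on ties), and run a one-way ANOVA of score ~ method.
# (2) Across several independent tables, is one method consistently near
# the top? Rank the methods inside each table by their average score
# (rank 1 = best), take the geometric mean of a method's ranks as its rank
# product, and compute the exact tail probability by enumerating every
# rank tuple under the independent-uniform null.

#' Read a correlation table from TSV
#'
#' Rows are conditions (first column holds the condition label), remaining
#' columns are methods.
#'
#' @param path file path.
#' @return Numeric matrix, conditions x methods, with dimnames.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric entries in score table '", path, "'")
  m
}

# Accept a conditions x methods matrix or a named list method -> values;
# return the list form.
as_method_list <- function(table) {
  if (is.matrix(table)) {
    out <- lapply(seq_len(ncol(table)), function(j) unname(table[, j]))
    names(out) <- colnames(table)
    return(out)
  }
  if (is.list(table) && !is.null(names(table))) return(table)
  stop("expected a conditions x methods matrix or a named list")
}

#' Percentile-rank normalization of a score table
#'
#' Pools all N values, ranks them ascending with average (mid) ranks on
#' ties, and rescores each observation as rank / N, so scores lie in
#' (0, 1]. The transform is invariant to any strictly monotone
#' transformation of the input values.
#'
#' @param table conditions x methods matrix or named list method -> values.
#' @param midpoint use `(rank - 0.5) / N` instead of `rank / N`.
#' @return Same shape as the input, with percentile scores.
#' @export
percentile_scores <- function(table, midpoint = FALSE) {
  lst <- as_method_list(table)
  vals <- unlist(lst, use.names = FALSE)
  N <- length(vals)
  rk <- rank(vals, ties.method = "average")
  sc <- if (midpoint) (rk - 0.5) / N else rk / N
  scored <- utils::relist(sc, lst)
  if (is.matrix(table)) {
    out <- table
    for (j in seq_len(ncol(out))) out[, j] <- scored[[j]]
    return(out)
  }
  scored
}

#' One-way ANOVA F test on percentile scores
#'
#' Tests whether the method-by-condition scores differ between methods:
#' F is the ratio of between-method to within-method mean squares on
#' (K - 1, N - K) degrees of freedom, with the P value from the upper tail
#' of the F distribution. By default the table is percentile-rank
#' normalized first, making the test a rank-based comparison insensitive
#' to the scale of the raw correlations.
#'
#' @param table conditions x methods matrix or named list method -> values.
#' @param percentile normalize via [percentile_scores()] first
#'   (default TRUE).
#' @param midpoint passed to [percentile_scores()].
#' @return A list of class `anova_result`: `f_ratio`, `sigma_b2` and
#'   `sigma_w2` (between/within mean squares), `df_between`, `df_within`,
#'   `p_value`.
#' @export
anova_f_test <- function(table, percentile = TRUE, midpoint = FALSE) {
  lst <- as_method_list(table)
  if (length(lst) < 2L) stop("need at least two methods")
  if (percentile) lst <- percentile_scores(lst, midpoint = midpoint)
  vals <- unlist(lst, use.names = FALSE)
  grp <- factor(rep(names(lst), lengths(lst)), levels = names(lst))
  N <- length(vals); K <- nlevels(grp)
  if (N <= K) stop("need more observations than methods")
  fit <- stats::anova(stats::lm(vals ~ grp))
  msb <- fit[["Mean Sq"]][1]; msw <- fit[["Mean Sq"]][2]
  if (msw <= .Machine$double.eps) {
    warning("zero within-method variance; F is infinite, P reported as 0")
    f <- Inf; p <- 0
  } else {
    f <- fit[["F value"]][1]; p <- fit[["Pr(>F)"]][1]
  }
  structure(list(f_ratio = f, sigma_b2 = msb, sigma_w2 = msw,
                 df_between = K - 1L, df_within = N - K, p_value = p),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, P = %.3g\n",
              x$df_between, x$df_within, x$f_ratio, x$p_value))
  invisible(x)
}

#' Per-table method ranks from average scores
#'
#' Averages each method's scores within a table (unrounded) and ranks the
#' methods descending, rank 1 = best, average (mid) ranks on ties.
#'
#' @param table conditions x methods matrix or named list method -> values.
#' @return Named numeric rank vector.
#' @export
method_ranks <- function(table) {
  lst <- as_method_list(table)
  avg <- vapply(lst, mean, 0)
  rank(-avg, ties.method = "average")
}

#' Exhaustive rank-product permutation test
#'
#' Within each of T independent tables, methods are ranked by their
#' unrounded average scores (descending, mid-ranks on ties). The rank
#' product of a method is the geometric mean of its T ranks. Under the
#' null, the method's rank in table t is uniform on {1, ..., n_t}
#' independently across tables; the P value is the exact fraction of all
#' `prod(n_t)` rank tuples whose product is less than or equal to the
#' observed product -- a rational number with denominator `prod(n_t)`.
#'
#' @param tables list of tables (each a conditions x methods matrix, a
#'   named list method -> values, or an already-averaged named numeric
#'   vector of per-method scores).
#' @param method method id; must appear in every table.
#' @return A list of class `rank_product_result`: `ranks` (per table),
#'   `rank_product`, `p_value`, `favorable` and `denominator` (the exact
#'   rational P is favorable / denominator), `table_sizes`.
#' @export
rank_product_test <- function(tables, method) {
  stopifnot(length(tables) >= 1L)
  ranks_all <- lapply(tables, function(tb) {
    if (is.numeric(tb) && !is.matrix(tb) && !is.null(names(tb)))
      rank(-tb, ties.method = "average")
    else method_ranks(tb)
  })
  sizes <- vapply(ranks_all, length, 0L)
  miss <- vapply(ranks_all, function(r) !method %in% names(r), TRUE)
  if (any(miss))
    stop("method '", method, "' missing from table(s) ",
         paste(which(miss), collapse = ", "))
  obs <- vapply(ranks_all, function(r) r[[method]], 0)
  obs_prod <- prod(obs)
  tuples <- expand.grid(lapply(sizes, seq_len))
  prods <- Reduce(`*`, tuples)
  favorable <- sum(prods <= obs_prod + 1e-12)
  structure(list(ranks = obs, rank_product = obs_prod^(1 / length(obs)),
                 p_value = favorable / prod(sizes),
                 favorable = favorable, denominator = prod(sizes),
                 table_sizes = sizes),
            class = "rank_product_result")
}

#' @export
print.rank_product_result <- function(x, ...) {
  cat(sprintf("rank product = %.4g (ranks: %s), P = %d/%d = %.4g\n",
              x$rank_product, paste(x$ranks, collapse = ", "),
              x$favorable, x$denominator, x$p_value))
  invisible(x)
}

#' Bundled benchmark correlation tables
#'
#' Transcriptions of three published method-by-condition Pearson
#' correlation tables benchmarking flux-prediction methods: yeast exchange
#' fluxes at two glucose-uptake rates (7 methods x 2 conditions),
#' wild-type E. coli intracellular fluxes across five dilution rates
#' (8 methods x 5 conditions), and E. coli single-gene-knockout strains
#' (7 methods x 24 conditions). Correlations printed below the table
#' resolution ("<0.01") are transcribed as 0.005.
#'
#' @return Named list of three conditions x methods matrices.
#' @export
benchmark_tables <- function() {
  files <- c(yeast_exchange = "yeast_exchange_rho.tsv",
             ecoli_dilution = "ecoli_dilution_rho.tsv",
             ecoli_knockout = "ecoli_knockout_rho.tsv")
  lapply(files, function(f)
    read_score_table(system.file("extdata", f, package = "efmin",
                                 mustWork = TRUE)))
}
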