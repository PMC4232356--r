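# Comparing predicted flux vectors against measured fluxes.

#' Read measured fluxes from TSV
#'
#' Two columns, `reaction_id <tab> value`; header detected as in
#' [read_expression()].
#'
#' @param path file path.
#' @return Named numeric vector of measured fluxes.
#' @export
read_measured_fluxes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 2L)
    stop("measured-flux TSV must have two columns, got ", ncol(tab))
  if (nrow(tab) > 0 && is.na(suppressWarnings(as.numeric(tab[1, 2]))))
    tab <- tab[-1, , drop = FALSE]
  vals <- as.numeric(tab[[2]])
  if (anyNA(vals)) stop("non-numeric flux value in '", path, "'")
  if (anyDuplicated(tab[[1]]))
    stop("duplicate reaction ids in '", path, "'")
  stats::setNames(vals, tab[[1]])
}

as_named_fluxes <- function(x) {
  if (inherits(x, "flux_distribution")) x$fluxes else x
}

#' Match predicted and measured fluxes on a common scale
#'
#' Rescales both vectors so the reference reaction's magnitude equals
#' `reference_value` (e.g. glucose uptake = 100), then pairs the reactions
#' present in both. Measurements naming reactions absent from the
#' prediction are dropped with a warning. Pearson correlation is invariant
#' to this common rescaling; it is applied so that SSE is reported on the
#' conventional scale.
#'
#' @param pred a `flux_distribution` or named numeric vector.
#' @param meas named numeric vector of measured fluxes.
#' @param reference reaction id present, with nonzero flux, in both.
#' @param reference_value target magnitude (default 100).
#' @return A list with aligned numeric vectors `pred` and `meas`, `n`, and
#'   `dropped` (measurement ids without a predicted counterpart).
#' @export
match_and_scale <- function(pred, meas, reference, reference_value = 100) {
  p <- as_named_fluxes(pred)
  for (nmv in list(p, meas)) {
    if (!reference %in% names(nmv) || abs(nmv[[reference]]) < 1e-12)
      stop("reference reaction '", reference,
           "' must carry nonzero flux in both vectors")
  }
  p <- p * reference_value / abs(p[[reference]])
  m <- meas * reference_value / abs(meas[[reference]])
  common <- intersect(names(m), names(p))
  dropped <- setdiff(names(m), names(p))
  if (length(common) == 0L) stop("no reactions shared between vectors")
  if (length(dropped))
    warning("dropping measured reaction(s) absent from prediction: ",
            paste(dropped, collapse = ", "))
  list(pred = unname(p[common]), meas = unname(m[common]),
       ids = common, n = length(common), dropped = dropped)
}

#' Pearson correlation with two-sided P value
#'
#' Standard Pearson rho; significance from the exact t transform
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (two-sided), as implemented by [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length, `n >= 3` for a finite P.
#' @return List with `rho`, `p_value`, `n`. Zero variance in either vector
#'   gives `rho = NA` with a warning rather than a fabricated value.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined (fewer than 2 points or zero variance)")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(rho = unname(ct$estimate),
       p_value = if (n >= 3) ct$p.value else NA_real_, n = n)
}

#' Sum of squared error
#' @param x,y numeric vectors of equal length.
#' @return `sum((x - y)^2)`, in squared flux units.
#' @export
sse <- function(x, y) {
  stopifnot(length(x) == length(y))
  sum((x - y)^2)
}

#' Drop fluxes stuck at finite bounds
#'
#' Alternative-optima artifacts in FBA-type solutions show up as fluxes
#' saturating a finite bound. Reactions whose flux lies within
#' `tolerance * max(1, |bound|)` of a finite lower or upper bound are
#' removed from the vector; the removed ids are recorded in
#' `attr(, "outliers_removed")`.
#'
#' @param pred a `flux_distribution` or named numeric vector.
#' @param model the `metabolic_model` supplying the bounds.
#' @param tolerance relative closeness to the bound (default 1e-6).
#' @return The flux vector without the saturated reactions.
#' @export
remove_bound_outliers <- function(pred, model, tolerance = 1e-6) {
  p <- as_named_fluxes(pred)
  bounds <- reaction_bounds(model)
  at_bound <- vapply(names(p), function(rid) {
    if (!rid %in% rownames(bounds)) return(FALSE)
    lb <- bounds[rid, "lb"]; ub <- bounds[rid, "ub"]
    (is.finite(ub) && ub != 0 &&
       abs(p[[rid]] - ub) <= tolerance * max(1, abs(ub))) ||
    (is.finite(lb) && lb != 0 &&
       abs(p[[rid]] - lb) <= tolerance * max(1, abs(lb)))
  }, TRUE)
  out <- p[!at_bound]
  attr(out, "outliers_removed") <- names(p)[at_bound]
  out
}

#' Evaluate a flux prediction against measurements
#'
#' Convenience wrapper: optional bound-outlier removal, common rescaling to
#' the reference reaction, Pearson correlation with P value, and SSE.
#'
#' @param pred a `flux_distribution` or named numeric vector.
#' @param meas named numeric vector of measured fluxes.
#' @param reference,reference_value see [match_and_scale()].
#' @param model needed only when `drop_bound_outliers = TRUE`.
#' @param drop_bound_outliers remove bound-saturated predicted fluxes
#'   before pairing.
#' @param tolerance passed to [remove_bound_outliers()].
#' @return A list of class `evaluation_result`: `rho`, `p_value`, `sse`,
#'   `n`, `outliers_removed`.
#' @export
evaluate_prediction <- function(pred, meas, reference,
                                reference_value = 100, model = NULL,
                                drop_bound_outliers = FALSE,
                                tolerance = 1e-6) {
  outliers <- character(0)
  if (drop_bound_outliers) {
    if (is.null(model))
      stop("drop_bound_outliers = TRUE requires the model")
    pred <- remove_bound_outliers(pred, model, tolerance)
    outliers <- attr(pred, "outliers_removed")
  }
  ms <- match_and_scale(pred, meas, reference, reference_value)
  pp <- pearson_with_p(ms$pred, ms$meas)
  structure(list(rho = pp$rho, p_value = pp$p_value,
                 sse = sse(ms$pred, ms$meas), n = ms$n,
                 outliers_removed = outliers),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("rho = %.4f (P = %.3g), SSE = %.4g, n = %d\n",
              x$rho, x$p_value, x$sse, x$n))
  if (length(x$outliers_removed))
    cat("bound outliers removed:",
        paste(x$outliers_removed, collapse = ", "), "\n")
  invisible(x)
}
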