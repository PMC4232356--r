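# Core solver: expression-weighted flux minimization.
#
# The optimization is
#     min  sum_i w_i |r_i|
#     s.t. S r = 0,  r_L <= r <= r_U,  r_B >= epsilon
# linearized with one auxiliary magnitude variable per reaction,
# t_i >= r_i and t_i >= -r_i, and objective sum_i w_i t_i. At any optimum
# t_i = |r_i| wherever w_i > 0; reactions with w_i = 0 keep their t_i
# constrained so that a variability analysis over the objective remains
# meaningful, but contribute nothing to the cost.

#' Solver configuration for E-Fmin
#'
#' @param epsilon minimum biomass flux, mmol/(gDW h). Any positive value
#'   works: the solution scales linearly in epsilon, so results normalized
#'   to a common reference flux are invariant to it. Default 0.01.
#' @param big_bound finite stand-in magnitude for infinite bounds, for use
#'   with solvers lacking native unboundedness. The internal simplex
#'   handles `Inf` natively, so the default leaves bounds untouched.
#' @param tolerance feasibility/zero tolerance used when classifying
#'   active reactions and checking mass balance.
#' @return A list of class `efmin_config`.
#' @export
efmin_config <- function(epsilon = 0.01, big_bound = Inf,
                         tolerance = 1e-8) {
  stopifnot(epsilon > 0, big_bound > 0, tolerance > 0)
  structure(list(epsilon = epsilon, big_bound = big_bound,
                 tolerance = tolerance), class = "efmin_config")
}

# Shared constraint-assembly: stoichiometry rows and bound vectors.
flux_lp_parts <- function(model, big_bound = Inf) {
  S <- stoichiometric_matrix(model)
  bounds <- reaction_bounds(model)
  lb <- bounds[, "lb"]; ub <- bounds[, "ub"]
  if (is.finite(big_bound)) {
    lb[!is.finite(lb)] <- -big_bound
    ub[!is.finite(ub)] <- big_bound
  }
  list(S = S, rids = colnames(S), lb = lb, ub = ub, n = ncol(S))
}

# Rows t_i >= +-r_i in <= form over the stacked variable vector (r, t).
abs_link_rows <- function(n) {
  rbind(cbind(diag(n), -diag(n)),    #  r - t <= 0
        cbind(-diag(n), -diag(n)))   # -r - t <= 0
}

as_flux_distribution <- function(x, rids, model, method, weights = NULL,
                                 tolerance = 1e-8) {
  if (x$status != "optimal") {
    return(structure(list(fluxes = stats::setNames(rep(NA_real_,
                                                       length(rids)), rids),
                          objective = NA_real_, status = x$status,
                          biomass_flux = NA_real_, method = method,
                          weights = weights),
                     class = "flux_distribution"))
  }
  fluxes <- stats::setNames(x$x[seq_along(rids)], rids)
  fluxes[abs(fluxes) < tolerance] <- 0
  structure(list(fluxes = fluxes, objective = x$objective,
                 status = "optimal",
                 biomass_flux = unname(fluxes[model$biomass]),
                 method = method, weights = weights),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("Flux distribution (", x$method, "): status ", x$status, sep = "")
  if (identical(x$status, "optimal")) {
    cat(", objective ", format(x$objective),
        ", biomass flux ", format(x$biomass_flux),
        ", ", sum(abs(x$fluxes) > 0), " active reactions", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Reactions carrying flux in a solution
#' @param sol a `flux_distribution`.
#' @param tolerance absolute flux threshold.
#' @return Character vector of reaction ids with `|flux| > tolerance`.
#' @export
active_reactions <- function(sol, tolerance = 1e-6) {
  names(sol$fluxes)[abs(sol$fluxes) > tolerance]
}

#' Solve the expression-weighted flux-minimization problem
#'
#' Minimizes the weighted sum of flux magnitudes subject to steady-state
#' mass balance, directionality bounds, and a minimum biomass flux
#' `r_B >= epsilon`. More generally, a set of required reactions with
#' individual minimum fluxes can be supplied via `required`; the biomass
#' default is the recommended, context-independent choice.
#'
#' @param model a validated `metabolic_model`.
#' @param weights named weight vector from [compute_weights()]; reactions
#'   not named default to weight 1. `NULL` means uniform weights (plain
#'   flux minimization guided by no expression data).
#' @param config an [efmin_config()].
#' @param required named numeric vector of minimum fluxes for required
#'   reactions; default `c(<biomass> = epsilon)`.
#' @return A `flux_distribution` with fields `fluxes`, `objective`,
#'   `status` (`"optimal"`, `"infeasible"` or `"unbounded"`) and
#'   `biomass_flux`.
#' @examples
#' toy <- build_toy_network()
#' sol <- solve_efmin(toy)           # uniform weights: shortest route wins
#' active_reactions(sol)
#' @export
solve_efmin <- function(model, weights = NULL, config = efmin_config(),
                        required = NULL) {
  parts <- flux_lp_parts(model, config$big_bound)
  n <- parts$n
  w <- rep(1, n); names(w) <- parts$rids
  if (!is.null(weights)) {
    unknown <- setdiff(names(weights), parts$rids)
    if (length(unknown))
      stop("weights name unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    w[names(weights)] <- as.numeric(weights)
  }
  if (any(w < 0)) stop("weights must be non-negative")
  if (is.null(required))
    required <- stats::setNames(config$epsilon, model$biomass)
  req_idx <- match(names(required), parts$rids)
  if (anyNA(req_idx))
    stop("required reaction(s) not in model: ",
         paste(names(required)[is.na(req_idx)], collapse = ", "))

  A_eq <- cbind(parts$S, matrix(0, nrow(parts$S), n))
  req_rows <- matrix(0, length(required), 2 * n)
  req_rows[cbind(seq_along(req_idx), req_idx)] <- -1   # -r_j <= -min_j
  A_ub <- rbind(abs_link_rows(n), req_rows)
  b_ub <- c(rep(0, 2 * n), -as.numeric(required))

  res <- lp_solve(c(rep(0, n), unname(w)),
                  A_eq = A_eq, b_eq = rep(0, nrow(parts$S)),
                  A_ub = A_ub, b_ub = b_ub,
                  lower = c(parts$lb, rep(0, n)),
                  upper = c(parts$ub, rep(Inf, n)))
  out <- as_flux_distribution(res, parts$rids, model, "efmin",
                              weights = w, tolerance = config$tolerance)
  out$epsilon <- config$epsilon
  out$required <- required
  out
}

#' Rescale a flux distribution to a reference reaction
#'
#' Multiplies every flux by `reference_value / |flux(reference)|`, the
#' standard way to report minimized fluxes on a measured scale (e.g.
#' glucose uptake = 100 mmol/(gDW h)). Because the E-Fmin solution scales
#' linearly with epsilon, normalized solutions are invariant to it.
#'
#' @param sol a `flux_distribution` with status `"optimal"`.
#' @param reference reaction id carrying nonzero flux.
#' @param reference_value target magnitude for the reference reaction.
#' @param tolerance smallest reference magnitude accepted.
#' @return The rescaled `flux_distribution`.
#' @export
normalize_fluxes <- function(sol, reference, reference_value = 100,
                             tolerance = 1e-9) {
  if (!identical(sol$status, "optimal"))
    stop("cannot normalize a non-optimal solution (status: ", sol$status, ")")
  if (!reference %in% names(sol$fluxes))
    stop("reference reaction '", reference, "' not in solution")
  ref <- sol$fluxes[[reference]]
  if (abs(ref) <= tolerance)
    stop("reference reaction '", reference,
         "' carries (near-)zero flux; cannot normalize")
  fac <- reference_value / abs(ref)
  sol$fluxes <- sol$fluxes * fac
  sol$objective <- sol$objective * fac
  sol$biomass_flux <- sol$biomass_flux * fac
  sol
}

#' Flux variability analysis at the E-Fmin optimum
#'
#' For each reaction, minimizes and maximizes its flux subject to the
#' original constraints plus the weighted-magnitude budget
#' `sum_i w_i t_i <= fraction * z*`, where `z*` is the optimal objective.
#' Degenerate (zero-width) ranges certify a unique optimum; wide ranges
#' expose alternative optimal routings.
#'
#' @param model,weights,config,required as in [solve_efmin()].
#' @param fraction objective slack multiplier, `>= 1`; 1 restricts to exact
#'   alternative optima.
#' @param solution an existing [solve_efmin()] result to reuse (otherwise
#'   it is recomputed).
#' @return A data frame of class `fva_range` with columns `reaction`,
#'   `min_flux`, `max_flux`.
#' @export
run_fva <- function(model, weights = NULL, config = efmin_config(),
                    required = NULL, fraction = 1.0, solution = NULL) {
  stopifnot(fraction >= 1)
  if (is.null(solution))
    solution <- solve_efmin(model, weights, config, required)
  if (!identical(solution$status, "optimal"))
    stop("E-Fmin did not solve to optimality (status: ",
         solution$status, ")")
  parts <- flux_lp_parts(model, config$big_bound)
  n <- parts$n
  w <- solution$weights
  required <- solution$required

  A_eq <- cbind(parts$S, matrix(0, nrow(parts$S), n))
  req_idx <- match(names(required), parts$rids)
  req_rows <- matrix(0, length(required), 2 * n)
  req_rows[cbind(seq_along(req_idx), req_idx)] <- -1
  budget <- c(rep(0, n), unname(w))
  A_ub <- rbind(abs_link_rows(n), req_rows, budget)
  # tiny relative slack keeps the budget row numerically feasible at the
  # returned vertex even when fraction = 1
  b_ub <- c(rep(0, 2 * n), -as.numeric(required),
            fraction * solution$objective +
              1e-10 * max(1, abs(solution$objective)))
  lower <- c(parts$lb, rep(0, n))
  upper <- c(parts$ub, rep(Inf, n))

  mins <- maxs <- numeric(n)
  for (j in seq_len(n)) {
    obj <- numeric(2 * n); obj[j] <- 1
    lo <- lp_solve(obj, A_eq = A_eq, b_eq = rep(0, nrow(parts$S)),
                   A_ub = A_ub, b_ub = b_ub, lower = lower, upper = upper)
    hi <- lp_solve(obj, A_eq = A_eq, b_eq = rep(0, nrow(parts$S)),
                   A_ub = A_ub, b_ub = b_ub, lower = lower, upper = upper,
                   maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem for reaction '", parts$rids[j],
           "' returned status ", lo$status, "/", hi$status)
    mins[j] <- lo$objective; maxs[j] <- hi$objective
  }
  zero <- abs(mins) < config$tolerance; mins[zero] <- 0
  zero <- abs(maxs) < config$tolerance; maxs[zero] <- 0
  structure(data.frame(reaction = parts$rids, min_flux = mins,
                       max_flux = maxs, stringsAsFactors = FALSE),
            class = c("fva_range", "data.frame"))
}

#' Write fluxes (and optional FVA ranges) as TSV
#'
#' @param sol a `flux_distribution`.
#' @param path output path.
#' @param fva optional `fva_range` from [run_fva()].
#' @return `path`, invisibly.
#' @export
write_fluxes <- function(sol, path, fva = NULL) {
  tab <- data.frame(reaction_id = names(sol$fluxes),
                    flux = as.numeric(sol$fluxes))
  if (!is.null(fva)) {
    idx <- match(tab$reaction_id, fva$reaction)
    tab$fva_min <- fva$min_flux[idx]
    tab$fva_max <- fva$max_flux[idx]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
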