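# Benchmark methods: classical FBA, FBA with secondary flux minimization,
# GIMME, and E-Flux. All share the steady-state feasibility contract
# S r = 0 with directionality bounds; they differ in objective and in how
# expression data enters (weights for GIMME, bounds for E-Flux).

#' Classical flux balance analysis
#'
#' Maximizes the flux of one reaction (typically biomass) subject to
#' steady-state mass balance and bounds. Without at least one bounded
#' uptake the LP is unbounded, which is reported as such rather than as an
#' error: it is the expected outcome for a fully unconstrained network.
#'
#' @param model a validated `metabolic_model`.
#' @param objective_reaction reaction id to maximize; defaults to the
#'   model's biomass reaction.
#' @param big_bound finite stand-in for infinite bounds (default: none).
#' @return A `flux_distribution`; `status` is `"unbounded"` when the
#'   objective has no finite maximum.
#' @export
solve_fba <- function(model, objective_reaction = model$biomass,
                      big_bound = Inf) {
  parts <- flux_lp_parts(model, big_bound)
  j <- match(objective_reaction, parts$rids)
  if (is.na(j)) stop("objective reaction '", objective_reaction,
                     "' not in model")
  obj <- numeric(parts$n); obj[j] <- 1
  res <- lp_solve(obj, A_eq = parts$S, b_eq = rep(0, nrow(parts$S)),
                  lower = parts$lb, upper = parts$ub, maximize = TRUE)
  out <- as_flux_distribution(res, parts$rids, model, "fba")
  out$objective_reaction <- objective_reaction
  out
}

#' FBA with flux minimization as a secondary objective
#'
#' First maximizes the objective reaction (classical FBA), then fixes that
#' optimum and minimizes the total absolute flux `sum_i |r_i|` over the
#' optimal face. This removes the bound-saturated outlier fluxes that
#' alternative FBA optima can produce.
#'
#' @inheritParams solve_fba
#' @return A `flux_distribution`; `objective` is the minimized total
#'   absolute flux, `fba_optimum` records the fixed primary optimum.
#' @export
solve_pfba <- function(model, objective_reaction = model$biomass,
                       big_bound = Inf) {
  primary <- solve_fba(model, objective_reaction, big_bound)
  if (!identical(primary$status, "optimal")) return(primary)
  vstar <- primary$fluxes[[objective_reaction]]
  parts <- flux_lp_parts(model, big_bound)
  n <- parts$n
  j <- match(objective_reaction, parts$rids)
  fix_row <- numeric(2 * n); fix_row[j] <- 1
  A_eq <- rbind(cbind(parts$S, matrix(0, nrow(parts$S), n)), fix_row)
  b_eq <- c(rep(0, nrow(parts$S)), vstar)
  res <- lp_solve(c(rep(0, n), rep(1, n)),
                  A_eq = A_eq, b_eq = b_eq,
                  A_ub = abs_link_rows(n), b_ub = rep(0, 2 * n),
                  lower = c(parts$lb, rep(0, n)),
                  upper = c(parts$ub, rep(Inf, n)))
  out <- as_flux_distribution(res, parts$rids, model, "pfba")
  out$objective_reaction <- objective_reaction
  out$fba_optimum <- vstar
  out
}

#' GIMME configuration
#'
#' @param rmf_reactions ids of required-metabolic-functionality reactions;
#'   `NULL` means the model's biomass reaction.
#' @param rmf_threshold each RMF reaction must carry at least this fraction
#'   of its own FBA maximum (default 0.90).
#' @param g_cutoff expression cutoff below which reactions are penalized
#'   (default 0.05).
#' @return A list of class `gimme_config`.
#' @export
gimme_config <- function(rmf_reactions = NULL, rmf_threshold = 0.90,
                         g_cutoff = 0.05) {
  stopifnot(rmf_threshold > 0, rmf_threshold <= 1,
            g_cutoff > 0, g_cutoff <= 1)
  structure(list(rmf_reactions = rmf_reactions,
                 rmf_threshold = rmf_threshold, g_cutoff = g_cutoff),
            class = "gimme_config")
}

#' GIMME: penalize below-cutoff reactions under an RMF constraint
#'
#' Computes the FBA maximum of each required reaction, constrains it to at
#' least `rmf_threshold` times that maximum, and minimizes
#' `sum_i w_i |r_i|` with `w_i = max(g_cutoff - g_i, 0)` (missing
#' expression counts as `g_cutoff`).
#'
#' @param model a validated `metabolic_model`.
#' @param rexpr a `reaction_expression` from [map_expression()].
#' @param config a [gimme_config()].
#' @param big_bound finite stand-in for infinite bounds.
#' @return A `flux_distribution` (`method = "gimme"`).
#' @export
solve_gimme <- function(model, rexpr, config = gimme_config(),
                        big_bound = Inf) {
  rmf <- config$rmf_reactions
  if (is.null(rmf)) rmf <- model$biomass
  mins <- vapply(rmf, function(rid) {
    fba <- solve_fba(model, rid, big_bound)
    if (!identical(fba$status, "optimal"))
      stop("FBA for RMF reaction '", rid, "' returned status ",
           fba$status, "; bound an uptake first")
    config$rmf_threshold * fba$fluxes[[rid]]
  }, 0)
  w <- compute_weights(rexpr, mode = "gimme", g_cutoff = config$g_cutoff)
  out <- solve_efmin(model, weights = w,
                     config = efmin_config(big_bound = big_bound),
                     required = stats::setNames(mins, rmf))
  out$method <- "gimme"
  out
}

#' E-Flux configuration
#'
#' @param bound_scale flux magnitude multiplying the normalized expression
#'   level to form each data-carrying reaction's capacity. `NULL` picks the
#'   model's largest finite bound magnitude, or 1000 when every bound is
#'   infinite.
#' @return A list of class `eflux_config`.
#' @export
eflux_config <- function(bound_scale = NULL) {
  if (!is.null(bound_scale)) stopifnot(bound_scale > 0)
  structure(list(bound_scale = bound_scale), class = "eflux_config")
}

#' E-Flux: expression-scaled bounds with biomass maximization
#'
#' Reactions with mapped expression data get capacity
#' `ub = bound_scale * g` (and `lb = -bound_scale * g` if reversible);
#' reactions without data keep their existing bounds. The objective
#' reaction's flux is then maximized. An all-zero expression route to the
#' objective yields an optimum of 0, not an error.
#'
#' @param model a validated `metabolic_model`.
#' @param rexpr a `reaction_expression` from [map_expression()].
#' @param config an [eflux_config()].
#' @param objective_reaction reaction to maximize (default biomass).
#' @return A `flux_distribution` (`method = "eflux"`).
#' @export
solve_eflux <- function(model, rexpr, config = eflux_config(),
                        objective_reaction = model$biomass) {
  scale <- config$bound_scale
  if (is.null(scale)) {
    finite <- abs(reaction_bounds(model))
    finite <- finite[is.finite(finite) & finite > 0]
    scale <- if (length(finite)) max(finite) else 1000
  }
  g <- as.numeric(rexpr); names(g) <- names(rexpr)
  model$reactions <- lapply(model$reactions, function(rxn) {
    gi <- g[[rxn$id]]
    if (!is.na(gi)) {
      rxn$ub <- scale * gi
      rxn$lb <- if (rxn$reversible) -scale * gi else 0
    }
    rxn
  })
  out <- solve_fba(model, objective_reaction)
  out$method <- "eflux"
  out$bound_scale <- scale
  out
}
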