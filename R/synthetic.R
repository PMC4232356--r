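# Synthetic fixtures: the nine-reaction toy network, random expression
# profiles, planted-flux parallel-path conditions, and a balanced-cycle
# network. Everything is generated in code from a seed, so the whole
# package is testable without any external model or dataset.

# Run fn with a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' The nine-reaction toy network
#'
#' A substrate is taken up (r1) into intracellular metabolite A, which can
#' leave as a secreted product (r2: path P1) or reach the biomass precursor
#' B through three routes: directly (r3; path P2 = r1, r3, r9), via C
#' (r4, r5; path P3 = r1, r4, r5, r9), or via D and E (r6, r7, r8; path
#' P4 = r1, r6, r7, r8, r9). B is drained by the biomass reaction r9. Five
#' internal metabolites (A--E) give five steady-state constraints for nine
#' unknown fluxes, so the system is underdetermined -- the setting in which
#' weighted flux minimization picks a route. All reactions are
#' irreversible and each carries a single identity gene (g1--g9).
#'
#' @return A validated `metabolic_model` with an attribute `pathways`
#'   listing the reaction sets of P1--P4.
#' @export
build_toy_network <- function() {
  mets <- data.frame(
    id = c("S_ext", "A", "B", "C", "D", "E", "P_ext", "BIO_ext"),
    internal = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  mets$name <- mets$id
  rxns <- list(
    reaction("r1", c(S_ext = -1, A = 1), gpr = "g1"),
    reaction("r2", c(A = -1, P_ext = 1), gpr = "g2"),
    reaction("r3", c(A = -1, B = 1), gpr = "g3"),
    reaction("r4", c(A = -1, C = 1), gpr = "g4"),
    reaction("r5", c(C = -1, B = 1), gpr = "g5"),
    reaction("r6", c(A = -1, D = 1), gpr = "g6"),
    reaction("r7", c(D = -1, E = 1), gpr = "g7"),
    reaction("r8", c(E = -1, B = 1), gpr = "g8"),
    reaction("r9", c(B = -1, BIO_ext = 1), gpr = "g9"))
  model <- metabolic_model(mets, rxns, "r9")
  attr(model, "pathways") <- list(
    P1 = c("r1", "r2"),
    P2 = c("r1", "r3", "r9"),
    P3 = c("r1", "r4", "r5", "r9"),
    P4 = c("r1", "r6", "r7", "r8", "r9"))
  model
}

#' Random expression profile for a model
#'
#' Draws one uniform(0, 1) expression value per gene appearing in the
#' model's GPR rules and removes a seeded fraction of them, exercising the
#' missing-data path (those reactions fall back to the neutral weight).
#'
#' @param model a `metabolic_model`.
#' @param seed integer seed; the generator is a pure function of it.
#' @param missing_fraction fraction of genes left unmeasured, in \[0, 1).
#' @return Named numeric expression profile.
#' @export
gen_expression <- function(model, seed, missing_fraction = 0) {
  stopifnot(missing_fraction >= 0, missing_fraction < 1)
  genes <- model_genes(model)
  with_seed(seed, function() {
    vals <- stats::setNames(stats::runif(length(genes)), genes)
    n_drop <- round(missing_fraction * length(genes))
    if (n_drop > 0) vals <- vals[-sample(length(genes), n_drop)]
    vals
  })
}

#' Planted-flux parallel-path condition
#'
#' Builds a network of `n_parallel_paths` linear substrate-to-biomass
#' routes of random lengths, designates one as the truly active path, and
#' generates expression so the designated path's genes sit at 1 while all
#' others sit at a low baseline plus Gaussian noise (clipped to \[0, 1\]
#' rather than re-normalized, preserving the planted ordering). The
#' ground-truth flux routes one unit through the designated path.
#'
#' @param n_parallel_paths number of parallel routes, `>= 2`.
#' @param seed integer seed.
#' @param noise_sd standard deviation of the expression noise.
#' @param baseline expression level of off-path genes before noise.
#' @param max_path_length maximum number of intermediate metabolites per
#'   path (lengths are drawn uniformly from 1..max_path_length).
#' @return A list of class `synthetic_condition`: `model`, `profile`,
#'   `truth` (named ground-truth flux vector satisfying S r = 0 exactly),
#'   `planted_path` (active reaction ids, including the shared uptake and
#'   biomass reactions), `seed`.
#' @export
gen_planted_condition <- function(n_parallel_paths = 3, seed = 1,
                                  noise_sd = 0.05, baseline = 0.2,
                                  max_path_length = 3) {
  stopifnot(n_parallel_paths >= 2, noise_sd >= 0, max_path_length >= 1)
  with_seed(seed, function() {
    lens <- sample(max_path_length, n_parallel_paths, replace = TRUE)
    mets <- data.frame(id = c("S_ext", "X0", "B", "BIO_ext"),
                       internal = c(FALSE, TRUE, TRUE, FALSE),
                       stringsAsFactors = FALSE)
    rxns <- list(reaction("uptake", c(S_ext = -1, X0 = 1),
                          gpr = "g_uptake"))
    path_rxns <- vector("list", n_parallel_paths)
    for (k in seq_len(n_parallel_paths)) {
      chain <- if (lens[k] > 1)
        paste0("M", k, "_", seq_len(lens[k] - 1)) else character(0)
      nodes <- c("X0", chain, "B")
      if (length(chain))
        mets <- rbind(mets, data.frame(id = chain, internal = TRUE,
                                       stringsAsFactors = FALSE))
      ids <- character(length(nodes) - 1)
      for (s in seq_len(length(nodes) - 1)) {
        rid <- paste0("p", k, "_s", s)
        st <- stats::setNames(c(-1, 1), c(nodes[s], nodes[s + 1]))
        rxns[[length(rxns) + 1L]] <- reaction(rid, st,
                                              gpr = paste0("g_", rid))
        ids[s] <- rid
      }
      path_rxns[[k]] <- ids
    }
    rxns[[length(rxns) + 1L]] <- reaction("biomass",
                                          c(B = -1, BIO_ext = 1),
                                          gpr = "g_biomass")
    mets$name <- mets$id
    model <- metabolic_model(mets, rxns, "biomass")

    truth_path <- sample(n_parallel_paths, 1)
    genes <- model_genes(model)
    on_path <- genes %in% paste0("g_", path_rxns[[truth_path]]) |
      genes %in% c("g_uptake", "g_biomass")
    expr <- ifelse(on_path, 1, baseline) +
      stats::rnorm(length(genes), sd = noise_sd)
    expr <- pmin(pmax(expr, 0), 1)
    # planted genes stay exactly at the top of the ordering
    expr[on_path] <- 1
    names(expr) <- genes

    active <- c("uptake", path_rxns[[truth_path]], "biomass")
    truth <- stats::setNames(rep(0, length(rxns)), reaction_ids(model))
    truth[active] <- 1
    structure(list(model = model, profile = expr, truth = truth,
                   planted_path = active, seed = seed),
              class = "synthetic_condition")
  })
}

#' Toy network with a planted stoichiometrically balanced cycle
#'
#' Adds internal metabolites F, G, H and three reactions c1: F -> G,
#' c2: G -> H, c3: H -> F to the toy network. The loop is balanced and
#' carries no net production, and it is kept off the productive routes so
#' that any nonzero flux through it is a pure circulation -- the
#' thermodynamically infeasible kind of solution that flux minimization
#' with strictly positive weights must exclude, while a plain
#' objective-maximizing method is indifferent to it. (An arc between the
#' toy's own metabolites would instead open a new substrate-to-biomass
#' route and could legitimately carry flux.)
#'
#' @return A validated `metabolic_model`; the added cycle reaction ids are
#'   in `attr(, "cycle")`.
#' @export
build_cycle_fixture <- function() {
  model <- build_toy_network()
  model$metabolites <- rbind(
    model$metabolites,
    data.frame(id = c("F", "G", "H"), name = c("F", "G", "H"),
               internal = TRUE, stringsAsFactors = FALSE))
  model$reactions <- c(model$reactions, list(
    reaction("c1", c(F = -1, G = 1), gpr = "gc1"),
    reaction("c2", c(G = -1, H = 1), gpr = "gc2"),
    reaction("c3", c(H = -1, F = 1), gpr = "gc3")))
  model <- validate_model(model)
  attr(model, "pathways") <- attr(build_toy_network(), "pathways")
  attr(model, "cycle") <- c("c1", "c2", "c3")
  model
}
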