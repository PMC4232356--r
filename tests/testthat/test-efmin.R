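toy <- build_toy_network()

test_that("uniform weights select the shortest biomass route, not the shorter product route", {
  sol <- solve_efmin(toy)
  expect_equal(sol$status, "optimal")
  expect_setequal(active_reactions(sol), c("r1", "r3", "r9"))  # P2
  expect_equal(sol$objective, 3 * 0.01)
  expect_equal(sol$biomass_flux, 0.01)
  # mass balance at the optimum
  S <- stoichiometric_matrix(toy)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-8)
})

test_that("expression-derived weights reroute flux to the cheapest expressed path", {
  sol3 <- solve_efmin(toy, toy_case1_weights())
  expect_setequal(active_reactions(sol3), c("r1", "r4", "r5", "r9"))  # P3
  # per-unit route costs: P2 = 0.9, P3 = 0.1 + 0.1 = 0.2, P4 = 0.6
  expect_equal(sol3$objective, 0.2 * 0.01)
  w4 <- compute_weights(map_expression(toy, toy_case_p4_profile()))
  sol4 <- solve_efmin(toy, w4)
  expect_setequal(active_reactions(sol4),
                  c("r1", "r6", "r7", "r8", "r9"))  # P4
})

test_that("a zero-cost biomass route gives objective zero at flux epsilon", {
  w <- stats::setNames(rep(1, 9), reaction_ids(toy))
  w[c("r1", "r3", "r9")] <- 0
  sol <- solve_efmin(toy, w)
  expect_equal(sol$objective, 0)
  expect_gte(sol$biomass_flux, 0.01 - 1e-9)
})

test_that("structurally blocked biomass is reported infeasible", {
  blocked <- toy
  for (i in which(reaction_ids(toy) %in% c("r3", "r5", "r8")))
    blocked$reactions[[i]]$ub <- 0
  sol <- solve_efmin(blocked)
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective))
})

test_that("normalized solutions are invariant to epsilon", {
  sols <- lapply(c(1e-4, 1e-2, 1), function(eps) {
    s <- solve_efmin(toy, toy_case1_weights(),
                     efmin_config(epsilon = eps))
    normalize_fluxes(s, "r1", 100)$fluxes
  })
  expect_equal(sols[[1]], sols[[2]], tolerance = 1e-10)
  expect_equal(sols[[2]], sols[[3]], tolerance = 1e-10)
  # and on a planted condition
  pc <- gen_planted_condition(3, seed = 5, noise_sd = 0.05)
  w <- compute_weights(map_expression(pc$model, pc$profile))
  sols <- lapply(c(1e-4, 1e-2, 1), function(eps) {
    s <- solve_efmin(pc$model, w, efmin_config(epsilon = eps))
    normalize_fluxes(s, "uptake", 100)$fluxes
  })
  expect_equal(sols[[1]], sols[[2]], tolerance = 1e-10)
  expect_equal(sols[[2]], sols[[3]], tolerance = 1e-10)
})

test_that("normalization rescales linearly and rejects a zero reference", {
  sol <- solve_efmin(toy)
  n <- normalize_fluxes(sol, "r1", 100)
  expect_equal(unname(n$fluxes[c("r1", "r3", "r9")]), c(100, 100, 100))
  same <- normalize_fluxes(sol, "r1", sol$fluxes[["r1"]])
  expect_equal(same$fluxes, sol$fluxes)
  expect_error(normalize_fluxes(sol, "r2", 100), "zero flux")
})

test_that("objective matches brute-force vertex enumeration on small networks", {
  set.seed(321)
  for (k in 1:10) {
    pc <- gen_planted_condition(n_parallel_paths = sample(2:3, 1),
                                seed = 1000 + k, noise_sd = 0.3,
                                max_path_length = 3)
    w <- stats::setNames(runif(length(pc$model$reactions), 0.05, 1),
                         reaction_ids(pc$model))
    cfg <- efmin_config(epsilon = 0.01)
    sol <- solve_efmin(pc$model, w, cfg)
    expect_equal(sol$status, "optimal")
    oracle <- vertex_min_objective(pc$model, w[reaction_ids(pc$model)],
                                   eps = cfg$epsilon)
    expect_equal(sol$objective, oracle, tolerance = 1e-9,
                 info = paste("instance", k))
  }
})

test_that("FVA certifies the unique optimum and exposes constructed degeneracy", {
  fva <- run_fva(toy)   # uniform weights: P2 unique
  width <- fva$max_flux - fva$min_flux
  # near-degenerate: width well under 1e-6 x the 0.01 throughput
  expect_true(all(width < 1e-8))
  sol <- solve_efmin(toy)
  expect_true(all(sol$fluxes >= fva$min_flux - 1e-9 &
                    sol$fluxes <= fva$max_flux + 1e-9))

  # degenerate instance: make P3 and P4 cost the same per unit and cheaper
  # than P2; the flux can then split anywhere between r4 and r6
  w <- c(r1 = 0, r2 = 1, r3 = 0.9, r4 = 0.2, r5 = 0.2,
         r6 = 0.1, r7 = 0.1, r8 = 0.2, r9 = 0)   # both paths cost 0.4
  sol <- solve_efmin(toy, w)
  fva2 <- run_fva(toy, w, solution = sol)
  thr <- sol$fluxes[["r1"]]
  for (rid in c("r4", "r6")) {
    i <- which(fva2$reaction == rid)
    expect_equal(fva2$min_flux[i], 0, tolerance = 1e-8)
    expect_equal(fva2$max_flux[i], thr, tolerance = 1e-6)
  }
  # an off-path weighted reaction stays pinned at zero
  i2 <- which(fva2$reaction == "r2")
  expect_equal(fva2$max_flux[i2], 0, tolerance = 1e-8)
})

test_that("no flux circulates a balanced internal cycle under positive weights", {
  cyc <- build_cycle_fixture()
  cycle_ids <- attr(cyc, "cycle")
  set.seed(99)
  for (k in 1:20) {
    w <- stats::setNames(runif(length(cyc$reactions), 0.05, 1),
                         reaction_ids(cyc))
    sol <- solve_efmin(cyc, w)
    expect_equal(sol$status, "optimal")
    expect_equal(unname(sol$fluxes[cycle_ids]), c(0, 0, 0),
                 info = paste("seed draw", k))
  }
})

test_that("flux TSV output carries optional FVA columns", {
  sol <- solve_efmin(toy)
  fva <- run_fva(toy, solution = sol)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fluxes(sol, f, fva = fva)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(names(tab), c("reaction_id", "flux", "fva_min", "fva_max"))
  expect_equal(tab$flux[tab$reaction_id == "r3"], 0.01)
})
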