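toy <- build_toy_network()
toy_capped <- toy
toy_capped$reactions[[1]]$ub <- 1   # glucose-style uptake limit

test_that("FBA maximizes biomass under the uptake cap and flags unbounded models", {
  sol <- solve_fba(toy_capped)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$biomass_flux, 1)       # unit stoichiometry: full conversion
  expect_equal(solve_fba(toy)$status, "unbounded")
  blocked <- toy_capped
  for (i in which(reaction_ids(toy) %in% c("r3", "r5", "r8")))
    blocked$reactions[[i]]$ub <- 0
  expect_equal(solve_fba(blocked)$biomass_flux, 0)
})

test_that("pFBA keeps the FBA optimum and picks the minimal-total-flux route", {
  fba <- solve_fba(toy_capped)
  pfba <- solve_pfba(toy_capped)
  expect_equal(pfba$biomass_flux, fba$biomass_flux)
  expect_setequal(active_reactions(pfba), c("r1", "r3", "r9"))
  expect_equal(pfba$objective, 3)   # total |flux| on the short path
})

test_that("pFBA zeroes a balanced cycle that FBA tolerates", {
  cyc <- build_cycle_fixture()
  cyc$reactions[[1]]$ub <- 1
  cycle_ids <- attr(cyc, "cycle")
  pfba <- solve_pfba(cyc)
  expect_equal(unname(pfba$fluxes[cycle_ids]), c(0, 0, 0))
})

test_that("GIMME meets the RMF threshold and reroutes below-cutoff reactions", {
  # P2 genes below cutoff, P3 genes above: GIMME penalizes only r3
  prof <- c(g1 = 1, g2 = 0.5, g3 = 0.01, g4 = 0.5, g5 = 0.5,
            g6 = 0.5, g7 = 0.5, g8 = 0.5, g9 = 1)
  re <- map_expression(toy_capped, prof)
  sol <- solve_gimme(toy_capped, re)
  expect_equal(sol$status, "optimal")
  expect_gte(sol$biomass_flux, 0.9 * 1 - 1e-9)
  expect_false("r3" %in% active_reactions(sol))
  expect_true(all(c("r4", "r5") %in% active_reactions(sol)))
  # threshold 1 forces biomass to the exact FBA maximum
  sol1 <- solve_gimme(toy_capped, re, gimme_config(rmf_threshold = 1))
  expect_equal(sol1$biomass_flux, 1)
  # all expression at/above cutoff: objective identically zero
  re_hi <- map_expression(toy_capped,
                          stats::setNames(rep(1, 9), paste0("g", 1:9)))
  expect_equal(solve_gimme(toy_capped, re_hi)$objective, 0)
})

test_that("E-Flux caps fluxes by expression and closes unexpressed essentials", {
  # essential r1 at zero expression blocks biomass entirely
  prof0 <- c(g1 = 0, g2 = 1, g3 = 1, g4 = 1, g5 = 1, g6 = 1, g7 = 1,
             g8 = 1, g9 = 1)
  sol0 <- solve_eflux(toy, map_expression(toy, prof0),
                      eflux_config(bound_scale = 10))
  expect_equal(sol0$biomass_flux, 0)
  # uniform full expression reduces to FBA with uniform bounds
  prof1 <- stats::setNames(rep(1, 9), paste0("g", 1:9))
  sol1 <- solve_eflux(toy, map_expression(toy, prof1),
                      eflux_config(bound_scale = 10))
  fba <- solve_fba(apply_thermodynamic_bounds(toy, big = 10))
  expect_equal(sol1$biomass_flux, fba$biomass_flux)
  # capacity 0.1 on r3 pushes throughput onto the fully expressed P3
  prof2 <- c(g1 = 1, g2 = 0.1, g3 = 0.1, g4 = 1, g5 = 1, g6 = 0.1,
             g7 = 0.1, g8 = 0.1, g9 = 1)
  sol2 <- solve_eflux(toy, map_expression(toy, prof2),
                      eflux_config(bound_scale = 1))
  expect_equal(sol2$biomass_flux, 1)        # r1 cap 1 is the bottleneck
  expect_gte(sol2$fluxes[["r4"]], 0.9 - 1e-9)
})

test_that("all methods satisfy steady-state mass balance and the FBA envelope", {
  prof <- gen_expression(toy_capped, seed = 3)
  re <- map_expression(toy_capped, prof)
  w <- compute_weights(re)
  S <- stoichiometric_matrix(toy_capped)
  fba <- solve_fba(toy_capped)
  sols <- list(efmin = solve_efmin(toy_capped, w),
               fba = fba,
               pfba = solve_pfba(toy_capped),
               gimme = solve_gimme(toy_capped, re),
               eflux = solve_eflux(toy_capped, re,
                                   eflux_config(bound_scale = 1)))
  for (nm in names(sols)) {
    expect_equal(sols[[nm]]$status, "optimal", info = nm)
    expect_lt(max(abs(S %*% sols[[nm]]$fluxes)), 1e-7)
    expect_lte(sols[[nm]]$biomass_flux, fba$biomass_flux + 1e-9)
  }
})

test_that("GIMME converges to the E-Fmin solution family as threshold drops and cutoff rises", {
  prof <- gen_expression(toy_capped, seed = 8)
  re <- map_expression(toy_capped, prof)
  gim <- solve_gimme(toy_capped, re,
                     gimme_config(rmf_threshold = 1e-4, g_cutoff = 1))
  ef <- solve_efmin(toy_capped, compute_weights(re))
  # weights coincide (cutoff 1 makes g_cutoff - g = 1 - g) so the chosen
  # route must agree; flux scale differs with the active constraint
  expect_setequal(active_reactions(gim), active_reactions(ef))
})
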