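test_that("toy network builds with the expected dimensions and pathways", {
  toy <- build_toy_network()
  expect_length(toy$reactions, 9)
  expect_equal(sum(toy$metabolites$internal), 5)
  S <- stoichiometric_matrix(toy)
  expect_equal(dim(S), c(5L, 9L))
  # r5 converts C to B: exactly one -1 and one +1 in its column
  expect_equal(unname(sort(S[, "r5"])), c(-1, 0, 0, 0, 1))
  # every declared pathway at unit throughput is mass-balanced
  for (p in attr(toy, "pathways")) {
    r <- stats::setNames(rep(0, 9), reaction_ids(toy))
    r[p] <- 1
    expect_equal(max(abs(S %*% r)), 0, info = paste(p, collapse = ","))
  }
})

test_that("model validation rejects broken inputs", {
  mets <- data.frame(id = c("X", "Y"), internal = c(TRUE, FALSE))
  rxn_ok <- reaction("r1", c(X = -1, Y = 1))
  expect_error(metabolic_model(mets, list(rxn_ok), "nope"),
               "biomass")
  expect_error(
    metabolic_model(mets, list(reaction("r1", c(Z = -1))), "r1"),
    "undeclared metabolite")
  expect_error(
    metabolic_model(mets, list(rxn_ok, reaction("r1", c(X = 1))), "r1"),
    "duplicate reaction")
  expect_error(reaction("r1", c(X = -1), lb = 2, ub = 1) |>
                 (\(r) metabolic_model(mets, list(r), "r1"))(),
               "lb > ub")
})

test_that("stoichiometric matrix excludes external metabolites", {
  mets <- data.frame(id = c("a_ext", "b_ext"), internal = c(FALSE, FALSE))
  m <- metabolic_model(mets, list(reaction("ex", c(a_ext = -1, b_ext = 1))),
                       "ex")
  expect_equal(nrow(stoichiometric_matrix(m)), 0L)
})

test_that("thermodynamic bounds respect directionality and keep measured bounds", {
  mets <- data.frame(id = c("X"), internal = FALSE)
  m <- metabolic_model(mets, list(
    reaction("fwd", c(X = 1), reversible = FALSE),
    reaction("rev", c(X = 1), reversible = TRUE),
    reaction("meas", c(X = -1), reversible = FALSE, lb = 0, ub = 10)),
    "fwd")
  b_inf <- reaction_bounds(apply_thermodynamic_bounds(m))
  expect_equal(unname(b_inf["fwd", ]), c(0, Inf))
  expect_equal(unname(b_inf["rev", ]), c(-Inf, Inf))
  expect_equal(unname(b_inf["meas", ]), c(0, 10))  # measured bound kept
  b_big <- reaction_bounds(apply_thermodynamic_bounds(m, big = 1e6))
  expect_equal(unname(b_big["rev", ]), c(-1e6, 1e6))
  b_reset <- reaction_bounds(apply_thermodynamic_bounds(m, reset = TRUE))
  expect_equal(unname(b_reset["meas", ]), c(0, Inf))
})

test_that("JSON round-trip is lossless and TSV preserves structure", {
  toy <- build_toy_network()
  toy$reactions[[1]]$ub <- 12.5  # a finite measured bound must survive
  jf <- withr::local_tempfile(fileext = ".json")
  write_model(toy, jf, "json")
  back <- load_model(jf)
  expect_equal(back$metabolites, toy$metabolites)
  expect_equal(lapply(back$reactions, unclass),
               lapply(toy$reactions, unclass))
  expect_equal(back$biomass, toy$biomass)

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_model(toy, tf, "tsv")
  back2 <- load_model(tf)
  expect_equal(reaction_ids(back2), reaction_ids(toy))
  expect_equal(stoichiometric_matrix(back2), stoichiometric_matrix(toy))
  expect_equal(back2$biomass, "r9")
})

test_that("malformed model files fail with informative errors", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": []}', f)
  expect_error(load_model(f), "missing required field")
  writeLines("not json at all {", f)
  expect_error(load_model(f), "parse failure")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#!biomass=r1", "r1\t0\t\tX:abc"), tf)
  expect_error(load_model(tf), "non-numeric coefficient")
})

test_that("SBML ingestion marks boundary species external and flattens fbc GPRs", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1">
 <model id="mini">
  <listOfSpecies>
   <species id="glc_e" boundaryCondition="true"/>
   <species id="glc_c" boundaryCondition="false"/>
   <species id="bio_e" boundaryCondition="true"/>
  </listOfSpecies>
  <fbc:listOfGeneProducts>
   <fbc:geneProduct fbc:id="G_b1" fbc:label="b1"/>
   <fbc:geneProduct fbc:id="G_b2" fbc:label="b2"/>
   <fbc:geneProduct fbc:id="G_b3" fbc:label="b3"/>
  </fbc:listOfGeneProducts>
  <listOfReactions>
   <reaction id="uptake" reversible="false">
    <listOfReactants><speciesReference species="glc_e" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="glc_c" stoichiometry="1"/></listOfProducts>
    <fbc:geneProductAssociation>
     <fbc:or>
      <fbc:geneProductRef fbc:geneProduct="G_b1"/>
      <fbc:and>
       <fbc:geneProductRef fbc:geneProduct="G_b2"/>
       <fbc:geneProductRef fbc:geneProduct="G_b3"/>
      </fbc:and>
     </fbc:or>
    </fbc:geneProductAssociation>
   </reaction>
   <reaction id="biomass" reversible="false">
    <listOfReactants><speciesReference species="glc_c" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="bio_e" stoichiometry="1"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  m <- load_model(f, "sbml")
  expect_equal(m$metabolites$internal,
               m$metabolites$id == "glc_c")
  expect_equal(m$biomass, "biomass")
  up <- m$reactions[[1]]
  expect_equal(up$stoich[c("glc_e", "glc_c")], c(glc_e = -1, glc_c = 1))
  # flattened rule evaluates like the original association
  expect_equal(evaluate_gpr(parse_gpr(up$gpr),
                            c(b1 = 0.2, b2 = 0.9, b3 = 0.6)),
               max(0.2, min(0.9, 0.6)))
})
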