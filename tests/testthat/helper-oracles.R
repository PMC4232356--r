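# Independent oracles used across the suite.

# Brute-force minimum of sum(w * r) over the vertices of
#   {S r = 0, r >= 0, r_B >= eps}
# for fully irreversible networks (so |r| = r and the objective is linear).
# The feasible set is written in standard form with one surplus variable on
# the biomass row and every basic feasible solution is enumerated directly
# -- no pivoting shared with the package's simplex.
vertex_min_objective <- function(model, w, eps) {
  S <- stoichiometric_matrix(model)
  rids <- colnames(S)
  n <- ncol(S)
  biomass_row <- as.numeric(rids == model$biomass)
  A <- rbind(cbind(S, 0), c(biomass_row, -1))
  b <- c(rep(0, nrow(S)), eps)
  qt <- qr(t(A))
  keep <- qt$pivot[seq_len(qt$rank)]
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  m <- nrow(A)
  best <- Inf
  for (cols in utils::combn(ncol(A), m, simplify = FALSE)) {
    M <- A[, cols, drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    x <- solve(M, b)
    if (any(x < -1e-9)) next
    full <- numeric(ncol(A)); full[cols] <- x
    best <- min(best, sum(w * full[seq_len(n)]))
  }
  best
}

# Independent GPR evaluation: rewrite the Boolean rule as an R expression
# with user operators (AND -> min, OR -> max) and eval() it with gene
# values bound -- a textual route sharing nothing with the package's
# recursive-descent parser. R gives both user operators equal precedence,
# so this oracle is only valid for fully parenthesized rules (as
# random_gpr() produces) with every gene measured.
gpr_minmax_eval <- function(rule, profile) {
  ex <- gsub("\\bor\\b", "%OR%", rule, ignore.case = TRUE)
  ex <- gsub("\\band\\b", "%AND%", ex, ignore.case = TRUE)
  eval(parse(text = ex),
       envir = c(as.list(profile),
                 list(`%OR%` = function(a, b) max(a, b),
                      `%AND%` = function(a, b) min(a, b))))
}

# Random fully parenthesized GPR rule of bounded depth, plus gene pool.
random_gpr <- function(depth, genes) {
  if (depth == 0 || (depth < 3 && runif(1) < 0.3))
    return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  kids <- vapply(seq_len(k), function(i) random_gpr(depth - 1, genes), "")
  paste0("(", paste(kids, collapse = paste0(" ", op, " ")), ")")
}

toy_case1_weights <- function() {
  c(r1 = 0, r2 = 1, r3 = 0.9, r4 = 0.1, r5 = 0.1,
    r6 = 0.2, r7 = 0.2, r8 = 0.2, r9 = 0)
}

# Expression profile that puts the long route P4 at full expression and
# penalizes the alternatives.
toy_case_p4_profile <- function() {
  c(g1 = 1, g2 = 0.1, g3 = 0.2, g4 = 0.4, g5 = 0.4,
    g6 = 1, g7 = 1, g8 = 1, g9 = 1)
}
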