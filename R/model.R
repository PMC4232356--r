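# Metabolic network representation.
#
# A model is a plain list: a metabolite table, a list of reaction records
# (each holding its stoichiometry as a named numeric vector, i.e. sparse by
# construction), and the id of the biomass reaction. Declaration order is
# preserved everywhere so matrix rows/columns and LP bases are reproducible.

#' Construct a reaction record
#'
#' @param id unique reaction id.
#' @param stoich named numeric vector of signed stoichiometric coefficients
#'   (names are metabolite ids; negative = consumed, positive = produced).
#' @param reversible logical; irreversible reactions run only in the forward
#'   direction.
#' @param lb,ub flux bounds in mmol/(gDW h). Defaults follow thermodynamic
#'   directionality: `(-Inf, Inf)` if reversible, `(0, Inf)` otherwise.
#' @param gpr gene-protein-reaction Boolean rule over gene ids
#'   (`"A and (B or C)"`); empty string when no genes are associated.
#' @return A list of class `efmin_reaction`.
#' @export
reaction <- function(id, stoich, reversible = FALSE,
                     lb = NULL, ub = NULL, gpr = "") {
  if (is.null(lb)) lb <- if (reversible) -Inf else 0
  if (is.null(ub)) ub <- Inf
  structure(list(id = as.character(id), stoich = stoich,
                 reversible = isTRUE(reversible),
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 gpr = as.character(gpr)),
            class = "efmin_reaction")
}

#' Construct a metabolic model
#'
#' @param metabolites data frame with columns `id`, `name`, `internal`
#'   (internal metabolites are mass-balanced; external/boundary ones are
#'   not). `name` may be omitted and defaults to the id.
#' @param reactions list of [reaction()] records.
#' @param biomass id of the biomass reaction.
#' @return A validated object of class `metabolic_model`.
#' @seealso [load_model()], [stoichiometric_matrix()]
#' @export
metabolic_model <- function(metabolites, reactions, biomass) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  metabolites <- metabolites[, c("id", "name", "internal")]
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         biomass = as.character(biomass)),
    class = "metabolic_model")
  validate_model(model)
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, that every stoichiometry key resolves to a declared
#' metabolite, bound sanity (`lb <= ub`, irreversible implies `lb >= 0`),
#' non-empty stoichiometries, and that the biomass reaction exists.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly unchanged, or an error.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (rxn in model$reactions) {
    if (length(rxn$stoich) == 0L)
      stop("reaction '", rxn$id, "' has empty stoichiometry")
    unknown <- setdiff(names(rxn$stoich), mets$id)
    if (length(unknown))
      stop("reaction '", rxn$id, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (rxn$lb > rxn$ub)
      stop("reaction '", rxn$id, "' has lb > ub")
    if (!rxn$reversible && rxn$lb < 0)
      stop("irreversible reaction '", rxn$id, "' has negative lower bound")
  }
  if (!model$biomass %in% rids)
    stop("biomass reaction '", model$biomass, "' not found in model")
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", length(x$reactions), "reactions,",
      sum(x$metabolites$internal), "internal /",
      sum(!x$metabolites$internal), "external metabolites\n")
  cat("Biomass reaction:", x$biomass, "\n")
  invisible(x)
}

#' Reaction ids of a model, in declaration order
#' @param model a `metabolic_model`.
#' @return Character vector.
#' @export
reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

#' Reaction bounds of a model
#' @param model a `metabolic_model`.
#' @return A two-column matrix (lb, ub) with reaction ids as row names.
#' @export
reaction_bounds <- function(model) {
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  matrix(c(lb, ub), ncol = 2,
         dimnames = list(reaction_ids(model), c("lb", "ub")))
}

#' Stoichiometric matrix of the internal metabolites
#'
#' Materializes the dense m x n matrix S whose entry (i, j) is the signed
#' coefficient of internal metabolite i in reaction j. External/boundary
#' metabolites are excluded: they are not mass-balanced at steady state.
#' Row and column order follow declaration order.
#'
#' @param model a validated `metabolic_model`.
#' @return Numeric matrix with metabolite/reaction ids as dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  internal <- model$metabolites$id[model$metabolites$internal]
  rids <- reaction_ids(model)
  S <- matrix(0, length(internal), length(rids),
              dimnames = list(internal, rids))
  for (rxn in model$reactions) {
    keep <- names(rxn$stoich) %in% internal
    if (any(keep)) S[names(rxn$stoich)[keep], rxn$id] <- rxn$stoich[keep]
  }
  S
}

#' Apply thermodynamic directionality bounds
#'
#' Sets reversible reactions to `(-big, big)` and irreversible ones to
#' `(0, big)`. Pre-existing finite bounds (e.g. a measured substrate uptake)
#' are kept unless `reset = TRUE`, which discards them first -- useful when a
#' loaded model carries default capacity bounds that should not constrain
#' the analysis.
#'
#' @param model a `metabolic_model`.
#' @param big positive flux magnitude; `Inf` (the default) leaves reactions
#'   genuinely unbounded, which the internal solver supports natively.
#' @param reset drop pre-existing finite bounds before applying defaults.
#' @return The model with updated bounds.
#' @export
apply_thermodynamic_bounds <- function(model, big = Inf, reset = FALSE) {
  stopifnot(big > 0)
  model$reactions <- lapply(model$reactions, function(rxn) {
    lb <- rxn$lb; ub <- rxn$ub
    if (reset) { lb <- -Inf; ub <- Inf }
    if (!is.finite(lb) || (reset && rxn$reversible)) {
      lb <- if (rxn$reversible) -big else 0
    }
    if (!rxn$reversible) lb <- max(lb, 0)
    if (!is.finite(ub)) ub <- big
    rxn$lb <- lb; rxn$ub <- ub
    rxn
  })
  model
}

# ---------------------------------------------------------------------------
# File formats

#' Read a metabolic model
#'
#' Supported formats: the package JSON schema, a compact reaction-per-line
#' TSV, and read-only SBML Level 3 (boundary species marked external,
#' fbc gene associations honored when present).
#'
#' @param path file path.
#' @param format `"json"`, `"tsv"` or `"sbml"`; guessed from the file
#'   extension by default.
#' @return A validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", tsv = "tsv", txt = "tsv",
                     xml = "sbml", sbml = "sbml",
                     stop("cannot guess model format from '", path, "'"))
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format,
         json = read_model_json(path),
         tsv = read_model_tsv(path),
         sbml = read_model_sbml(path))
}

#' Write a metabolic model
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param format `"json"` (lossless round-trip) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  switch(format,
         json = write_model_json(model, path),
         tsv = write_model_tsv(model, path))
  invisible(path)
}

# JSON schema:
#   {"metabolites":[{"id","name","internal"}],
#    "reactions":[{"id","stoich":{met:coef},"reversible","lb","ub","gpr"}],
#    "biomass":"id"}
# Infinite bounds are encoded as null (lb null = -Inf, ub null = +Inf).
read_model_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("JSON parse failure in '", path, "': ",
                         conditionMessage(e)))
  for (field in c("metabolites", "reactions", "biomass"))
    if (is.null(obj[[field]]))
      stop("model JSON missing required field '", field, "'")
  mets <- do.call(rbind, lapply(obj$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite record without 'id'")
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               internal = isTRUE(m$internal), stringsAsFactors = FALSE)
  }))
  rxns <- lapply(obj$reactions, function(r) {
    if (is.null(r$id)) stop("reaction record without 'id'")
    if (is.null(r$stoich) || length(r$stoich) == 0L)
      stop("reaction '", r$id, "' has no stoichiometry")
    st <- unlist(r$stoich)
    reaction(r$id, st, reversible = isTRUE(r$reversible),
             lb = if (is.null(r$lb)) -Inf else r$lb,
             ub = if (is.null(r$ub)) Inf else r$ub,
             gpr = if (is.null(r$gpr)) "" else r$gpr)
  })
  metabolic_model(mets, rxns, obj$biomass)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, internal = m$internal)
  })
  rxns <- lapply(model$reactions, function(r) {
    out <- list(id = r$id, stoich = as.list(r$stoich),
                reversible = r$reversible)
    if (is.finite(r$lb)) out$lb <- r$lb
    if (is.finite(r$ub)) out$ub <- r$ub
    out$gpr <- r$gpr
    out
  })
  jsonlite::write_json(list(metabolites = mets, reactions = rxns,
                            biomass = model$biomass),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# TSV: one reaction per line (id, reversible 0/1, gpr, "met:coef;met:coef"),
# with directive lines "#!biomass=<id>" and "#!external=<met,met>".
read_model_tsv <- function(path) {
  lines <- readLines(path)
  biomass <- NULL; external <- character(0)
  for (ln in grep("^#!", lines, value = TRUE)) {
    kv <- sub("^#!", "", ln)
    key <- sub("=.*$", "", kv); val <- sub("^[^=]*=", "", kv)
    if (key == "biomass") biomass <- trimws(val)
    if (key == "external")
      external <- trimws(strsplit(val, ",")[[1]])
  }
  if (is.null(biomass)) stop("TSV model '", path,
                             "' lacks a '#!biomass=' directive")
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rxns <- lapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L)
      stop("malformed TSV reaction line (need 4 fields): '", ln, "'")
    pairs <- strsplit(f[4], ";", fixed = TRUE)[[1]]
    sp <- strsplit(pairs, ":", fixed = TRUE)
    bad <- vapply(sp, length, 0L) != 2L
    if (any(bad)) stop("malformed stoichiometry in reaction '", f[1], "'")
    st <- vapply(sp, function(p) suppressWarnings(as.numeric(p[2])), 0)
    names(st) <- vapply(sp, `[[`, "", 1)
    if (anyNA(st)) stop("non-numeric coefficient in reaction '", f[1], "'")
    reaction(f[1], st, reversible = f[2] %in% c("1", "TRUE", "true"),
             gpr = f[3])
  })
  met_ids <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  mets <- data.frame(id = met_ids, name = met_ids,
                     internal = !met_ids %in% external,
                     stringsAsFactors = FALSE)
  metabolic_model(mets, rxns, biomass)
}

write_model_tsv <- function(model, path) {
  external <- model$metabolites$id[!model$metabolites$internal]
  header <- c(paste0("#!biomass=", model$biomass),
              paste0("#!external=", paste(external, collapse = ",")))
  body <- vapply(model$reactions, function(r) {
    st <- paste(names(r$stoich), r$stoich, sep = ":", collapse = ";")
    paste(r$id, as.integer(r$reversible), r$gpr, st, sep = "\t")
  }, "")
  writeLines(c(header, body), path)
}

# Minimal SBML Level 3 reader (namespace-agnostic XPath). Boundary species
# (boundaryCondition="true") become external metabolites; fbc
# geneProductAssociation trees are flattened back to Boolean rule strings.
read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("SBML parse failure in '", path, "': ",
                         conditionMessage(e)))
  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  if (length(sp_nodes) == 0L) stop("no species found in '", path, "'")
  mets <- do.call(rbind, lapply(sp_nodes, function(nd) {
    data.frame(
      id = xml2::xml_attr(nd, "id"),
      name = {
        nm <- xml2::xml_attr(nd, "name")
        if (is.na(nm)) xml2::xml_attr(nd, "id") else nm
      },
      internal = !identical(xml2::xml_attr(nd, "boundaryCondition"), "true"),
      stringsAsFactors = FALSE)
  }))
  # geneProduct id -> label map (fbc)
  gp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_map <- stats::setNames(
    vapply(gp_nodes, function(nd) {
      lb <- xml2::xml_attr(nd, "label")
      if (is.na(lb)) xml2::xml_attr(nd, "id") else lb
    }, ""),
    vapply(gp_nodes, xml2::xml_attr, "", "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (length(rx_nodes) == 0L) stop("no reactions found in '", path, "'")
  rxns <- lapply(rx_nodes, function(nd) {
    rid <- xml2::xml_attr(nd, "id")
    spref <- function(side, sign) {
      refs <- xml2::xml_find_all(
        nd, paste0("./*[local-name()='", side,
                   "']/*[local-name()='speciesReference']"))
      if (length(refs) == 0L) return(numeric(0))
      coef <- vapply(refs, function(r) {
        s <- xml2::xml_attr(r, "stoichiometry")
        if (is.na(s)) 1 else as.numeric(s)
      }, 0)
      stats::setNames(sign * coef,
                      vapply(refs, xml2::xml_attr, "", "species"))
    }
    st <- c(spref("listOfReactants", -1), spref("listOfProducts", 1))
    if (anyDuplicated(names(st))) {    # merge duplicate species refs
      nm <- names(st)
      st <- vapply(unique(nm), function(s) sum(st[nm == s]), 0)
    }
    gpa <- xml2::xml_find_first(
      nd, ".//*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      child <- xml2::xml_find_first(gpa, "./*")
      if (inherits(child, "xml_missing")) "" else
        sbml_assoc_to_rule(child, gp_map)
    }
    reaction(rid, st,
             reversible = !identical(xml2::xml_attr(nd, "reversible"),
                                     "false"),
             gpr = gpr)
  })
  biomass_guess <- grep("biomass", vapply(rxns, `[[`, "", "id"),
                        ignore.case = TRUE, value = TRUE)
  if (length(biomass_guess) == 0L)
    stop("no biomass reaction identifiable in '", path,
         "'; supply one via metabolic_model()")
  metabolic_model(mets, rxns, biomass_guess[1])
}

sbml_assoc_to_rule <- function(node, gp_map) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    if (gid %in% names(gp_map)) return(gp_map[[gid]])
    return(gid)
  }
  kids <- xml2::xml_find_all(node, "./*")
  parts <- vapply(kids, sbml_assoc_to_rule, "", gp_map = gp_map)
  op <- switch(nm, "and" = " and ", "or" = " or ",
               stop("unsupported gene association node <", nm, ">"))
  paste0("(", paste(parts, collapse = op), ")")
}
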