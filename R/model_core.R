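#' Construct a metabolite
#'
#' @param id Unique metabolite identifier (non-empty string).
#' @param name Human-readable name; defaults to `id`.
#' @param compartment Compartment identifier (e.g. `"c"` for cytosol).
#' @return A `metabolite` object (named list).
#' @export
metabolite <- function(id, name = id, compartment = "c") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name, compartment = compartment),
            class = "metabolite")
}

#' Construct a reaction
#'
#' Stoichiometric coefficients follow the usual convention: negative for
#' consumed metabolites, positive for produced ones. Flux bounds are in
#' mmol per gram dry weight per hour.
#'
#' @param id Unique reaction identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound Flux bounds; `lower_bound <= upper_bound`.
#' @param name Human-readable name; defaults to `id`.
#' @return A `reaction` object.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     name = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop("reaction '", id, "': stoichiometry must be a non-empty named vector")
  }
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound > upper_bound")
  }
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound)),
            class = "reaction")
}

#' Construct a stoichiometric model
#'
#' The substrate for all flux-balance work: a list of metabolites (rows of
#' the stoichiometry matrix S), bounded reactions (columns of S), and the
#' identifier of the biomass pseudo-reaction whose flux is the growth rate.
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param biomass_id Identifier of the biomass reaction.
#' @param id Optional model identifier.
#' @return A validated `stoichiometric_model` object.
#' @export
stoichiometric_model <- function(metabolites, reactions, biomass_id,
                                 id = "model") {
  m <- structure(list(id = id,
                      metabolites = metabolites,
                      reactions = reactions,
                      biomass_id = biomass_id),
                 class = "stoichiometric_model")
  validate_model(m)
}

#' Validate a stoichiometric model
#'
#' Checks id uniqueness, that every metabolite referenced by a reaction is
#' declared, and that `biomass_id` names an existing reaction.
#'
#' @param model A `stoichiometric_model`.
#' @return The model, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "stoichiometric_model"))
  met_ids <- vapply(model$metabolites, `[[`, character(1), "id")
  rxn_ids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing)) {
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(missing, collapse = ", "))
    }
    if (r$lower_bound > r$upper_bound) {
      stop("reaction '", r$id, "': lower_bound > upper_bound")
    }
  }
  if (!model$biomass_id %in% rxn_ids) {
    stop("biomass_id '", model$biomass_id, "' is not a reaction in the model")
  }
  model
}

metabolite_ids <- function(model) {
  vapply(model$metabolites, `[[`, character(1), "id")
}

reaction_ids <- function(model) {
  vapply(model$reactions, `[[`, character(1), "id")
}

get_reaction <- function(model, id) {
  i <- match(id, reaction_ids(model))
  if (is.na(i)) stop("no reaction '", id, "' in model '", model$id, "'")
  model$reactions[[i]]
}

#' Replace a reaction's flux bounds
#'
#' @param model A `stoichiometric_model`.
#' @param id Reaction identifier.
#' @param lower_bound,upper_bound New bounds; `NULL` keeps the current value.
#' @return The modified model.
#' @export
set_bounds <- function(model, id, lower_bound = NULL, upper_bound = NULL) {
  i <- match(id, reaction_ids(model))
  if (is.na(i)) stop("no reaction '", id, "' in model '", model$id, "'")
  if (!is.null(lower_bound)) model$reactions[[i]]$lower_bound <- lower_bound
  if (!is.null(upper_bound)) model$reactions[[i]]$upper_bound <- upper_bound
  if (model$reactions[[i]]$lower_bound > model$reactions[[i]]$upper_bound) {
    stop("reaction '", id, "': lower_bound > upper_bound")
  }
  model
}

#' Dense stoichiometry matrix
#'
#' @param model A `stoichiometric_model`.
#' @return Numeric matrix, metabolites (rows) by reactions (columns).
#' @export
stoich_matrix <- function(model) {
  mets <- metabolite_ids(model)
  rxns <- reaction_ids(model)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' @export
print.stoichiometric_model <- function(x, ...) {
  cat("<stoichiometric_model> '", x$id, "': ",
      length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions; biomass = '", x$biomass_id, "'\n",
      sep = "")
  invisible(x)
}

#' Solve a flux-balance linear program
#'
#' Maximizes (or minimizes) the flux of one reaction subject to steady-state
#' mass balance (S v = 0) and the model's flux bounds, using the package's
#' bounded-variable simplex (two-phase, Bland's anti-cycling rule — FBA
#' problems are highly degenerate). Degenerate optima are generic in
#' flux-balance analysis, so only the objective value is contractual; the
#' returned flux vector is one optimal vertex.
#'
#' @param model A `stoichiometric_model`.
#' @param objective_id Reaction whose flux is optimized.
#' @param sense `"max"` or `"min"`.
#' @param tol Solver feasibility/pricing tolerance.
#' @return A `flux_solution`: list with `objective_value`, `fluxes` (named
#'   numeric vector) and `status` in `{"optimal", "infeasible", "unbounded"}`.
#' @export
solve_lp <- function(model, objective_id, sense = c("max", "min"),
                     tol = 1e-9) {
  sense <- match.arg(sense)
  rxns <- reaction_ids(model)
  j_obj <- match(objective_id, rxns)
  if (is.na(j_obj)) stop("objective '", objective_id, "' is not a reaction")

  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  if (any(!is.finite(lb))) {
    # shift needs finite lower bounds; mirror free directions generously
    lb[!is.finite(lb)] <- -1e9
  }

  # shift to non-negative coordinates x = v - lb
  cc <- numeric(length(rxns))
  cc[j_obj] <- if (sense == "max") 1 else -1
  res <- bounded_simplex(cc, S, as.vector(-S %*% lb), ub - lb, eps = tol)
  if (res$status != "optimal") {
    status <- if (res$status == "unbounded") "unbounded" else "infeasible"
    return(structure(list(objective_value = NA_real_,
                          fluxes = stats::setNames(rep(NA_real_, length(rxns)),
                                                   rxns),
                          status = status),
                     class = "flux_solution"))
  }
  v <- res$x + lb
  names(v) <- rxns
  structure(list(objective_value = unname(if (sense == "max") res$value
                                          else -res$value),
                 fluxes = v, status = "optimal"),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status =", x$status,
      "objective =", format(x$objective_value, digits = 10), "\n")
  invisible(x)
}

# ---- model IO ---------------------------------------------------------------

#' Read a metabolic model from COBRA-style JSON or SBML L3 + FBC
#'
#' The JSON dialect follows COBRA conventions (`reactions` / `metabolites`
#' arrays with `lower_bound` / `upper_bound` keys; the biomass reaction is
#' the one with `objective_coefficient == 1` unless `biomass_id` is given).
#' The SBML reader handles Level 3 with the FBC package: bound parameters
#' referenced via `fbc:lowerFluxBound` / `fbc:upperFluxBound` and the active
#' FBC objective.
#'
#' @param path File path.
#' @param format `"json"` or `"sbml"`; guessed from the extension by default.
#' @param biomass_id Optional explicit biomass reaction id.
#' @return A validated `stoichiometric_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"),
                       biomass_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format,
         json = read_model_json(path, biomass_id = biomass_id),
         sbml = read_model_sbml(path, biomass_id = biomass_id))
}

read_model_json <- function(path, biomass_id = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("not a COBRA-style JSON model (missing 'metabolites'/'reactions'): ", path)
  }
  mets <- lapply(doc$metabolites, function(m) {
    metabolite(id = m$id,
               name = if (!is.null(m$name)) m$name else m$id,
               compartment = if (!is.null(m$compartment)) m$compartment else "c")
  })
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    reaction(id = r$id,
             stoichiometry = st,
             lower_bound = r$lower_bound,
             upper_bound = r$upper_bound,
             name = if (!is.null(r$name)) r$name else r$id)
  })
  if (is.null(biomass_id)) {
    objc <- vapply(doc$reactions, function(r) {
      if (is.null(r$objective_coefficient)) 0 else as.numeric(r$objective_coefficient)
    }, numeric(1))
    hit <- which(objc != 0)
    if (length(hit) != 1L) {
      stop("cannot identify the biomass reaction in ", path,
           " (need exactly one nonzero objective_coefficient or an explicit biomass_id)")
    }
    biomass_id <- doc$reactions[[hit]]$id
  }
  stoichiometric_model(mets, rxns, biomass_id,
                       id = if (!is.null(doc$id)) doc$id else "model")
}

#' Write a model to COBRA-style JSON
#'
#' @param model A `stoichiometric_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  mets <- lapply(model$metabolites, function(m) {
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id, name = r$name,
         metabolites = as.list(r$stoichiometry),
         lower_bound = r$lower_bound,
         upper_bound = r$upper_bound,
         objective_coefficient = if (r$id == model$biomass_id) 1 else 0)
  })
  jsonlite::write_json(list(id = model$id, metabolites = mets, reactions = rxns),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# SBML ids must be SId-conformant; COBRA tooling prefixes "M_"/"R_".
sbml_sid <- function(prefix, id) paste0(prefix, gsub("[^A-Za-z0-9_]", "_", id))

#' Write a model to SBML Level 3 with FBC bounds
#'
#' Emits one FBC bound parameter per distinct bound value and an active FBC
#' objective pointing at the biomass reaction, matching what the reader
#' consumes.
#'
#' @param model A `stoichiometric_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbc, level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_sid("", model$id),
                             "fbc:strict" = "true")

  comps <- unique(vapply(model$metabolites, `[[`, character(1), "compartment"))
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(loc, "compartment", id = cp, constant = "true")
  }

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites) {
    xml2::xml_add_child(los, "species", id = sbml_sid("M_", m$id), name = m$name,
                        compartment = m$compartment,
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  bounds <- unique(c(vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
                     vapply(model$reactions, `[[`, numeric(1), "upper_bound")))
  bid <- function(v) sprintf("fb_%d", match(v, bounds))
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bounds) {
    xml2::xml_add_child(lop, "parameter", id = bid(v),
                        value = format(v, digits = 17), constant = "true")
  }

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(lor, "reaction", id = sbml_sid("R_", r$id),
                              name = r$name, reversible =
                                if (r$lower_bound < 0) "true" else "false",
                              fast = "false",
                              "fbc:lowerFluxBound" = bid(r$lower_bound),
                              "fbc:upperFluxBound" = bid(r$upper_bound))
    st <- r$stoichiometry
    if (any(st < 0)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(st)[st < 0]) {
        xml2::xml_add_child(lre, "speciesReference", species = sbml_sid("M_", m),
                            stoichiometry = format(-st[[m]], digits = 17),
                            constant = "true")
      }
    }
    if (any(st > 0)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(st)[st > 0]) {
        xml2::xml_add_child(lpr, "speciesReference", species = sbml_sid("M_", m),
                            stoichiometry = format(st[[m]], digits = 17),
                            constant = "true")
      }
    }
  }

  loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = sbml_sid("R_", model$biomass_id),
                      "fbc:coefficient" = "1")

  xml2::write_xml(doc, path)
  invisible(path)
}

strip_sbml_prefix <- function(id, prefix) sub(paste0("^", prefix), "", id)

read_model_sbml <- function(path, biomass_id = NULL) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp) == 0L) stop("no species found in SBML file: ", path)
  mets <- lapply(sp, function(n) {
    id <- strip_sbml_prefix(xml2::xml_attr(n, "id"), "M_")
    nm <- xml2::xml_attr(n, "name")
    metabolite(id = id, name = if (is.na(nm)) id else nm,
               compartment = xml2::xml_attr(n, "compartment"))
  })

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx, function(n) {
    id <- strip_sbml_prefix(xml2::xml_attr(n, "id"), "R_")
    nm <- xml2::xml_attr(n, "name")
    reac <- xml2::xml_find_all(n, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(n, "./s:listOfProducts/s:speciesReference", ns)
    ids <- c(strip_sbml_prefix(xml2::xml_attr(reac, "species"), "M_"),
             strip_sbml_prefix(xml2::xml_attr(prod, "species"), "M_"))
    coef <- c(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
              as.numeric(xml2::xml_attr(prod, "stoichiometry")))
    st <- tapply(coef, ids, sum)  # merge duplicate species references
    st <- stats::setNames(as.numeric(st), names(st))
    lbp <- xml2::xml_attr(n, "fbc:lowerFluxBound", ns = ns)
    ubp <- xml2::xml_attr(n, "fbc:upperFluxBound", ns = ns)
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else
      if (identical(xml2::xml_attr(n, "reversible"), "true")) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000
    reaction(id = id, stoichiometry = st, lower_bound = lb, upper_bound = ub,
             name = if (is.na(nm)) id else nm)
  })

  if (is.null(biomass_id)) {
    fo <- xml2::xml_find_first(
      doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
    if (inherits(fo, "xml_missing")) {
      stop("no FBC objective in ", path, "; pass biomass_id explicitly")
    }
    biomass_id <- strip_sbml_prefix(xml2::xml_attr(fo, "fbc:reaction", ns = ns), "R_")
  }
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id")
  stoichiometric_model(mets, rxns, biomass_id,
                       id = if (is.na(mid)) "model" else mid)
}
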