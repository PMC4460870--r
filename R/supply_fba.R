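#' Construct an amino-acid map
#'
#' Maps one-letter residue codes to the metabolite ids carrying the free
#' amino acids in a given model. Genome-scale maps carry all 20 canonical
#' codes; toy models may use a smaller alphabet, so completeness is only
#' enforced when `complete = TRUE`.
#'
#' @param codes Character vector of single-letter residue codes.
#' @param metabolite_ids Character vector of metabolite ids, same length.
#' @param model Optional model against which the ids are checked.
#' @param complete Require all 20 canonical codes.
#' @return Named character vector (code -> metabolite id), class `aa_map`.
#' @export
aa_map <- function(codes, metabolite_ids, model = NULL, complete = FALSE) {
  stopifnot(length(codes) == length(metabolite_ids), !anyDuplicated(codes))
  if (any(nchar(codes) != 1L)) stop("residue codes must be single letters")
  map <- structure(stats::setNames(as.character(metabolite_ids), codes),
                   class = "aa_map")
  validate_aa_map(map, model = model, complete = complete)
}

CANONICAL_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate an amino-acid map
#'
#' @param map An `aa_map`.
#' @param model Optional model; all mapped metabolites must exist in it.
#' @param complete If `TRUE` require the 20 canonical residue codes.
#' @return The map, invisibly, if valid.
#' @export
validate_aa_map <- function(map, model = NULL, complete = FALSE) {
  if (complete) {
    missing <- setdiff(CANONICAL_AA, names(map))
    if (length(missing)) {
      stop("aa_map missing canonical residue(s): ", paste(missing, collapse = ", "))
    }
  }
  if (!is.null(model)) {
    absent <- setdiff(unname(map), metabolite_ids(model))
    if (length(absent)) {
      stop("aa_map metabolite(s) absent from model: ",
           paste(absent, collapse = ", "))
    }
  }
  map
}

#' Read an amino-acid map from a two-column TSV (code, metabolite_id)
#'
#' The package ships a default map for the iJO1366 E. coli reconstruction
#' (BiGG cytosolic L-amino-acid ids) under
#' `system.file("extdata", "aa_map_iJO1366.tsv", package = "aasupply")`.
#'
#' @param path TSV path with columns `code` and `metabolite_id`.
#' @inheritParams aa_map
#' @return An `aa_map`.
#' @export
read_aa_map <- function(path, model = NULL, complete = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("code", "metabolite_id") %in% names(tab)))
  aa_map(tab$code, tab$metabolite_id, model = model, complete = complete)
}

#' Build an amino-acid map by metabolite-name matching
#'
#' For models that do not use BiGG ids (e.g. Yeast-6's opaque `s_xxxx`
#' ids), match canonical amino-acid names ("L-alanine", "glycine", ...)
#' against metabolite names. When the same amino acid occurs in several
#' compartments, the compartment referenced by the biomass reaction wins.
#'
#' @param model A `stoichiometric_model`.
#' @return An `aa_map` for the codes that could be matched.
#' @export
aa_map_from_names <- function(model) {
  aa_names <- c(A = "alanine", C = "cysteine", D = "aspartate", E = "glutamate",
                F = "phenylalanine", G = "glycine", H = "histidine",
                I = "isoleucine", K = "lysine", L = "leucine", M = "methionine",
                N = "asparagine", P = "proline", Q = "glutamine",
                R = "arginine", S = "serine", T = "threonine", V = "valine",
                W = "tryptophan", Y = "tyrosine")
  alt <- c(D = "aspartic acid", E = "glutamic acid")
  met_names <- tolower(vapply(model$metabolites, `[[`, character(1), "name"))
  met_ids <- metabolite_ids(model)
  biomass <- get_reaction(model, model$biomass_id)
  in_biomass <- met_ids %in% names(biomass$stoichiometry)
  codes <- character(0); ids <- character(0)
  for (code in names(aa_names)) {
    pats <- c(aa_names[[code]], alt[code])
    pats <- pats[!is.na(pats)]
    hits <- which(Reduce(`|`, lapply(pats, function(p) {
      grepl(paste0("(^|[^a-z])", p, "($|[^a-z])"), met_names)
    })))
    if (!length(hits)) next
    if (length(hits) > 1L && any(in_biomass[hits])) hits <- hits[in_biomass[hits]]
    codes <- c(codes, code)
    ids <- c(ids, met_ids[hits[1L]])
  }
  aa_map(codes, ids, model = model)
}

#' Maximum growth rate (FBA step 1)
#'
#' Maximizes the biomass reaction flux under the model's bounds: the
#' standard FBA growth objective. The substrate-uptake bound (glucose
#' uptake 10 mmol/gDW/h in the published setting) is part of the model's
#' bounds and must already be set by the caller (see [set_bounds()]).
#'
#' @param model A `stoichiometric_model`.
#' @return Growth rate mu (1/h).
#' @export
max_growth <- function(model) {
  sol <- solve_lp(model, model$biomass_id, sense = "max")
  if (sol$status != "optimal") {
    stop("growth optimization not optimal (status: ", sol$status, ")")
  }
  sol$objective_value
}

#' Scale the amino-acid coefficients of the biomass reaction (partial biomass)
#'
#' Returns a copy of the model whose biomass reaction demands only a basal
#' fraction `beta` of every amino acid, with every other biomass component
#' unchanged. This is the partial-biomass reaction of the two-step supply
#' estimation: fixing its flux at the optimal growth rate keeps all
#' non-amino-acid growth demands at full rate while freeing 1 - beta of the
#' amino-acid biosynthetic capacity.
#'
#' @param model A `stoichiometric_model`.
#' @param map An `aa_map` for this model.
#' @param beta Basal fraction in (0, 1]; the published default is 0.3.
#' @return A modified copy of the model.
#' @export
make_partial_biomass <- function(model, map, beta = 0.3) {
  stopifnot(beta > 0, beta <= 1)
  validate_aa_map(map, model = model)
  i <- match(model$biomass_id, reaction_ids(model))
  st <- model$reactions[[i]]$stoichiometry
  aa_mets <- unname(map)
  absent <- setdiff(aa_mets, names(st))
  if (length(absent)) {
    warning("amino-acid metabolite(s) not in the biomass reaction: ",
            paste(absent, collapse = ", "))
  }
  hit <- intersect(aa_mets, names(st))
  st[hit] <- st[hit] * beta
  model$reactions[[i]]$stoichiometry <- st
  model
}

#' Add a protein-specific amino-acid sink reaction
#'
#' The sink consumes the free amino acids in the protein's residue
#' proportions and produces nothing; its maximal flux (in residue
#' equivalents per gDW per hour) is the protein's amino-acid supply.
#' Frequencies, not raw counts, are used so supplies are comparable across
#' proteins of different length.
#'
#' @param model A `stoichiometric_model`.
#' @param map An `aa_map`.
#' @param aa_freq Named numeric vector (residue code -> frequency); must be
#'   non-negative and sum to 1 within 1e-9.
#' @param sink_id Identifier for the added reaction.
#' @return List with elements `model` (with the sink appended, bounds
#'   `[0, Inf)`) and `sink_id`.
#' @export
make_protein_sink <- function(model, map, aa_freq, sink_id = "PROTEIN_SINK") {
  if (any(aa_freq < 0)) stop("amino-acid frequencies must be non-negative")
  if (abs(sum(aa_freq) - 1) > 1e-9) {
    stop("amino-acid frequencies must sum to 1 (got ", format(sum(aa_freq)), ")")
  }
  unknown <- setdiff(names(aa_freq), names(map))
  if (length(unknown)) {
    stop("residue code(s) not in the amino-acid map: ",
         paste(unknown, collapse = ", "))
  }
  aa_freq <- aa_freq[aa_freq > 0]
  st <- stats::setNames(-as.numeric(aa_freq), unname(map[names(aa_freq)]))
  sink <- reaction(sink_id, st, lower_bound = 0, upper_bound = Inf,
                   name = "protein-specific amino-acid sink")
  model$reactions <- c(model$reactions, list(sink))
  list(model = validate_model(model), sink_id = sink_id)
}

#' Amino-acid supply for one protein (FBA step 2)
#'
#' With the partial-biomass flux fixed at the growth rate `mu` from step 1,
#' maximizes the flux of the protein-specific amino-acid sink. On numerical
#' infeasibility of the exact fixing the constraint is relaxed once to
#' `mu * (1 - 1e-6)` with a message.
#'
#' @param model The base model (same substrate bounds used for `mu`).
#' @param map An `aa_map`.
#' @param aa_freq Residue frequencies of the protein (see
#'   [make_protein_sink()]).
#' @param beta Basal amino-acid fraction of the partial biomass.
#' @param mu Growth rate from [max_growth()] on the same model.
#' @param protein_id Identifier reported in the result.
#' @return A `supply_result`: list with `protein_id`, `supply`, `mu`,
#'   `basal_level` and `status`.
#' @export
amino_acid_supply <- function(model, map, aa_freq, beta = 0.3, mu,
                              protein_id = "protein") {
  partial <- make_partial_biomass(model, map, beta)
  withsink <- make_protein_sink(partial, map, aa_freq)
  m <- set_bounds(withsink$model, model$biomass_id,
                  lower_bound = mu, upper_bound = mu)
  sol <- solve_lp(m, withsink$sink_id, sense = "max")
  if (sol$status == "infeasible" && mu > 0) {
    message("exact growth fixing infeasible; relaxing to mu * (1 - 1e-6)")
    mu_rel <- mu * (1 - 1e-6)
    m <- set_bounds(withsink$model, model$biomass_id,
                    lower_bound = mu_rel, upper_bound = mu_rel)
    sol <- solve_lp(m, withsink$sink_id, sense = "max")
  }
  supply <- if (sol$status == "optimal") sol$objective_value else NA_real_
  structure(list(protein_id = protein_id, supply = supply, mu = mu,
                 basal_level = beta, status = sol$status),
            class = "supply_result")
}

#' Amino-acid supply for a whole proteome
#'
#' Runs the two-step estimation once per protein: the growth rate is
#' computed once on the base model and reused; each protein then gets its
#' own sink maximization. Per-protein infeasibilities become `NA` supplies,
#' never an abort.
#'
#' @param model A `stoichiometric_model`.
#' @param map An `aa_map`.
#' @param proteome List of `protein_record`s (see [protein_record()]) or a
#'   named list of frequency vectors.
#' @param beta Basal amino-acid fraction (default 0.3).
#' @param uptake Substrate uptake rate (mmol/gDW/h, default 10), applied as
#'   a negative lower bound on `exchange_id` when that is given.
#' @param exchange_id Optional substrate exchange reaction to bound.
#' @return A tibble: `protein_id`, `supply`, `mu`, `beta`, `status`, in
#'   input order.
#' @export
supply_table <- function(model, map, proteome, beta = 0.3, uptake = 10,
                         exchange_id = NULL) {
  stopifnot(length(proteome) > 0)
  if (!is.null(exchange_id)) {
    model <- set_bounds(model, exchange_id, lower_bound = -uptake)
  }
  mu <- max_growth(model)
  res <- lapply(seq_along(proteome), function(i) {
    p <- proteome[[i]]
    if (inherits(p, "protein_record")) {
      id <- p$id; fr <- p$aa_freq
    } else {
      id <- names(proteome)[i]; fr <- p
      if (is.null(id) || !nzchar(id)) id <- paste0("protein_", i)
    }
    amino_acid_supply(model, map, fr, beta = beta, mu = mu, protein_id = id)
  })
  tibble::tibble(
    protein_id = vapply(res, `[[`, character(1), "protein_id"),
    supply = vapply(res, `[[`, numeric(1), "supply"),
    mu = mu,
    beta = beta,
    status = vapply(res, `[[`, character(1), "status"))
}
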