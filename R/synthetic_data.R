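#' Specification of a toy metabolic network
#'
#' A toy network has one limiting substrate with an exchange reaction, one
#' synthesis reaction per amino acid (substrate -> yield units of the
#' residue), and a biomass reaction consuming the stated composition.
#' Optima are hand-computable, which is what makes these models useful as
#' oracles for the linear-programming machinery.
#'
#' @param yields Named numeric vector, residue code -> product units per
#'   substrate unit (> 0).
#' @param biomass_composition Named numeric vector, residue code ->
#'   coefficient consumed per unit of biomass flux; defaults to 1 for each
#'   residue in `yields`.
#' @param substrate_uptake Uptake bound on the exchange reaction
#'   (mmol/gDW/h, > 0).
#' @param extra_biomass_components Optional named numeric vector of
#'   non-amino-acid biomass coefficients; each component gets its own
#'   1:1 synthesis reaction from substrate.
#' @return A `toy_model_spec`.
#' @export
toy_model_spec <- function(yields,
                           biomass_composition =
                             stats::setNames(rep(1, length(yields)), names(yields)),
                           substrate_uptake = 10,
                           extra_biomass_components = NULL) {
  stopifnot(length(yields) >= 2L, all(yields > 0), substrate_uptake > 0,
            !is.null(names(yields)),
            all(names(biomass_composition) %in% names(yields)))
  structure(list(yields = yields,
                 biomass_composition = biomass_composition,
                 substrate_uptake = substrate_uptake,
                 extra_biomass_components = extra_biomass_components),
            class = "toy_model_spec")
}

#' Build a toy stoichiometric model from its specification
#'
#' Deterministic ids: `EX_substrate`, `SYN_<code>`, `BIOMASS`, metabolites
#' `substrate` and `aa_<code>`. Uptake follows the COBRA sign convention
#' (uptake u means lower bound -u on the exchange reaction).
#'
#' @param spec A [toy_model_spec()].
#' @return A `stoichiometric_model`.
#' @export
build_toy_model <- function(spec) {
  stopifnot(inherits(spec, "toy_model_spec"))
  codes <- names(spec$yields)
  mets <- c(list(metabolite("substrate", "limiting substrate")),
            lapply(codes, function(a) {
              metabolite(paste0("aa_", a), paste0("amino acid ", a))
            }))
  rxns <- list(reaction("EX_substrate", c(substrate = -1),
                        lower_bound = -spec$substrate_uptake,
                        upper_bound = 1000,
                        name = "substrate exchange"))
  for (a in codes) {
    st <- stats::setNames(c(-1, spec$yields[[a]]),
                          c("substrate", paste0("aa_", a)))
    rxns <- c(rxns, list(reaction(paste0("SYN_", a), st,
                                  name = paste0("synthesis of ", a))))
  }
  bio <- stats::setNames(-as.numeric(spec$biomass_composition),
                         paste0("aa_", names(spec$biomass_composition)))
  extra <- spec$extra_biomass_components
  if (!is.null(extra)) {
    for (comp in names(extra)) {
      mets <- c(mets, list(metabolite(comp)))
      rxns <- c(rxns, list(reaction(paste0("SYN_", comp),
                                    stats::setNames(c(-1, 1),
                                                    c("substrate", comp)))))
    }
    bio <- c(bio, stats::setNames(-as.numeric(extra), names(extra)))
  }
  rxns <- c(rxns, list(reaction("BIOMASS", bio, name = "biomass")))
  stoichiometric_model(mets, rxns, "BIOMASS", id = "toy")
}

#' The canonical TOY1 fixture
#'
#' Two amino acids: A with yield 2 and B with yield 1 per substrate unit,
#' biomass consuming 1 A + 1 B, substrate uptake 10. Closed-form optima:
#' growth rate 20/3; at basal level 0.3 the supplies of an all-A, all-B and
#' half-half protein are 14, 7 and 28/3.
#'
#' @return A `stoichiometric_model`.
#' @export
toy1_model <- function() {
  build_toy_model(toy_model_spec(yields = c(A = 2, B = 1),
                                 substrate_uptake = 10))
}

#' Amino-acid map for a toy model
#'
#' @param model A toy `stoichiometric_model` from [build_toy_model()].
#' @return An `aa_map` covering the toy alphabet.
#' @export
toy_aa_map <- function(model) {
  ids <- metabolite_ids(model)
  aa_ids <- ids[startsWith(ids, "aa_")]
  aa_map(sub("^aa_", "", aa_ids), aa_ids, model = model)
}

#' Planted statistical parameters for synthetic datasets
#'
#' @param target_spearman_supply_te Population Spearman correlation planted
#'   between supply and TE (and, with the same copula, between supply and
#'   RD and supply and mRNA level), in (-1, 1).
#' @param replicate_cv Coefficient of variation of the lognormal replicate
#'   noise (>= 0).
#' @param buffering_delta Excess of the PAAS median starvation fold change
#'   over the WAAS one at the extremes of the supply ranking (>= 0).
#' @param n_genes Number of genes.
#' @param seed Mandatory integer seed; every generator is a pure function
#'   of its inputs and this seed.
#' @param fc_sdlog Log-scale noise of the starvation fold change.
#' @return A `planted_params` list.
#' @export
planted_params <- function(target_spearman_supply_te = 0.30,
                           replicate_cv = 0.1,
                           buffering_delta = 0.2,
                           n_genes = 2000L,
                           seed,
                           fc_sdlog = 0.25) {
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1L,
            abs(target_spearman_supply_te) < 1,
            replicate_cv >= 0, buffering_delta >= 0, n_genes >= 1L,
            fc_sdlog >= 0)
  structure(list(target_spearman_supply_te = target_spearman_supply_te,
                 replicate_cv = replicate_cv,
                 buffering_delta = buffering_delta,
                 n_genes = as.integer(n_genes),
                 seed = as.integer(seed),
                 fc_sdlog = fc_sdlog),
            class = "planted_params")
}

#' Generate a synthetic proteome over a toy model's alphabet
#'
#' Per-protein residue compositions are drawn from a Dirichlet distribution
#' (so supplies spread across proteins) whose mean interpolates between
#' uniform (`composition_bias = 0`) and a point mass on the cheapest
#' residue, i.e. the one with the highest synthesis yield
#' (`composition_bias = 1`); sequences are then multinomial draws of fixed
#' length.
#'
#' @param n Number of proteins.
#' @param spec A [toy_model_spec()] providing the alphabet and yields.
#' @param composition_bias Bias toward the cheapest residue, in `[0, 1]`.
#' @param length Sequence length (residues).
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration scaling (> 0); larger means
#'   less between-protein composition spread.
#' @return Named list of `protein_record`s.
#' @export
gen_proteome <- function(n, spec, composition_bias = 0.5, length = 300L,
                         seed, concentration = 10) {
  stopifnot(n >= 1L, inherits(spec, "toy_model_spec"),
            composition_bias >= 0, composition_bias <= 1, !missing(seed))
  codes <- names(spec$yields)
  k <- length(codes)
  cheapest <- codes[which.max(spec$yields)]
  ids <- sprintf("prot_%04d", seq_len(n))
  recs <- withr::with_seed(seed, {
    mean_comp <- (1 - composition_bias) / k +
      composition_bias * (codes == cheapest)
    lapply(seq_len(n), function(i) {
      probs <- if (composition_bias >= 1) {
        as.numeric(codes == cheapest)
      } else {
        g <- stats::rgamma(k, shape = concentration * mean_comp)
        if (sum(g) == 0) mean_comp else g / sum(g)
      }
      seqn <- paste(sample(codes, length, replace = TRUE, prob = probs),
                    collapse = "")
      protein_record(ids[i], seqn, alphabet = codes)
    })
  })
  stats::setNames(recs, ids)
}

# ranks -> standard normal scores, the latent variable of the copula
normal_scores <- function(x) {
  n <- length(x)
  stats::qnorm(rank(x, ties.method = "average") / (n + 1))
}

# lognormal multiplicative noise with unit mean and the stated CV
replicate_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic expression tables with a planted rank correlation
#'
#' A Gaussian-copula construction: the latent normal behind each planted
#' variable (TE, RD, mRNA level, mRNA-fragment RPKM) is correlated with
#' the normal scores of the supply vector at
#' `r = 2 sin(pi * rho_s / 6)`, which makes the population Spearman
#' correlation with supply exactly the target `rho_s`. Observable tables
#' are lognormal transforms of the latent variables; replicate columns
#' (two per series) carry multiplicative lognormal noise with the stated
#' coefficient of variation. Protein abundance is TE times mRNA level and
#' footprint RPKM is RD times fragment RPKM, so recomputing TE/RD from the
#' tables recovers the planted values exactly when `replicate_cv = 0`.
#'
#' @param supplies Numeric vector of per-gene supplies (from
#'   [supply_table()]).
#' @param params A [planted_params()]; `params$n_genes` must equal
#'   `length(supplies)`.
#' @return Tibble with columns `gene_id`, `supply`, `mrna_level`,
#'   `protein_abundance`, `fp_rep1`, `fp_rep2`, `mr_rep1`, `mr_rep2` and
#'   the latent truths `te_true`, `rd_true`.
#' @export
gen_expression <- function(supplies, params) {
  stopifnot(inherits(params, "planted_params"),
            length(supplies) == params$n_genes)
  rho <- params$target_spearman_supply_te
  r <- 2 * sin(pi * rho / 6)
  if (params$replicate_cv > 0 && abs(rho) > 0.99) {
    stop("target Spearman too close to +/-1 for noisy replicates")
  }
  n <- length(supplies)
  withr::with_seed(params$seed, {
    zs <- normal_scores(supplies)
    zs <- zs / stats::sd(zs)
    latent <- function() r * zs + sqrt(1 - r^2) * stats::rnorm(n)
    te_true <- exp(1.0 + 1.0 * latent())         # ppm per molecule/cell
    rd_true <- exp(0.0 + 0.5 * latent())         # dimensionless, median ~1
    mrna_level <- exp(1.5 + 1.0 * latent())      # molecules/cell
    mr_true <- exp(3.8 + 1.0 * latent())         # fragment RPKM, median ~45
    fp_true <- rd_true * mr_true
    cv <- params$replicate_cv
    tibble::tibble(
      gene_id = sprintf("gene_%04d", seq_len(n)),
      supply = supplies,
      mrna_level = mrna_level,
      protein_abundance = te_true * mrna_level,
      fp_rep1 = fp_true * replicate_noise(n, cv),
      fp_rep2 = fp_true * replicate_noise(n, cv),
      mr_rep1 = mr_true * replicate_noise(n, cv),
      mr_rep2 = mr_true * replicate_noise(n, cv),
      te_true = te_true,
      rd_true = rd_true)
  })
}

#' Generate a synthetic starvation table with planted buffering
#'
#' The median fold change of gene i is
#' `1 + buffering_delta * (1 - supply_percentile_i)` — poorly supplied
#' genes change most — times multiplicative lognormal noise of log-sd
#' `fc_sdlog` (median-preserving). `buffering_delta = 0` gives fold
#' changes independent of supply, the calibration null.
#'
#' @param records Data frame with `gene_id`, `supply`, `rd` (normal
#'   condition) and `mrna_level` columns (e.g. a `gene_table`).
#' @param params A [planted_params()].
#' @return Tibble with `gene_id`, `rd_normal`, `rd_starved`, `fold_change`,
#'   `supply`, `mrna_level`.
#' @export
gen_starvation <- function(records, params) {
  stopifnot(inherits(params, "planted_params"),
            all(c("gene_id", "supply", "rd") %in% names(records)))
  n <- nrow(records)
  withr::with_seed(params$seed + 1L, {
    pct <- (rank(records$supply, ties.method = "average") - 0.5) / n
    med_fc <- 1 + params$buffering_delta * (1 - pct)
    fc <- med_fc * exp(params$fc_sdlog * stats::rnorm(n))
    tibble::tibble(
      gene_id = records$gene_id,
      rd_normal = records$rd,
      rd_starved = records$rd * fc,
      fold_change = fc,
      supply = records$supply,
      mrna_level = if ("mrna_level" %in% names(records))
        records$mrna_level else NA_real_)
  })
}
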