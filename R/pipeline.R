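#' Read a pipeline configuration file
#'
#' One flat declarative YAML file of key/value pairs; see [run_all()] for
#' the recognized keys. Referenced files are checked for existence before
#' any computation.
#'
#' @param path YAML config path.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_pipeline_config(yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' @param config Named list of configuration values.
#' @return The config with defaults filled, class `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  defaults <- list(beta = 0.3, uptake = 10, exchange_id = NULL,
                   aa_map_path = NULL, expression_path = NULL,
                   starvation_path = NULL, folding_path = NULL,
                   apply_filters = TRUE, out_dir = "results", seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("model_path", "proteome_path")) {
    if (is.null(config[[nm]])) stop("config is missing required key: ", nm)
    if (!file.exists(config[[nm]])) {
      stop("config: file for '", nm, "' not found: ", config[[nm]])
    }
  }
  for (nm in c("expression_path", "starvation_path", "aa_map_path",
               "folding_path")) {
    if (!is.null(config[[nm]]) && !file.exists(config[[nm]])) {
      stop("config: file for '", nm, "' not found: ", config[[nm]])
    }
  }
  if (config$beta <= 0 || config$beta > 1) stop("config: beta must be in (0, 1]")
  structure(config, class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the whole analysis end to end
#'
#' Stages: amino-acid supply estimation (two-step LP per protein), TE/RD
#' metrics with reliability filters, rank correlations of supply with
#' expression measures, rank-based regressions (`rd ~ supply + cai +
#' folding_energy` and `te ~ supply + rd + cai + folding_energy`, with
#' covariates dropped when entirely missing), and — when a starvation
#' table is present — the WAAS/PAAS buffering comparison and the
#' RD-increased-genes mRNA comparison. Each stage writes one TSV under
#' `out_dir`, plus a versioned JSON summary whose every number is
#' reproducible from the TSVs.
#'
#' Config keys: `model_path`, `proteome_path` (required);
#' `expression_path`, `starvation_path`, `aa_map_path`, `folding_path`,
#' `exchange_id`, `beta` (0.3), `uptake` (10), `apply_filters` (TRUE),
#' `out_dir`, `seed`.
#'
#' @param config A `pipeline_config` (list or [read_pipeline_config()]
#'   output).
#' @return The summary list, invisibly; side effect: TSV/JSON files under
#'   `config$out_dir`.
#' @export
run_all <- function(config) {
  config <- validate_pipeline_config(unclass(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("aasupply pipeline, package version %s",
       as.character(utils::packageVersion("aasupply")))
  logf("beta = %g, uptake = %g, filters = %s, seed = %d, strict thresholds: mRNA > 0.5, mean RPKM > 1, max/min < 1.5, FC > 2",
       config$beta, config$uptake, config$apply_filters, config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  model <- stage("supply", read_model(config$model_path))
  map <- stage("supply", if (!is.null(config$aa_map_path)) {
    read_aa_map(config$aa_map_path, model = model)
  } else if (startsWith(model$id, "toy")) {
    toy_aa_map(model)
  } else {
    aa_map_from_names(model)
  })
  alphabet <- names(map)
  proteome <- stage("supply", read_proteome_fasta(config$proteome_path,
                                                  alphabet = alphabet))
  supplies <- stage("supply", supply_table(
    model, map, proteome, beta = config$beta, uptake = config$uptake,
    exchange_id = config$exchange_id))
  write_tsv(supplies, file.path(config$out_dir, "supply.tsv"))
  logf("supply: %d proteins, mu = %.6g", nrow(supplies), supplies$mu[1])

  summary <- list(schema_version = "1.0",
                  parameters = list(beta = config$beta, uptake = config$uptake,
                                    seed = config$seed),
                  supply = list(n = nrow(supplies), mu = supplies$mu[1]))

  if (!is.null(config$expression_path)) {
    expr <- stage("metrics",
                  utils::read.delim(config$expression_path,
                                    stringsAsFactors = FALSE))
    metrics <- stage("metrics", gene_metrics(expr))
    gt <- stage("metrics", build_gene_table(supplies, metrics))
    if (config$apply_filters) {
      gt_te <- gt[gt$passed_te_filter, , drop = FALSE]
      gt_rd <- gt[gt$passed_rd_filter, , drop = FALSE]
    } else {
      gt_te <- gt; gt_rd <- gt
    }
    write_tsv(gt, file.path(config$out_dir, "gene_table.tsv"))
    logf("metrics: %d genes joined; %d pass TE filter, %d pass RD filter",
         nrow(gt), nrow(gt_te), nrow(gt_rd))

    cors <- list(
      supply_te = spearman(gt_te$supply, gt_te$te),
      supply_rd = spearman(gt_rd$supply, gt_rd$rd),
      supply_mrna = spearman(gt_te$supply, gt_te$mrna_level))
    summary$correlations <- lapply(cors, function(cr) {
      list(r = cr$r, p_value = cr$p_value, n = cr$n)
    })
    for (nm in names(cors)) {
      logf("spearman %s: r = %.4f, p = %.3g, n = %d", nm, cors[[nm]]$r,
           cors[[nm]]$p_value, cors[[nm]]$n)
    }

    regress_one <- function(data, response, covariates) {
      covariates <- covariates[vapply(covariates, function(cv) {
        cv %in% names(data) && any(!is.na(data[[cv]])) &&
          stats::sd(data[[cv]], na.rm = TRUE) > 0
      }, logical(1))]
      if (!length(covariates)) return(NULL)
      fit <- rank_regression(data[, covariates, drop = FALSE],
                             data[[response]])
      list(response = response, covariates = covariates,
           coefficients = as.list(fit$coefficients),
           p_values = as.list(fit$p_values),
           total_r_dispersion_based = fit$total_r)
    }
    summary$regressions <- Filter(Negate(is.null), list(
      rd = stage("regress",
                 regress_one(gt_rd, "rd",
                             c("supply", "cai", "folding_energy"))),
      te = stage("regress",
                 regress_one(gt_te, "te",
                             c("supply", "rd", "cai", "folding_energy")))))
  }

  if (!is.null(config$starvation_path)) {
    sv <- stage("starvation",
                utils::read.delim(config$starvation_path,
                                  stringsAsFactors = FALSE))
    sv$fold_change <- rd_fold_change(sv$rd_starved, sv$rd_normal)
    halves <- stage("starvation", split_waas_paas(sv))
    buf <- stage("starvation", compare_fold_changes(halves$waas, halves$paas))
    inc <- stage("starvation", rd_increased_mrna_comparison(sv))
    write_tsv(sv, file.path(config$out_dir, "starvation.tsv"))
    summary$starvation <- list(
      waas_vs_paas = list(medians = as.list(buf$medians), n = as.list(buf$n),
                          p_value = buf$p_value, alternative = buf$alternative),
      rd_increased_mrna = list(medians = as.list(inc$medians),
                               n = as.list(inc$n), p_value = inc$p_value,
                               alternative = inc$alternative,
                               empty = inc$empty))
    logf("starvation: WAAS/PAAS medians %.4g vs %.4g (n %d vs %d), p = %.3g",
         buf$medians[1], buf$medians[2], buf$n[1], buf$n[2], buf$p_value)
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}

#' Generate a complete synthetic input bundle on disk
#'
#' Builds the TOY1-class model, a synthetic proteome, the expression table
#' with planted correlations, and a starvation table, writing each in the
#' format the pipeline reads (JSON model, FASTA proteome, TSV tables) plus
#' a ready-to-run `config.yaml`. This is the simulate preset used by the
#' analysis scripts and the end-to-end tests.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for all randomness.
#' @param n_genes Number of synthetic genes/proteins.
#' @param params Optional [planted_params()]; default uses
#'   `target_spearman_supply_te = 0.30`, `replicate_cv = 0.1`,
#'   `buffering_delta = 0.2`.
#' @param n_amino_acids Size of the toy alphabet.
#' @return The config list, invisibly.
#' @export
simulate_inputs <- function(out_dir, seed, n_genes = 2000L, params = NULL,
                            n_amino_acids = 6L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(params)) params <- planted_params(n_genes = n_genes, seed = seed)
  spec <- withr::with_seed(seed, {
    codes <- LETTERS[seq_len(n_amino_acids)]
    toy_model_spec(yields = stats::setNames(
      stats::runif(n_amino_acids, 0.5, 3), codes))
  })
  model <- build_toy_model(spec)
  model_path <- file.path(out_dir, "toy_model.json")
  write_model_json(model, model_path)

  proteome <- gen_proteome(params$n_genes, spec, composition_bias = 0.5,
                           seed = seed + 1L)
  proteome_path <- file.path(out_dir, "proteome.fasta")
  write_proteome_fasta(proteome, proteome_path)

  map <- toy_aa_map(model)
  supplies <- supply_table(model, map, proteome)
  expr <- gen_expression(supplies$supply, params)
  expr$gene_id <- supplies$protein_id  # shared id space
  expr_path <- file.path(out_dir, "expression.tsv")
  write_tsv(expr[, c("gene_id", "mrna_level", "protein_abundance",
                     "fp_rep1", "fp_rep2", "mr_rep1", "mr_rep2")],
            expr_path)

  metrics <- gene_metrics(expr)
  sv_in <- tibble::tibble(gene_id = expr$gene_id, supply = expr$supply,
                          rd = metrics$rd, mrna_level = metrics$mr_rpkm_mean)
  sv <- gen_starvation(sv_in, params)
  sv_path <- file.path(out_dir, "starvation.tsv")
  write_tsv(sv[, c("gene_id", "rd_normal", "rd_starved", "supply",
                   "mrna_level")], sv_path)

  config <- list(model_path = model_path, proteome_path = proteome_path,
                 expression_path = expr_path, starvation_path = sv_path,
                 beta = 0.3, uptake = 10,
                 out_dir = file.path(out_dir, "results"), seed = seed)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  invisible(config)
}
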