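#' Translation efficiency
#'
#' TE is protein abundance (ppm) divided by mRNA expression level
#' (molecules/cell): the yield of protein per unit of mRNA, degradation not
#' considered. A zero or missing denominator yields `NA`.
#'
#' @param protein_abundance Numeric vector (ppm).
#' @param mrna_level Numeric vector (molecules/cell).
#' @return Numeric vector of TE values.
#' @export
translation_efficiency <- function(protein_abundance, mrna_level) {
  te <- ifelse(!is.na(mrna_level) & mrna_level > 0,
               protein_abundance / mrna_level, NA_real_)
  as.numeric(te)
}

#' Ribosome density
#'
#' RD is the ribosome-footprint RPKM divided by the mRNA-fragment RPKM,
#' each averaged over replicates first: bound ribosomes per unit of mRNA.
#' A zero or missing denominator yields `NA`.
#'
#' @param footprint_rpkm_mean Numeric vector, replicate-mean footprint RPKM.
#' @param mrna_rpkm_mean Numeric vector, replicate-mean mRNA-fragment RPKM.
#' @return Numeric vector of RD values.
#' @export
ribosome_density <- function(footprint_rpkm_mean, mrna_rpkm_mean) {
  rd <- ifelse(!is.na(mrna_rpkm_mean) & mrna_rpkm_mean > 0,
               footprint_rpkm_mean / mrna_rpkm_mean, NA_real_)
  as.numeric(rd)
}

#' Filter genes on mRNA expression level
#'
#' Keeps genes with mRNA level strictly greater than the threshold
#' (0.5 molecules/cell in the published analysis), a reliability filter on
#' the TE denominator.
#'
#' @param records Data frame with an `mrna_level` column.
#' @param threshold Strict lower threshold (molecules/cell).
#' @return The filtered data frame.
#' @export
filter_mrna_level <- function(records, threshold = 0.5) {
  stopifnot("mrna_level" %in% names(records))
  keep <- !is.na(records$mrna_level) & records$mrna_level > threshold
  records[keep, , drop = FALSE]
}

replicate_stats <- function(records, cols) {
  m <- as.matrix(records[, cols, drop = FALSE])
  means <- rowMeans(m, na.rm = TRUE)
  ratio <- apply(m, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) <= 1L) return(1)  # single replicate: vacuously consistent
    if (min(x) <= 0) return(Inf)
    max(x) / min(x)
  })
  list(mean = means, ratio = ratio)
}

#' Filter genes on RPKM reliability
#'
#' Keeps genes for which BOTH the footprint and the mRNA-fragment replicate
#' series have mean RPKM strictly greater than `min_mean` and max/min
#' replicate ratio strictly below `max_fold` (the published thresholds:
#' mean > 1, variation < 1.5-fold). Single-replicate series pass the
#' variation check vacuously.
#'
#' @param records Data frame with replicate columns.
#' @param footprint_cols,mrna_cols Column names of the replicate series;
#'   default to columns matching `^fp_` and `^mr_`.
#' @param min_mean Strict lower bound on the replicate mean.
#' @param max_fold Strict upper bound on the max/min replicate ratio.
#' @return The filtered data frame.
#' @export
filter_rpkm <- function(records,
                        footprint_cols = grep("^fp_", names(records), value = TRUE),
                        mrna_cols = grep("^mr_", names(records), value = TRUE),
                        min_mean = 1, max_fold = 1.5) {
  stopifnot(length(footprint_cols) >= 1L, length(mrna_cols) >= 1L)
  fp <- replicate_stats(records, footprint_cols)
  mr <- replicate_stats(records, mrna_cols)
  keep <- fp$mean > min_mean & fp$ratio < max_fold &
    mr$mean > min_mean & mr$ratio < max_fold
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Compute per-gene TE/RD metrics from an expression table
#'
#' Applies [translation_efficiency()] and [ribosome_density()] columnwise
#' and records which reliability filters each gene passes, without dropping
#' any row (filter flags, not removal).
#'
#' @inheritParams filter_rpkm
#' @param records Data frame with `gene_id`, `mrna_level`,
#'   `protein_abundance` and replicate columns.
#' @param mrna_threshold Strict threshold for the mRNA-level filter.
#' @return Tibble: `gene_id`, `te`, `rd`, `passed_te_filter`,
#'   `passed_rd_filter`.
#' @export
gene_metrics <- function(records,
                         footprint_cols = grep("^fp_", names(records), value = TRUE),
                         mrna_cols = grep("^mr_", names(records), value = TRUE),
                         mrna_threshold = 0.5, min_mean = 1, max_fold = 1.5) {
  stopifnot(all(c("gene_id", "mrna_level", "protein_abundance") %in%
                  names(records)))
  fp <- replicate_stats(records, footprint_cols)
  mr <- replicate_stats(records, mrna_cols)
  tibble::tibble(
    gene_id = records$gene_id,
    mrna_level = records$mrna_level,
    protein_abundance = records$protein_abundance,
    te = translation_efficiency(records$protein_abundance, records$mrna_level),
    rd = ribosome_density(fp$mean, mr$mean),
    fp_rpkm_mean = fp$mean,
    mr_rpkm_mean = mr$mean,
    passed_te_filter = !is.na(records$mrna_level) &
      records$mrna_level > mrna_threshold,
    passed_rd_filter = fp$mean > min_mean & fp$ratio < max_fold &
      mr$mean > min_mean & mr$ratio < max_fold)
}

#' Join supply, metrics and sequence features into one gene table
#'
#' Inner join on the shared gene/protein id space; duplicate ids within an
#' input and empty intersections are errors (they indicate malformed
#' inputs, not missing data). Missing covariates within a surviving row are
#' kept as `NA` and flagged by downstream statistics as needed.
#'
#' @param supply Tibble from [supply_table()] (`protein_id` key).
#' @param metrics Tibble from [gene_metrics()] (`gene_id` key).
#' @param features Optional tibble with a `gene_id` column and covariates
#'   (e.g. `cai`, `folding_energy`).
#' @param id_map Optional two-column data frame (`protein_id`, `gene_id`)
#'   when the id spaces differ.
#' @return Tibble with one row per gene, class `gene_table`.
#' @export
build_gene_table <- function(supply, metrics, features = NULL, id_map = NULL) {
  sup <- tibble::as_tibble(supply)
  if (!is.null(id_map)) {
    stopifnot(all(c("protein_id", "gene_id") %in% names(id_map)))
    sup <- merge(sup, id_map, by = "protein_id")
  } else {
    sup$gene_id <- sup$protein_id
  }
  for (nm in c("supply input", "metrics input")) {
    tab <- if (nm == "supply input") sup$gene_id else metrics$gene_id
    dup <- unique(tab[duplicated(tab)])
    if (length(dup)) {
      stop("duplicated id(s) in ", nm, ": ", paste(dup, collapse = ", "))
    }
  }
  out <- merge(sup, tibble::as_tibble(metrics), by = "gene_id")
  if (nrow(out) == 0L) stop("no shared ids between supply and metrics tables")
  if (!is.null(features)) {
    fdup <- unique(features$gene_id[duplicated(features$gene_id)])
    if (length(fdup)) {
      stop("duplicated id(s) in features input: ", paste(fdup, collapse = ", "))
    }
    out <- merge(out, tibble::as_tibble(features), by = "gene_id",
                 all.x = TRUE)
  }
  out <- tibble::as_tibble(out)
  class(out) <- c("gene_table", class(out))
  out
}
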