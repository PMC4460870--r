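#' Ribosome-density fold change under starvation
#'
#' Plain ratio (starved over normal), not a log ratio. A zero or missing
#' normal-condition density yields `NA`.
#'
#' @param rd_starved,rd_normal Numeric vectors.
#' @return Numeric vector of fold changes.
#' @export
rd_fold_change <- function(rd_starved, rd_normal) {
  fc <- ifelse(!is.na(rd_normal) & rd_normal > 0,
               rd_starved / rd_normal, NA_real_)
  as.numeric(fc)
}

#' Split genes into well- and poorly-amino-acid-supplied halves
#'
#' WAAS is the top 50% of the supply ranking; with an odd number of genes
#' the WAAS group is the larger one (e.g. 2801 genes split 1401 vs 1400).
#' Ties at the median are resolved by stable input order, earlier rows
#' going to WAAS first.
#'
#' @param records Data frame with a `supply` column.
#' @return List with elements `waas` and `paas` (data frames) and
#'   `waas_idx` (row indices of the WAAS half in the input).
#' @export
split_waas_paas <- function(records) {
  stopifnot("supply" %in% names(records))
  supply <- records$supply
  if (anyNA(supply)) stop("supplies must be present for the WAAS/PAAS split")
  n <- length(supply)
  ord <- order(-supply)  # stable: ties keep input order
  waas_idx <- sort(ord[seq_len(ceiling(n / 2))])
  list(waas = records[waas_idx, , drop = FALSE],
       paas = records[-waas_idx, , drop = FALSE],
       waas_idx = waas_idx)
}

#' Compare starvation fold changes between WAAS and PAAS genes
#'
#' One-sided Wilcoxon rank-sum test of the buffering hypothesis: the RD
#' fold change of well-supplied genes is smaller than that of poorly
#' supplied genes.
#'
#' @param waas,paas Data frames with a `fold_change` column, or numeric
#'   vectors of fold changes.
#' @return A `group_comparison`: list with labels, `medians`, `n`,
#'   `p_value`, `alternative`.
#' @export
compare_fold_changes <- function(waas, paas) {
  fc_w <- if (is.data.frame(waas)) waas$fold_change else waas
  fc_p <- if (is.data.frame(paas)) paas$fold_change else paas
  ts <- wilcoxon_ranksum_one_sided(fc_w, fc_p, alternative = "x_less")
  structure(list(group_a_label = "WAAS", group_b_label = "PAAS",
                 medians = c(WAAS = ts$median_x, PAAS = ts$median_y),
                 n = c(WAAS = ts$n_x, PAAS = ts$n_y),
                 p_value = ts$p_value,
                 alternative = "WAAS fold change < PAAS fold change",
                 empty = FALSE),
            class = "group_comparison")
}

#' Compare mRNA levels of RD-increased genes against the rest
#'
#' RD-increased genes are those whose starvation fold change strictly
#' exceeds `fc_threshold` (2.0 in the published analysis); the test asks
#' whether their mRNA expression is lower than that of the other genes
#' (one-sided Wilcoxon rank-sum).
#'
#' @param records Data frame with `fold_change` and `mrna_level` columns.
#' @param fc_threshold Strict fold-change threshold.
#' @return A `group_comparison`; if no gene passes the threshold the
#'   result is flagged `empty = TRUE` with `NA` p-value.
#' @export
rd_increased_mrna_comparison <- function(records, fc_threshold = 2.0) {
  stopifnot(all(c("fold_change", "mrna_level") %in% names(records)))
  ok <- !is.na(records$fold_change) & !is.na(records$mrna_level)
  records <- records[ok, , drop = FALSE]
  inc <- records$fold_change > fc_threshold
  if (!any(inc) || all(inc)) {
    return(structure(list(group_a_label = "RD-increased",
                          group_b_label = "others",
                          medians = c(`RD-increased` = NA_real_,
                                      others = NA_real_),
                          n = c(`RD-increased` = sum(inc),
                                others = sum(!inc)),
                          p_value = NA_real_,
                          alternative = "RD-increased mRNA < others",
                          empty = TRUE),
                     class = "group_comparison"))
  }
  ts <- wilcoxon_ranksum_one_sided(records$mrna_level[inc],
                                   records$mrna_level[!inc],
                                   alternative = "x_less")
  structure(list(group_a_label = "RD-increased", group_b_label = "others",
                 medians = c(`RD-increased` = ts$median_x, others = ts$median_y),
                 n = c(`RD-increased` = ts$n_x, others = ts$n_y),
                 p_value = ts$p_value,
                 alternative = "RD-increased mRNA < others",
                 empty = FALSE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("Group comparison (", x$group_a_label, " vs ", x$group_b_label,
        "): empty group, no test\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("%s vs %s: medians %.4g vs %.4g, n %d vs %d, one-sided p = %.3g\n",
              x$group_a_label, x$group_b_label, x$medians[1], x$medians[2],
              x$n[1], x$n[2], x$p_value))
  invisible(x)
}
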