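#' Select the top eQTL variant per gene across a condition pair
#'
#' By default the variant with the smallest nominal p-value across the two
#' conditions' per-gene top records is chosen (`min_over_conditions`); exact
#' p ties are broken by smaller |distance to TSS|, then lexicographic
#' variant id. Genes absent from one condition are skipped with a warning.
#'
#' @param eqtl_ctrl,eqtl_stim `eqtl_result` tables (per-gene top records)
#'   for control and stimulus.
#' @param mode `"min_over_conditions"` (default), `"control_only"` or
#'   `"stimulus_only"`.
#' @return data.frame: gene_id, variant_id, source_condition.
#' @export
select_top_eqtl <- function(eqtl_ctrl, eqtl_stim,
                            mode = c("min_over_conditions", "control_only",
                                     "stimulus_only")) {
  mode <- match.arg(mode)
  shared <- intersect(eqtl_ctrl$gene_id, eqtl_stim$gene_id)
  dropped <- length(union(eqtl_ctrl$gene_id, eqtl_stim$gene_id)) - length(shared)
  if (dropped > 0) {
    warning(sprintf("%d gene(s) absent from one condition skipped", dropped))
  }
  rows <- lapply(shared, function(gid) {
    cand <- rbind(
      cbind(eqtl_ctrl[eqtl_ctrl$gene_id == gid,
                      c("variant_id", "p_nominal", "distance")],
            source_condition = "ctrl"),
      cbind(eqtl_stim[eqtl_stim$gene_id == gid,
                      c("variant_id", "p_nominal", "distance")],
            source_condition = "stim"))
    if (mode == "control_only") cand <- cand[cand$source_condition == "ctrl", ]
    if (mode == "stimulus_only") cand <- cand[cand$source_condition == "stim", ]
    cand <- cand[order(cand$p_nominal, abs(cand$distance), cand$variant_id), ]
    data.frame(gene_id = gid, variant_id = cand$variant_id[1],
               source_condition = cand$source_condition[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Slope-difference z-test for response (e2QTL) effects
#'
#' `z = (slope_stim - slope_ctrl) / sqrt(se_stim^2 + se_ctrl^2)` with a
#' two-sided standard-normal p-value. The two slope estimates are treated as
#' independent.
#'
#' @param slope_ctrl,se_ctrl,slope_stim,se_stim Numeric vectors (recycled).
#' @return data.frame: delta_slope, z, p.
#' @export
e2qtl_ztest <- function(slope_ctrl, se_ctrl, slope_stim, se_stim) {
  if (any(se_ctrl <= 0) || any(se_stim <= 0)) stopf("standard errors must be positive")
  delta <- slope_stim - slope_ctrl
  z <- delta / sqrt(se_stim^2 + se_ctrl^2)
  data.frame(delta_slope = delta, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Call response eQTL (e2QTL) for one condition pair
#'
#' Applies the slope-difference z-test to every gene's selected top variant
#' and Bonferroni-corrects over the number of genes tested in this
#' condition pair. Significance requires `p_bonf < alpha`.
#'
#' @param top Output of [select_top_eqtl()].
#' @param stats_ctrl,stats_stim data.frames with gene_id, variant_id, slope,
#'   se covering the selected pairs in each condition (e.g. from
#'   [map_cis_nominal()]).
#' @param condition Stimulus label stored in the output.
#' @param alpha Significance level on the Bonferroni-adjusted p. Default 0.05.
#' @return Class `e2qtl_result` data.frame: gene_id, variant_id, condition,
#'   slope_ctrl, se_ctrl, slope_stim, se_stim, delta_slope, z, p, p_bonf,
#'   significant; attribute `n_tests`.
#' @export
call_response_eqtl <- function(top, stats_ctrl, stats_stim,
                               condition = "stim", alpha = 0.05) {
  key <- function(d) paste(d$gene_id, d$variant_id)
  ic <- match(key(top), key(stats_ctrl))
  is_ <- match(key(top), key(stats_stim))
  ok <- !is.na(ic) & !is.na(is_)
  ok[ok] <- ok[ok] & stats_ctrl$se[ic[ok]] > 0 & stats_stim$se[is_[ok]] > 0
  if (!all(ok)) {
    warning(sprintf("%d gene(s) without usable slope estimates in both conditions skipped",
                    sum(!ok)))
  }
  top <- top[ok, , drop = FALSE]
  ic <- ic[ok]; is_ <- is_[ok]
  n_tests <- nrow(top)
  if (n_tests == 0) stopf("no gene with slope estimates in both conditions")
  zt <- e2qtl_ztest(stats_ctrl$slope[ic], stats_ctrl$se[ic],
                    stats_stim$slope[is_], stats_stim$se[is_])
  out <- data.frame(
    gene_id = top$gene_id, variant_id = top$variant_id,
    condition = condition,
    slope_ctrl = stats_ctrl$slope[ic], se_ctrl = stats_ctrl$se[ic],
    slope_stim = stats_stim$slope[is_], se_stim = stats_stim$se[is_],
    delta_slope = zt$delta_slope, z = zt$z, p = zt$p,
    p_bonf = pmin(1, zt$p * n_tests),
    stringsAsFactors = FALSE)
  out$significant <- out$p_bonf < alpha
  rownames(out) <- NULL
  class(out) <- c("e2qtl_result", "data.frame")
  attr(out, "n_tests") <- n_tests
  attr(out, "fraction_significant") <- mean(out$significant)
  out
}

#' Full response-eQTL analysis for one condition pair
#'
#' Convenience wrapper: selects the top variant per gene from the two
#' conditions' gene-level eQTL results, refits slope and SE for that variant
#' in both conditions via the nominal scan, and calls e2QTL.
#'
#' @param genotypes `genotype_matrix`.
#' @param prepared_ctrl,prepared_stim `prepared_expression` objects.
#' @param eqtl_ctrl,eqtl_stim `eqtl_result` tables from [map_cis_eqtl()].
#' @param condition Stimulus label.
#' @param alpha Bonferroni significance level. Default 0.05.
#' @param mode Top-variant selection mode (see [select_top_eqtl()]).
#' @param df_adjust Passed to [nominal_scan()].
#' @return An `e2qtl_result` (see [call_response_eqtl()]).
#' @export
map_response_eqtl <- function(genotypes, prepared_ctrl, prepared_stim,
                              eqtl_ctrl, eqtl_stim, condition = "stim",
                              alpha = 0.05, mode = "min_over_conditions",
                              df_adjust = 0) {
  g <- as_genotype_matrix(genotypes)
  top <- select_top_eqtl(eqtl_ctrl, eqtl_stim, mode = mode)
  refit <- function(prepared) {
    do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
      gid <- top$gene_id[i]
      if (!gid %in% colnames(prepared$expr)) return(NULL)
      sc <- nominal_scan(prepared$expr[, gid],
                         g$dosage[, top$variant_id[i], drop = FALSE],
                         df_adjust = df_adjust)
      if (nrow(sc) == 0) return(NULL)
      cbind(gene_id = gid, sc)
    }))
  }
  call_response_eqtl(top, refit(prepared_ctrl), refit(prepared_stim),
                     condition = condition, alpha = alpha)
}
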