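#' Overlap eQTL and e2QTL results with GWAS hits
#'
#' Assembles the trait-association table. GWAS hits are first restricted to
#' genome-wide significance (`p < gwas_p_max`). For every hit present in the
#' genotype matrix and every mapped gene whose cis window contains it, a
#' record is emitted when either
#' \itemize{
#'   \item the gene is a Bonferroni-significant e2QTL in that condition, the
#'     gene is a significant eQTL (`qval < qval_max`), and the GWAS variant
#'     is in strong LD (`r2 > r2_min`) with the top e2QTL variant
#'     (class `e2qtl`; no differential-expression requirement); or
#'   \item the gene is a significant eQTL (`qval < qval_max`), strongly
#'     differentially expressed (`p_adj < de_p_adj_max` and
#'     `|log2fc| > de_abs_log2fc_min`), and the GWAS variant is in strong LD
#'     with the top eQTL variant (class `eqtl`).
#' }
#' All comparisons are strict, one record per (gene, trait, condition); when
#' both rules apply the e2QTL class takes precedence.
#'
#' @param eqtl `eqtl_result` for the condition (per-gene top records with
#'   qval).
#' @param e2qtl `e2qtl_result` for the condition (may be NULL when the
#'   condition is the control).
#' @param de `de_result` for the condition (may be NULL for the control).
#' @param gwas_hits data.frame: variant_id, trait, p (risk_allele optional).
#' @param genotypes `genotype_matrix` for LD computation.
#' @param genes Gene annotation (gene_id, chrom, tss).
#' @param condition Condition label for the output.
#' @param r2_min LD threshold. Default 0.7.
#' @param qval_max eQTL significance threshold. Default 0.05.
#' @param de_p_adj_max,de_abs_log2fc_min DE filter for the eqtl class.
#'   Defaults 0.05 and 2.
#' @param window cis window half-width. Default 1e6.
#' @param gwas_p_max Genome-wide significance filter applied to the hits on
#'   read. Default 5e-8.
#' @param coloc_results Optional named list (by gene_id) of `coloc_result`
#'   objects whose posteriors are attached to matching records.
#' @return Class `trait_association` data.frame: gene_id, condition, trait,
#'   gwas_variant, top_eqtl_variant, ld_r2, slope, qval, de_log2fc, de_p_adj,
#'   association_class, pp_h4, pp_ratio.
#' @export
gwas_overlap <- function(eqtl, e2qtl, de, gwas_hits, genotypes, genes,
                         condition = "stim", r2_min = 0.7, qval_max = 0.05,
                         de_p_adj_max = 0.05, de_abs_log2fc_min = 2,
                         window = 1e6, gwas_p_max = 5e-8,
                         coloc_results = NULL) {
  g <- as_genotype_matrix(genotypes)
  if (!is.null(gwas_hits$p)) gwas_hits <- gwas_hits[gwas_hits$p < gwas_p_max, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(gwas_hits))) {
    hv <- gwas_hits$variant_id[i]
    if (!hv %in% colnames(g$dosage)) {
      warning(sprintf("GWAS variant %s absent from genotypes; skipped", hv))
      next
    }
    hpos <- g$variants$pos[match(hv, g$variants$variant_id)]
    hchrom <- g$variants$chrom[match(hv, g$variants$variant_id)]
    for (k in seq_len(nrow(eqtl))) {
      gid <- eqtl$gene_id[k]
      ann <- genes[genes$gene_id == gid, , drop = FALSE]
      if (nrow(ann) == 0 || ann$chrom[1] != hchrom ||
          abs(hpos - ann$tss[1]) > window) next
      sig_eqtl <- eqtl$qval[k] < qval_max
      rec <- NULL
      e2row <- if (!is.null(e2qtl)) e2qtl[e2qtl$gene_id == gid, , drop = FALSE] else NULL
      if (!is.null(e2row) && nrow(e2row) && e2row$significant[1] && sig_eqtl) {
        r2 <- tryCatch(ld_r2(g$dosage[, hv], g$dosage[, e2row$variant_id[1]]),
                       error = function(e) NA_real_)
        if (!is.na(r2) && r2 > r2_min) {
          rec <- list(top_variant = e2row$variant_id[1], r2 = r2,
                      class = "e2qtl", slope = e2row$slope_stim[1])
        }
      }
      de_row <- if (!is.null(de)) de[de$gene_id == gid, , drop = FALSE] else NULL
      de_lfc <- if (!is.null(de_row) && nrow(de_row)) de_row$log2fc[1] else NA_real_
      de_padj <- if (!is.null(de_row) && nrow(de_row)) de_row$p_adj[1] else NA_real_
      if (is.null(rec) && sig_eqtl && !is.na(de_padj) &&
          de_padj < de_p_adj_max && abs(de_lfc) > de_abs_log2fc_min) {
        r2 <- tryCatch(ld_r2(g$dosage[, hv], g$dosage[, eqtl$variant_id[k]]),
                       error = function(e) NA_real_)
        if (!is.na(r2) && r2 > r2_min) {
          rec <- list(top_variant = eqtl$variant_id[k], r2 = r2,
                      class = "eqtl", slope = eqtl$slope[k])
        }
      }
      if (is.null(rec)) next
      cl <- if (!is.null(coloc_results) && gid %in% names(coloc_results)) {
        coloc_results[[gid]]
      } else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, condition = condition,
        trait = gwas_hits$trait[i], gwas_variant = hv,
        top_eqtl_variant = rec$top_variant, ld_r2 = rec$r2,
        slope = rec$slope, qval = eqtl$qval[k],
        de_log2fc = de_lfc, de_p_adj = de_padj,
        association_class = rec$class,
        pp_h4 = if (!is.null(cl)) unname(cl$summary["pp_h4"]) else NA_real_,
        pp_ratio = if (!is.null(cl)) cl$ratio_h4_h3 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), condition = character(0),
                      trait = character(0), gwas_variant = character(0),
                      top_eqtl_variant = character(0), ld_r2 = numeric(0),
                      slope = numeric(0), qval = numeric(0),
                      de_log2fc = numeric(0), de_p_adj = numeric(0),
                      association_class = character(0), pp_h4 = numeric(0),
                      pp_ratio = numeric(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_id, out$trait, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trait_association", "data.frame")
  out
}

#' Compare two eQTL result sets
#'
#' Concordance report over the shared (gene, variant) pairs: Spearman rank
#' correlation of slopes, and the genes whose shared pairs all have
#' opposite-sign slopes in the two sets.
#'
#' @param set_a,set_b data.frames with gene_id, variant_id, slope.
#' @return Class `eqtl_concordance`: list with `spearman`, `n_shared_pairs`,
#'   `opposite_genes`, `n_opposite`, `pairs`.
#' @export
compare_eqtl_sets <- function(set_a, set_b) {
  m <- merge(set_a[, c("gene_id", "variant_id", "slope")],
             set_b[, c("gene_id", "variant_id", "slope")],
             by = c("gene_id", "variant_id"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stopf("no shared (gene, variant) pairs")
  rho <- stats::cor(m$slope_a, m$slope_b, method = "spearman")
  opp <- tapply(sign(m$slope_a) * sign(m$slope_b) < 0 &
                  m$slope_a != 0 & m$slope_b != 0,
                m$gene_id, all)
  opposite <- names(opp)[which(opp)]
  structure(list(spearman = rho, n_shared_pairs = nrow(m),
                 opposite_genes = sort(opposite),
                 n_opposite = length(opposite), pairs = m),
            class = "eqtl_concordance")
}

#' @export
print.eqtl_concordance <- function(x, ...) {
  cat(sprintf("eQTL concordance: Spearman %.3f over %d shared pairs; %d gene(s) with consistently opposite slopes\n",
              x$spearman, x$n_shared_pairs, x$n_opposite))
  invisible(x)
}
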