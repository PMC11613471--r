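#' Configuration for the synthetic stimulation-design generator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study design the package targets: 461 donors whose
#' CD8+ T cells are split into six paired subsets (untreated control plus five
#' genotoxic stimuli), common variants organised in LD blocks, planted
#' cis-eQTL whose slopes attenuate upon stimulation, and a global-repression
#' differential-expression signature in which 85-99% of true DEGs per
#' stimulus are downregulated.
#'
#' @param n_donors Number of donors (same donors in every condition; paired
#'   design). Default 461.
#' @param n_variants Number of biallelic variants. Default 200.
#' @param n_genes Number of genes. Default 500.
#' @param maf_range Length-2 numeric in (0, 0.5]; allele frequencies are drawn
#'   uniformly from this interval. Default c(0.05, 0.5).
#' @param ld_block_size Number of consecutive variants per LD block. Default 10.
#' @param ld_decay Haplotype-copy probability in \[0, 1): adjacent variants in
#'   a block share their latent uniform with this probability, so expected r2
#'   decays geometrically with distance. Default 0.9.
#' @param conditions Ordered condition labels; the first is the unstimulated
#'   control. Default `c("CTRL","BPDE","HC","MMS","TBOOH","UVC")`.
#' @param planted_eqtl Optional data.frame with columns `gene_id`,
#'   `variant_id`, `condition`, `slope` (natural-log scale per alt-allele
#'   dosage). If `NULL`, `n_eqtl` gene/variant pairs are planted with slope
#'   `eqtl_slope` in the control and `eqtl_slope * eqtl_attenuation` in every
#'   stimulus.
#' @param n_eqtl Number of auto-planted cis-eQTL. Default 50.
#' @param eqtl_slope Control-condition eQTL slope (log-scale). Default 0.5.
#' @param eqtl_attenuation Multiplier applied to stimulus slopes; < 1 models
#'   the reduced genetic effect upon stimulation. Default 0.4.
#' @param de_fraction Fraction of genes that are true DEGs in each stimulus.
#'   Default 0.25.
#' @param de_shared Fraction of each stimulus' DEGs drawn from a common pool
#'   shared across stimuli (the rest are stimulus-specific). Default 0.5.
#' @param repressed_fraction Named numeric (per stimulus) or scalar: fraction
#'   of true DEGs that are downregulated. Defaults span the 85-99% repression
#'   range observed across stimuli (HC lowest, UVC highest).
#' @param de_logfc_location,de_logfc_scale Location/scale of the absolute
#'   log2 fold-change distribution (normal, truncated positive) for true DEGs.
#'   Defaults 2.5 and 0.5.
#' @param nb_dispersion Negative-binomial dispersion (1/size). Default 0.1.
#' @param mean_depth Mean library size (reads per sample). Default 1e7,
#'   matching 10M-read bulk libraries.
#' @param depth_sd_log Log-normal sd of library sizes. Default 0.2.
#' @param call_rate Genotype call rate; dosages are set missing with
#'   probability `1 - call_rate`. Default 1 (no missingness).
#' @param n_outliers Number of deliberately corrupted expression samples per
#'   stimulated condition (for outlier-QC testing). Default 0.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `sim_config` (validated list).
#' @export
simulation_config <- function(n_donors = 461,
                              n_variants = 200,
                              n_genes = 500,
                              maf_range = c(0.05, 0.5),
                              ld_block_size = 10,
                              ld_decay = 0.9,
                              conditions = c("CTRL", "BPDE", "HC", "MMS", "TBOOH", "UVC"),
                              planted_eqtl = NULL,
                              n_eqtl = 50,
                              eqtl_slope = 0.5,
                              eqtl_attenuation = 0.4,
                              de_fraction = 0.25,
                              de_shared = 0.5,
                              repressed_fraction = NULL,
                              de_logfc_location = 2.5,
                              de_logfc_scale = 0.5,
                              nb_dispersion = 0.1,
                              mean_depth = 1e7,
                              depth_sd_log = 0.2,
                              call_rate = 1,
                              n_outliers = 0,
                              seed = 1L) {
  if (!is.numeric(n_donors) || n_donors < 1) stopf("n_donors must be a positive count")
  if (!is.numeric(n_variants) || n_variants < 1) stopf("n_variants must be a positive count")
  if (!is.numeric(n_genes) || n_genes < 1) stopf("n_genes must be a positive count")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stopf("maf_range must be an increasing pair within (0, 0.5]")
  }
  if (ld_block_size < 1) stopf("ld_block_size must be >= 1")
  if (ld_decay < 0 || ld_decay >= 1) stopf("ld_decay must lie in [0, 1)")
  if (length(conditions) < 2 || anyDuplicated(conditions)) {
    stopf("conditions must be >= 2 distinct labels (control first)")
  }
  stimuli <- conditions[-1]
  if (is.null(repressed_fraction)) {
    # within the 85-99% repression range; HC lowest, UVC highest
    base <- c(BPDE = 0.95, HC = 0.85, MMS = 0.90, TBOOH = 0.93, UVC = 0.99)
    repressed_fraction <- ifelse(stimuli %in% names(base), base[stimuli], 0.92)
    names(repressed_fraction) <- stimuli
  } else if (length(repressed_fraction) == 1L) {
    repressed_fraction <- stats::setNames(rep(repressed_fraction, length(stimuli)), stimuli)
  } else {
    if (!all(stimuli %in% names(repressed_fraction))) {
      stopf("repressed_fraction must be scalar or named for every stimulus")
    }
    repressed_fraction <- repressed_fraction[stimuli]
  }
  if (any(repressed_fraction < 0 | repressed_fraction > 1)) {
    stopf("repressed_fraction must lie in [0, 1]")
  }
  if (de_fraction < 0 || de_fraction > 1) stopf("de_fraction must lie in [0, 1]")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (mean_depth <= 0) stopf("mean_depth must be positive")
  if (call_rate <= 0 || call_rate > 1) stopf("call_rate must lie in (0, 1]")
  if (!is.null(planted_eqtl)) {
    need <- c("gene_id", "variant_id", "condition", "slope")
    if (!all(need %in% names(planted_eqtl))) {
      stopf("planted_eqtl needs columns %s", paste(need, collapse = ", "))
    }
    if (any(!is.finite(planted_eqtl$slope))) stopf("planted slopes must be finite")
  }
  structure(list(
    n_donors = as.integer(n_donors), n_variants = as.integer(n_variants),
    n_genes = as.integer(n_genes), maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size), ld_decay = ld_decay,
    conditions = conditions, planted_eqtl = planted_eqtl,
    n_eqtl = as.integer(n_eqtl), eqtl_slope = eqtl_slope,
    eqtl_attenuation = eqtl_attenuation, de_fraction = de_fraction,
    de_shared = de_shared, repressed_fraction = repressed_fraction,
    de_logfc_location = de_logfc_location, de_logfc_scale = de_logfc_scale,
    nb_dispersion = nb_dispersion, mean_depth = mean_depth,
    depth_sd_log = depth_sd_log, call_rate = call_rate,
    n_outliers = as.integer(n_outliers), seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  donors: %d, variants: %d (LD blocks of %d, decay %.2f), genes: %d\n",
              x$n_donors, x$n_variants, x$ld_block_size, x$ld_decay, x$n_genes))
  cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = ", ")))
  cat(sprintf("  planted eQTL: %s; DE fraction %.2f (repressed %s)\n",
              if (is.null(x$planted_eqtl)) sprintf("%d auto (slope %.2f, attenuation %.2f)",
                                                   x$n_eqtl, x$eqtl_slope, x$eqtl_attenuation)
              else sprintf("%d records", nrow(x$planted_eqtl)),
              x$de_fraction,
              paste(sprintf("%s=%.2f", names(x$repressed_fraction),
                            x$repressed_fraction), collapse = " ")))
  invisible(x)
}
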