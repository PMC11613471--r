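#' Simulate a genotype matrix with block LD structure
#'
#' Generates biallelic dosages (0/1/2) for `n_donors` diploid individuals by
#' haplotype copying: within each LD block, a haplotype's latent uniform at a
#' variant is copied from the previous variant with probability `ld_decay` and
#' redrawn otherwise, so adjacent variants share alleles with geometrically
#' decaying probability and expected r2 decays with distance. Marginal allele
#' frequencies are exactly the per-variant frequencies drawn uniformly from
#' `maf_range`, regardless of the copying. Variants are placed every 5 kb
#' along a single chromosome so downstream cis windows are well populated.
#'
#' @param config A [simulation_config()] object.
#' @return A `genotype_matrix`: list with `dosage` (donors x variants, NA for
#'   missing calls) and `variants` (data.frame: variant_id, chrom, pos, ref,
#'   alt, block, freq).
#' @export
simulate_genotypes <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must come from simulation_config()")
  n <- config$n_donors
  m <- config$n_variants
  with_seed(config$seed, {
    freq <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    block <- rep(seq_len(ceiling(m / config$ld_block_size)),
                 each = config$ld_block_size)[seq_len(m)]
    hap <- function() {
      u <- matrix(NA_real_, n, m)
      for (j in seq_len(m)) {
        fresh <- stats::runif(n)
        if (j > 1 && block[j] == block[j - 1] && config$ld_decay > 0) {
          keep <- stats::runif(n) < config$ld_decay
          u[, j] <- ifelse(keep, u[, j - 1], fresh)
        } else {
          u[, j] <- fresh
        }
      }
      u < rep(freq, each = n)   # TRUE = alt allele, marginally Bernoulli(freq)
    }
    dosage <- hap() + hap()
    storage.mode(dosage) <- "double"
    if (config$call_rate < 1) {
      miss <- stats::runif(length(dosage)) > config$call_rate
      dosage[miss] <- NA_real_
    }
    dimnames(dosage) <- list(sprintf("D%04d", seq_len(n)),
                             sprintf("var%04d", seq_len(m)))
    variants <- data.frame(
      variant_id = colnames(dosage),
      chrom = "1",
      pos = 1000000L + (seq_len(m) - 1L) * 5000L,
      ref = "A", alt = "G",
      block = block,
      freq = freq,
      stringsAsFactors = FALSE
    )
    structure(list(dosage = dosage, variants = variants,
                   sim = list(freq = freq, block = block,
                              ld_decay = config$ld_decay)),
              class = "genotype_matrix")
  })
}

#' Re-simulate a larger cohort sharing a genotype matrix's LD structure
#'
#' Draws a fresh cohort of `n` individuals from the same allele frequencies,
#' block layout and copying probability that generated a simulated
#' `genotype_matrix`, so GWAS cohorts can re-use the eQTL cohort's LD.
#'
#' @param genotypes A simulated `genotype_matrix` (must carry its `sim` recipe).
#' @param n Cohort size.
#' @param seed Integer seed.
#' @return A `genotype_matrix` for the new cohort.
#' @export
resimulate_cohort <- function(genotypes, n, seed) {
  genotypes <- as_genotype_matrix(genotypes)
  if (is.null(genotypes$sim)) stopf("genotype matrix carries no simulation recipe")
  freq <- genotypes$sim$freq
  block <- genotypes$sim$block
  decay <- genotypes$sim$ld_decay
  m <- length(freq)
  with_seed(seed, {
    hap <- function() {
      u <- matrix(NA_real_, n, m)
      for (j in seq_len(m)) {
        fresh <- stats::runif(n)
        if (j > 1 && block[j] == block[j - 1] && decay > 0) {
          keep <- stats::runif(n) < decay
          u[, j] <- ifelse(keep, u[, j - 1], fresh)
        } else {
          u[, j] <- fresh
        }
      }
      u < rep(freq, each = n)
    }
    dosage <- hap() + hap()
    storage.mode(dosage) <- "double"
    dimnames(dosage) <- list(sprintf("S%05d", seq_len(n)),
                             genotypes$variants$variant_id)
    structure(list(dosage = dosage, variants = genotypes$variants,
                   sim = genotypes$sim),
              class = "genotype_matrix")
  })
}

#' Coerce dosage input to a `genotype_matrix`
#'
#' Accepts an existing `genotype_matrix` or a plain donors x variants dosage
#' matrix (variant metadata then defaults to unknown positions).
#'
#' @param x `genotype_matrix` or numeric matrix.
#' @return A `genotype_matrix`.
#' @export
as_genotype_matrix <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x)
  if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- sprintf("var%04d", seq_len(ncol(x)))
    if (is.null(rownames(x))) rownames(x) <- sprintf("D%04d", seq_len(nrow(x)))
    variants <- data.frame(variant_id = colnames(x),
                           chrom = rep("1", ncol(x)),
                           pos = seq_len(ncol(x)),
                           ref = rep("A", ncol(x)), alt = rep("G", ncol(x)),
                           block = rep(NA_integer_, ncol(x)),
                           freq = rep(NA_real_, ncol(x)),
                           stringsAsFactors = FALSE)
    return(structure(list(dosage = x, variants = variants, sim = NULL),
                     class = "genotype_matrix"))
  }
  stopf("cannot coerce object of class %s to genotype_matrix", class(x)[1])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d donors x %d variants (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Per-variant summary statistics
#'
#' Computes minor allele frequency, call rate and the exact Hardy-Weinberg
#' p-value for every variant of a dosage matrix.
#'
#' @param genotypes `genotype_matrix` or dosage matrix.
#' @return data.frame: variant_id, maf, call_rate, hwe_p.
#' @export
variant_stats <- function(genotypes) {
  g <- as_genotype_matrix(genotypes)
  d <- g$dosage
  called <- colSums(!is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  data.frame(variant_id = colnames(d),
             maf = maf,
             call_rate = called / nrow(d),
             hwe_p = hwe,
             row.names = NULL, stringsAsFactors = FALSE)
}
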