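#' Simulate GWAS summary statistics at a locus
#'
#' Simulates a cohort re-using the LD structure of a genotype matrix, draws a
#' phenotype from a single causal variant, and computes per-variant marginal
#' association statistics (beta, SE, p). Quantitative traits use per-variant
#' simple linear regression on a standard-normal-noise phenotype;
#' case-control traits use per-variant logistic regression on a liability
#' generated from the causal log-odds-ratio.
#'
#' @param genotypes `genotype_matrix` (simulated; its LD recipe is re-used
#'   when `n` exceeds the stored cohort).
#' @param causal_variant Variant id of the causal variant (must exist).
#' @param effect Causal effect: phenotype SD per alt allele (quant) or log
#'   odds ratio (cc).
#' @param n Cohort size. Default 10000.
#' @param type `"quant"` (default) or `"cc"`.
#' @param case_fraction Target case fraction for `type = "cc"`. Default 0.5.
#' @param trait Trait label.
#' @param seed Integer seed.
#' @return A `gwas_summary` data.frame: variant_id, chrom, pos, effect_allele,
#'   other_allele, beta, se, z, p, n (attributes: trait, type).
#' @export
simulate_gwas_summary <- function(genotypes, causal_variant, effect,
                                  n = 10000, type = c("quant", "cc"),
                                  case_fraction = 0.5,
                                  trait = "trait1", seed = 1L) {
  type <- match.arg(type)
  g <- as_genotype_matrix(genotypes)
  if (!causal_variant %in% g$variants$variant_id) {
    stopf("causal variant %s absent from genotype matrix", causal_variant)
  }
  cohort <- if (n <= nrow(g$dosage) && !anyNA(g$dosage)) {
    g$dosage[seq_len(n), , drop = FALSE]
  } else {
    resimulate_cohort(g, n, seed = seed + 7L)$dosage
  }
  with_seed(seed, {
    x_causal <- cohort[, causal_variant]
    if (type == "quant") {
      y <- effect * x_causal + stats::rnorm(n)
      yc <- y - mean(y)
      Xc <- sweep(cohort, 2, colMeans(cohort))
      sxx <- colSums(Xc^2)
      ok <- sxx > 0
      beta <- se <- p <- rep(NA_real_, ncol(cohort))
      beta[ok] <- colSums(Xc[, ok, drop = FALSE] * yc) / sxx[ok]
      rss <- sum(yc^2) - beta[ok]^2 * sxx[ok]
      se[ok] <- sqrt(pmax(rss, 0) / (n - 2) / sxx[ok])
      tt <- beta[ok] / se[ok]
      p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
    } else {
      alpha <- stats::qlogis(case_fraction) - effect * mean(x_causal)
      status <- stats::rbinom(n, 1, stats::plogis(alpha + effect * x_causal))
      beta <- se <- p <- rep(NA_real_, ncol(cohort))
      for (j in seq_len(ncol(cohort))) {
        xj <- cohort[, j]
        if (stats::var(xj) == 0) next
        fit <- suppressWarnings(
          stats::glm.fit(cbind(1, xj), status, family = stats::binomial()))
        cf <- fit$coefficients[2]
        # observed-information SE from the final IRLS weights
        W <- fit$weights
        X <- cbind(1, xj)
        V <- solve(crossprod(X * sqrt(W)))
        beta[j] <- cf
        se[j] <- sqrt(V[2, 2])
        p[j] <- 2 * stats::pnorm(-abs(cf / se[j]))
      }
    }
    out <- data.frame(
      variant_id = g$variants$variant_id,
      chrom = g$variants$chrom,
      pos = g$variants$pos,
      effect_allele = g$variants$alt,
      other_allele = g$variants$ref,
      beta = beta, se = se, z = beta / se, p = p, n = n,
      stringsAsFactors = FALSE)
    out <- out[!is.na(out$beta), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "trait") <- trait
    attr(out, "type") <- type
    class(out) <- c("gwas_summary", "data.frame")
    out
  })
}
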