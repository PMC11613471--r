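#' Linkage disequilibrium r-squared from dosages
#'
#' Composite LD: squared Pearson correlation of the two dosage vectors over
#' pairwise-complete observations. Phase-free and invariant to allele
#' flips (`2 - dosage`).
#'
#' @param dosage_a,dosage_b Numeric dosage vectors of equal length (>= 3
#'   complete pairs).
#' @return r2 in \[0, 1\].
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b)) stopf("dosage vectors differ in length")
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 3) stopf("need at least 3 complete pairs")
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) stopf("constant dosage vector")
  stats::cor(a, b)^2
}

#' Wakefield approximate Bayes factor for association
#'
#' With `V = se^2`, prior effect variance `W = prior_sd^2` and `z = beta/se`:
#' `log ABF = 0.5 log(V/(V+W)) + z^2 W / (2 (V+W))`. Default prior sd is
#' 0.15 for quantitative traits and 0.2 for case-control effects on the
#' log-odds scale.
#'
#' @param beta Effect estimates.
#' @param se Standard errors (> 0).
#' @param trait_type `"quant"` or `"cc"`.
#' @param prior_sd Optional explicit prior sd (> 0).
#' @return Vector of log approximate Bayes factors.
#' @export
wakefield_abf <- function(beta, se, trait_type = c("quant", "cc"),
                          prior_sd = NULL) {
  trait_type <- match.arg(trait_type)
  if (any(se <= 0)) stopf("standard errors must be positive")
  if (is.null(prior_sd)) prior_sd <- if (trait_type == "quant") 0.15 else 0.2
  if (prior_sd <= 0) stopf("prior_sd must be positive")
  V <- se^2
  W <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * log(V / (V + W)) + z2 * W / (2 * (V + W))
}

#' Enumeration-based Bayesian colocalization of two association signals
#'
#' Single-causal-variant colocalization from summary statistics. Per-variant
#' Wakefield log ABFs are computed for each trait, and the five hypotheses
#' (H0 no association; H1/H2 association in one trait; H3 two distinct
#' causal variants; H4 one shared causal variant) are weighted as
#' `1, p1*S1, p2*S2, p1*p2*(S1*S2 - S12), p12*S12` with
#' `S1 = sum_i BF1_i`, `S2 = sum_j BF2_j`, `S12 = sum_i BF1_i BF2_i`, all in
#' log space (the H3 pair sum over distinct variants is evaluated by exact
#' leave-one-out log-sums, so it is never negative and is accurate even when
#' one variant dominates both traits). Effect alleles are harmonized first;
#' variants with irreconcilable alleles are dropped with a warning.
#'
#' @param trait1,trait2 data.frames with variant_id, beta, se (optionally
#'   effect_allele / other_allele for harmonization).
#' @param p1,p2 Prior probability a variant is causal for trait 1 / trait 2.
#'   Defaults 1e-4.
#' @param p12 Prior probability a variant is causal for both. Default 1e-5.
#' @param type1,type2 Trait types for the ABF prior sd. Default "quant".
#' @param prior_sd1,prior_sd2 Optional explicit prior sds.
#' @return Class `coloc_result`: list with `summary` (pp_h0..pp_h4),
#'   `n_variants`, `priors`, `ratio_h4_h3` and `labf` (per-variant log ABFs).
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      type1 = "quant", type2 = "quant",
                      prior_sd1 = NULL, prior_sd2 = NULL) {
  m <- merge(trait1, trait2, by = "variant_id", suffixes = c("_1", "_2"))
  if (nrow(m) == 0) stopf("no shared variants between the two traits")
  if (all(c("effect_allele_1", "other_allele_1",
            "effect_allele_2", "other_allele_2") %in% names(m))) {
    same <- m$effect_allele_1 == m$effect_allele_2 &
      m$other_allele_1 == m$other_allele_2
    flipped <- m$effect_allele_1 == m$other_allele_2 &
      m$other_allele_1 == m$effect_allele_2
    m$beta_2[flipped] <- -m$beta_2[flipped]
    bad <- !(same | flipped)
    if (any(bad)) {
      warning(sprintf("%d variant(s) with irreconcilable alleles dropped", sum(bad)))
      m <- m[!bad, , drop = FALSE]
      if (nrow(m) == 0) stopf("no harmonizable shared variants")
    }
  }
  l1 <- wakefield_abf(m$beta_1, m$se_1, type1, prior_sd1)
  l2 <- wakefield_abf(m$beta_2, m$se_2, type2, prior_sd2)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  # H3 enumerates pairs of distinct causal variants:
  # sum_{i != j} BF1_i BF2_j = sum_i BF1_i * (S2 - BF2_i), evaluated with
  # exact leave-one-out log-sums for moderate loci (robust when one variant
  # dominates both traits) and a scaled subtraction otherwise
  nv <- length(l2)
  loo2 <- if (nv == 1) {
    -Inf
  } else if (nv <= 512) {
    vapply(seq_len(nv), function(i) logsumexp(l2[-i]), numeric(1))
  } else {
    m2 <- max(l2)
    log(pmax(sum(exp(l2 - m2)) - exp(l2 - m2), 0)) + m2
  }
  ls3 <- logsumexp(l1 + loo2)
  lw <- c(h0 = 0,
          h1 = log(p1) + ls1,
          h2 = log(p2) + ls2,
          h3 = log(p1) + log(p2) + ls3,
          h4 = log(p12) + ls12)
  pp <- exp(lw - logsumexp(lw))
  names(pp) <- paste0("pp_", names(lw))
  structure(list(
    summary = pp,
    n_variants = nrow(m),
    priors = c(p1 = p1, p2 = p2, p12 = p12),
    ratio_h4_h3 = unname(pp["pp_h4"] / pp["pp_h3"]),
    labf = data.frame(variant_id = m$variant_id, labf_1 = l1, labf_2 = l2,
                      stringsAsFactors = FALSE)
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d variants (p1=%.1e, p2=%.1e, p12=%.1e)\n",
              x$n_variants, x$priors["p1"], x$priors["p2"], x$priors["p12"]))
  print(round(x$summary, 4))
  cat(sprintf("  PP.H4/PP.H3 = %.3g\n", x$ratio_h4_h3))
  invisible(x)
}
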