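# shared fixture builders; everything is generated in code at test time

small_config <- function(...) {
  args <- list(n_donors = 150, n_variants = 30, n_genes = 40, n_eqtl = 5,
               maf_range = c(0.2, 0.4), seed = 42L,
               conditions = c("CTRL", "UVC"))
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

# dosage matrix with independent variants at given MAFs (HWE by construction)
random_dosages <- function(n, mafs, seed = 1) {
  withr::with_seed(seed, {
    d <- vapply(mafs, function(f) stats::rbinom(n, 2, f), numeric(n))
    colnames(d) <- sprintf("var%04d", seq_along(mafs))
    rownames(d) <- sprintf("D%04d", seq_len(n))
    d
  })
}

# full-enumeration oracle for the exact HWE test (independent of the
# implementation: plain normalized Levene-Haldane probabilities)
hwe_enumeration_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_rare <- min(n_a, 2 * n - n_a)
  hets <- seq.int(n_rare %% 2, n_rare, by = 2)
  probs <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - hom_rare - h
    exp(lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
          lfactorial(hom_common) + h * log(2) +
          lfactorial(n_rare) + lfactorial(2 * n - n_rare) - lfactorial(2 * n))
  }, numeric(1))
  probs <- probs / sum(probs)
  sum(probs[probs <= probs[match(n_Aa, hets)] * (1 + 1e-12)])
}

# brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m * p_(j) / j
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# brute-force colocalization: enumerate every causal configuration pair
coloc_enumeration_oracle <- function(bf1, bf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(bf1)
  h0 <- 1
  h1 <- p1 * sum(bf1)
  h2 <- p2 * sum(bf2)
  h3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) h3 <- h3 + p1 * p2 * bf1[i] * bf2[j]
  }
  h4 <- p12 * sum(bf1 * bf2)
  w <- c(h0, h1, h2, h3, h4)
  stats::setNames(w / sum(w), c("pp_h0", "pp_h1", "pp_h2", "pp_h3", "pp_h4"))
}
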