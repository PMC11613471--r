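test_that("inverse-normal transform maps ranks to normal quantiles", {
  x <- c(10, 2, 7, 30, 1)
  got <- inverse_normal_transform(x)
  expect_equal(sort(got), stats::qnorm(c(0.1, 0.3, 0.5, 0.7, 0.9)))
  expect_equal(order(got), order(x))
  # invariance under monotone distortion
  expect_equal(inverse_normal_transform(exp(x / 10)), got)
  # ties share their average rank
  tied <- inverse_normal_transform(c(1, 1, 2))
  expect_equal(tied[1], tied[2])
  expect_equal(tied[1], stats::qnorm((1.5 - 0.5) / 3))
})

test_that("expression preparation centres, filters and residualizes", {
  cfg <- small_config(n_donors = 80, n_genes = 50)
  sim <- simulate_expression(simulate_genotypes(cfg), cfg)
  prep <- prepare_expression(sim$expression$CTRL, n_expr_factors = 4)
  expect_lt(max(abs(colMeans(prep$expr))), 1e-10)
  expect_equal(prep$n_covariates, 4L)
  # covariate collinear with the intercept is rejected
  expect_error(prepare_expression(sim$expression$CTRL,
                                  covariates = rep(1, 80)),
               "collinear")
  # supplying a gene's own transformed values as a covariate annihilates it
  prep0 <- prepare_expression(sim$expression$CTRL, n_expr_factors = 0)
  cov <- prep0$expr[, 1, drop = FALSE]
  colnames(cov) <- "self"
  prep2 <- prepare_expression(sim$expression$CTRL, covariates = cov,
                              n_expr_factors = 0)
  expect_lt(max(abs(prep2$expr[, 1])), 1e-8)
})

test_that("cis pair enumeration respects the inclusive 1 Mb window", {
  genes <- data.frame(gene_id = "g1", chrom = "1", tss = 2e6)
  variants <- data.frame(variant_id = c("a", "b", "c"),
                         chrom = c("1", "1", "2"),
                         pos = c(1e6, 999999, 2e6))
  pairs <- cis_pairs(genes, variants, window = 1e6)
  expect_equal(pairs$variant_id, "a")
  expect_equal(pairs$distance, -1e6)
  genes2 <- rbind(genes, data.frame(gene_id = "g2", chrom = "1", tss = NA))
  expect_warning(cis_pairs(genes2, variants), "without TSS")
})

test_that("nominal scan recovers trivial and planted effects", {
  x <- c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1, 0, 2)
  sc <- nominal_scan(x, matrix(x, ncol = 1, dimnames = list(NULL, "v")))
  expect_equal(sc$slope, 1, tolerance = 1e-12)
  expect_equal(sc$p, 0)

  # exactly orthogonal expression: slope 0, p 1
  y <- rep(c(1, -1), 6)
  y <- qr.resid(qr(cbind(1, x)), y)
  sc2 <- nominal_scan(y, matrix(x, ncol = 1, dimnames = list(NULL, "v")))
  expect_equal(sc2$slope, 0, tolerance = 1e-12)
  expect_equal(sc2$p, 1, tolerance = 1e-10)

  # zero-variance variants are skipped
  sc3 <- nominal_scan(y, cbind(v1 = x, v2 = rep(1, 12)))
  expect_equal(sc3$variant_id, "v1")

  # planted slope is inside +-3 SE in >= 99% of 200 refits
  ok <- withr::with_seed(41, vapply(1:200, function(i) {
    dos <- stats::rbinom(400, 2, 0.3)
    yy <- 0.5 * dos + stats::rnorm(400)
    s <- nominal_scan(yy, matrix(dos, ncol = 1, dimnames = list(NULL, "v")))
    abs(s$slope - 0.5) <= 3 * s$se
  }, logical(1)))
  expect_gte(mean(ok), 0.99)
})

test_that("permutation pass approximates a uniform null for one cis variant", {
  withr::with_seed(42, {
    diffs <- vapply(1:20, function(i) {
      dos <- matrix(stats::rbinom(200, 2, 0.3), ncol = 1,
                    dimnames = list(NULL, "v"))
      y <- stats::rnorm(200)
      pp <- permutation_pass(y, dos, n_perm_min = 10000, n_perm_max = 10000,
                             seed = i)
      abs(pp$p_perm_beta - pp$top$p)
    }, numeric(1))
    expect_lt(max(diffs), 0.02)
  })
})

test_that("direct permutation p-value obeys the plus-one rule", {
  # balanced +-1 expression exactly orthogonal to a balanced binary variant:
  # the observed correlation is exactly zero while every permutation has
  # |r| >= 0, so no permuted minimum exceeds the observed p and the
  # plus-one rule returns exactly 1
  x <- rep(c(0, 2), each = 6)
  y <- rep(c(1, 1, 1, -1, -1, -1), 2)
  pp <- permutation_pass(y, matrix(x, ncol = 1, dimnames = list(NULL, "v")),
                         n_perm_min = 200, n_perm_max = 200, seed = 1)
  expect_equal(pp$p_perm_direct, 1.0)
  expect_error(permutation_pass(y, matrix(x, ncol = 1), n_perm_min = 50),
               "at least 100")
})

test_that("adaptive permutation escalates for strong signals", {
  withr::with_seed(43, {
    dos <- matrix(stats::rbinom(300, 2, 0.3), ncol = 1,
                  dimnames = list(NULL, "v"))
    y_sig <- 0.8 * dos[, 1] + stats::rnorm(300)
    pp_sig <- permutation_pass(y_sig, dos, n_perm_min = 1000,
                               n_perm_max = 5000, seed = 2)
    expect_equal(pp_sig$n_perm, 5000L)
    expect_lt(pp_sig$p_perm_beta, 0.01)
    y_null <- stats::rnorm(300)
    pp_null <- permutation_pass(y_null, dos, n_perm_min = 1000,
                                n_perm_max = 5000, seed = 2)
    expect_equal(pp_null$n_perm, 1000L)
  })
})

test_that("gene-level mapping finds planted eGenes and reports q-values", {
  cfg <- small_config(n_donors = 200, n_genes = 30, n_variants = 20,
                      n_eqtl = 4, seed = 44L)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(g, cfg)
  prep <- prepare_expression(sim$expression$CTRL, n_expr_factors = 3)
  eq <- map_cis_eqtl(g, prep, sim$expression$CTRL$genes, seed = 5)
  expect_true(all(c("gene_id", "variant_id", "slope", "se", "p_nominal",
                    "a", "b", "n_perm", "p_perm_beta", "qval") %in% names(eq)))
  expect_true(all(eq$p_perm_beta >= 0 & eq$p_perm_beta <= 1))
  expect_true(all(abs(eq$distance) <= 1e6))
  planted <- unique(sim$truth$eqtl$gene_id)
  planted <- planted[planted %in% eq$gene_id]
  expect_gte(mean(eq$qval[eq$gene_id %in% planted] < 0.05), 0.75)
  # mapping is deterministic given the seed
  eq2 <- map_cis_eqtl(g, prep, sim$expression$CTRL$genes, seed = 5)
  expect_identical(eq, eq2)
})
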