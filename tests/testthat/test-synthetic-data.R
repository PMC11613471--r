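test_that("generator is deterministic given config and seed", {
  cfg <- small_config()
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  e1 <- simulate_expression(g1, cfg)
  e2 <- simulate_expression(g2, cfg)
  expect_identical(e1, e2)
})

test_that("LD structure follows the haplotype-copy parameter", {
  # no copying: inter-variant r2 is at sampling-noise level
  cfg0 <- small_config(n_donors = 1000, n_variants = 10, ld_block_size = 5,
                       ld_decay = 0, maf_range = c(0.3, 0.3))
  g0 <- simulate_genotypes(cfg0)
  r2 <- vapply(1:9, function(j) ld_r2(g0$dosage[, j], g0$dosage[, j + 1]),
               numeric(1))
  expect_lt(mean(r2), 0.02)
  # near-total copying duplicates haplotypes within a block
  cfg1 <- small_config(n_donors = 500, n_variants = 10, ld_block_size = 5,
                       ld_decay = 0.99, maf_range = c(0.3, 0.3))
  g1 <- simulate_genotypes(cfg1)
  expect_gt(ld_r2(g1$dosage[, 1], g1$dosage[, 2]), 0.9)
  # r2 resets across block boundaries
  expect_lt(ld_r2(g1$dosage[, 5], g1$dosage[, 6]), 0.2)
})

test_that("empirical MAF matches the configured frequency", {
  cfg <- small_config(n_donors = 10000, n_variants = 10,
                      maf_range = c(0.3, 0.3), ld_decay = 0)
  st <- variant_stats(simulate_genotypes(cfg))
  expect_true(all(abs(st$maf - 0.3) < 0.02))
})

test_that("library sizes equal per-sample count totals", {
  cfg <- small_config(n_donors = 50, n_genes = 30)
  sim <- simulate_expression(simulate_genotypes(cfg), cfg)
  for (es in sim$expression) {
    expect_identical(es$lib_size, colSums(es$counts))
  }
})

test_that("planted slopes are recovered by OLS refits on the counts", {
  planted <- data.frame(gene_id = "g0001", variant_id = "var0001",
                        condition = c("CTRL", "UVC"), slope = c(0.5, 0.0))
  cfg <- small_config(n_donors = 400, n_genes = 20, n_variants = 10,
                      planted_eqtl = planted, de_fraction = 0,
                      nb_dispersion = 0.05, seed = 9L)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(g, cfg)
  dos <- g$dosage[, "var0001"]
  for (cond in c("CTRL", "UVC")) {
    truth <- planted$slope[planted$condition == cond]
    y <- log(sim$expression[[cond]]$counts["g0001", ] + 1) -
      log(sim$expression[[cond]]$lib_size)
    fit <- summary(stats::lm(y ~ dos))$coefficients
    expect_lt(abs(fit["dos", "Estimate"] - truth), 3 * fit["dos", "Std. Error"])
  }
  # noiseless limit: tiny dispersion, deep constant-depth libraries.
  # regress log counts directly (constant depth, so no offset that would
  # itself be confounded with dosage through the planted gene)
  cfg2 <- small_config(n_donors = 800, n_genes = 20, n_variants = 10,
                       planted_eqtl = planted[planted$condition == "CTRL", ],
                       de_fraction = 0, nb_dispersion = 1e-4,
                       mean_depth = 1e8, depth_sd_log = 0, seed = 10L)
  g2 <- simulate_genotypes(cfg2)
  sim2 <- simulate_expression(g2, cfg2)
  y <- log(sim2$expression$CTRL$counts["g0001", ])
  est <- unname(stats::coef(stats::lm(y ~ g2$dosage[, "var0001"]))[2])
  expect_lt(abs(est - 0.5) / 0.5, 0.01)
})

test_that("repressed fraction of true DEGs follows the configuration", {
  cfg <- small_config(n_donors = 20, n_genes = 2000, de_fraction = 0.25,
                      de_shared = 1, repressed_fraction = 0.95, n_eqtl = 0,
                      seed = 21L)
  sim <- simulate_expression(simulate_genotypes(cfg), cfg)
  de <- sim$truth$de[sim$truth$de$condition == "UVC", ]
  expect_equal(nrow(de), 500)
  n_down <- sum(de$status == "down")
  # binomial(500, 0.95): 3 sigma band around 475
  expect_true(n_down >= 460 && n_down <= 490)
  expect_true(all((de$status == "down") == (de$log2fc < 0)))
})

test_that("null GWAS summary statistics are calibrated", {
  cfg <- small_config(n_donors = 2000, n_variants = 200, ld_decay = 0,
                      maf_range = c(0.1, 0.5), seed = 5L)
  g <- simulate_genotypes(cfg)
  gw <- simulate_gwas_summary(g, "var0001", effect = 0, n = 2000, seed = 3L)
  expect_true(mean(gw$p < 0.05) > 0.02 && mean(gw$p < 0.05) < 0.09)
  lambda <- stats::median(gw$z^2) / stats::qchisq(0.5, 1)
  expect_true(lambda > 0.8 && lambda < 1.25)
})

test_that("marginal GWAS effects at LD neighbors follow the correlation", {
  cfg <- small_config(n_donors = 5000, n_variants = 10, ld_block_size = 10,
                      ld_decay = 0.98, maf_range = c(0.3, 0.3), seed = 6L)
  g <- simulate_genotypes(cfg)
  r <- stats::cor(g$dosage[, 1], g$dosage[, 2])
  expect_gt(r^2, 0.9)
  gw <- simulate_gwas_summary(g, "var0001", effect = 0.2, n = 5000, seed = 8L)
  z1 <- gw$z[gw$variant_id == "var0001"]
  z2 <- gw$z[gw$variant_id == "var0002"]
  expect_lt(abs(abs(z2) - abs(z1) * abs(r)), 2)
})

test_that("configuration errors are rejected", {
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(simulation_config(n_donors = 0), "n_donors")
  expect_error(simulation_config(ld_decay = 1), "ld_decay")
  expect_error(simulation_config(repressed_fraction = 1.2), "repressed_fraction")
  cfg <- small_config(planted_eqtl = data.frame(
    gene_id = "nope", variant_id = "var0001", condition = "CTRL", slope = 1))
  g <- simulate_genotypes(cfg)
  expect_error(simulate_expression(g, cfg), "planted gene")
  expect_error(simulate_gwas_summary(g, "missing_variant", 0.1, n = 100),
               "absent")
})
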