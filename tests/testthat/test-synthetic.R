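test_that("genotypes have {0,1,2} dosages, target MAFs, and spaced blocks", {
  cfg <- sim_config(n_test = 2000, n_truth = 20000, M = 400, n_blocks = 8,
                    n_causal = 2, seed = 41)
  G <- simulate_genotypes(cfg)
  expect_true(all(G$G %in% 0:2))
  emp_maf <- colMeans(G$G) / 2
  expect_lt(max(abs(emp_maf - G$mafs)), 0.05)
  # within-block span < 200 kb; same-chromosome blocks > 1 Mb apart
  for (b in seq_len(8)) {
    cols <- G$blocks$start_col[b]:G$blocks$end_col[b]
    expect_lt(diff(range(G$pos[cols])), 2e5)
    expect_equal(length(unique(G$chrom[cols])), 1L)
  }
  bl <- G$blocks
  for (i in seq_len(nrow(bl) - 1)) for (j in (i + 1):nrow(bl)) {
    if (bl$chrom[i] == bl$chrom[j]) {
      gap <- min(abs(range(G$pos[bl$start_col[i]:bl$end_col[i]]) -
                       rev(range(G$pos[bl$start_col[j]:bl$end_col[j]]))))
      expect_gt(gap, 1e6)
    }
  }
  # same seed -> identical matrix
  expect_identical(G$G, simulate_genotypes(cfg)$G)
})

test_that("within-block LD is strong and decays; rho = 0 gives independence", {
  # rho = 0.95, MAF 0.3, n = 5000: adjacent r^2 > 0.5 in >= 95% of seeds
  cfg <- sim_config(n_test = 5000, n_truth = 50000, M = 8, n_blocks = 1,
                    rho = 0.95, maf_range = c(0.3, 0.3), n_causal = 0)
  hits <- vapply(1:60, function(s) {
    G <- simulate_genotypes(cfg, seed = s)
    cor(G$G[, 1], G$G[, 2])^2 > 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  # adjacent-lag r^2 decreasing with lag on average (AR structure)
  G <- simulate_genotypes(cfg, seed = 7)
  r2 <- cor(G$G)^2
  lagmean <- vapply(1:5, function(l) mean(r2[cbind(1:(8 - l), (1 + l):8)]), 1)
  expect_true(all(diff(lagmean) < 0))
  # rho = 0: off-diagonal r^2 near zero
  cfg0 <- sim_config(n_test = 5000, n_truth = 50000, M = 10, n_blocks = 1,
                     rho = 0, n_causal = 0, seed = 5)
  G0 <- simulate_genotypes(cfg0)
  r20 <- cor(G0$G)^2
  expect_lt(max(r20[upper.tri(r20)]), 0.01)
})

test_that("assign_effects calibrates explained variance and handles edge laws", {
  cfg <- sim_config(n_test = 3000, n_truth = 30000, M = 500, n_blocks = 10,
                    n_causal = 5, hsq = 0.12, seed = 43)
  G <- simulate_genotypes(cfg)
  tm <- assign_effects(G, cfg)
  expect_length(tm$causal_ids, 5)
  eaf <- colMeans(G$G[, ld_index(G, tm$causal_ids), drop = FALSE]) / 2
  expect_equal(sum(2 * eaf * (1 - eaf) * tm$theta^2), 0.12, tolerance = 1e-10)
  # one causal per block
  blk <- findInterval(ld_index(G, tm$causal_ids), G$blocks$start_col)
  expect_equal(anyDuplicated(blk), 0L)
  # null model
  cfg0 <- sim_config(n_test = 1000, n_truth = 10000, M = 100, n_blocks = 2,
                     n_causal = 0)
  expect_equal(assign_effects(simulate_genotypes(cfg0), cfg0)$hsq, 0)
  # explicit effect list at MAF 0.5: explained variance = sum(0.5 theta^2)
  cfge <- sim_config(n_test = 4000, n_truth = 40000, M = 200, n_blocks = 4,
                     n_causal = 3, maf_range = c(0.5, 0.5),
                     effect_law = c(0.1, -0.2, 0.15), seed = 44)
  Ge <- simulate_genotypes(cfge)
  tme <- assign_effects(Ge, cfge)
  eafe <- colMeans(Ge$G[, ld_index(Ge, tme$causal_ids), drop = FALSE]) / 2
  expect_equal(tme$hsq, sum(2 * eafe * (1 - eafe) * c(0.1, -0.2, 0.15)^2),
               tolerance = 1e-12)
  expect_equal(tme$hsq, sum(0.5 * c(0.1, 0.2, 0.15)^2), tolerance = 0.01)
})

test_that("phenotypes have unit variance, are deterministic, and recover effects", {
  cfg <- sim_config(n_test = 20000, n_truth = 200000, M = 100, n_blocks = 2,
                    n_causal = 2, hsq = 0.1, seed = 45)
  G <- simulate_genotypes(cfg)
  tm <- assign_effects(G, cfg)
  y <- simulate_phenotype(G, tm, seed = 9)
  expect_lt(abs(var(y) - 1), 0.03)
  expect_identical(y, simulate_phenotype(G, tm, seed = 9))
  # hsq = 0 -> pure N(0,1) noise
  cfg0 <- sim_config(n_test = 20000, n_truth = 200000, M = 100, n_blocks = 2,
                     n_causal = 0, seed = 46)
  y0 <- simulate_phenotype(simulate_genotypes(cfg0), assign_effects(simulate_genotypes(cfg0), cfg0), seed = 10)
  expect_lt(abs(var(y0) - 1), 0.03)
  expect_lt(abs(mean(y0)), 0.03)

  # parameter recovery: theta-hat within 3 SE of theta in ~99.7% of draws
  cfg2 <- sim_config(n_test = 2000, n_truth = 20000, M = 60, n_blocks = 2,
                     n_causal = 2, hsq = 0.05, seed = 47)
  G2 <- simulate_genotypes(cfg2)
  tm2 <- assign_effects(G2, cfg2)
  j <- ld_index(G2, tm2$causal_ids[1])
  cover <- vapply(1:100, function(s) {
    y <- simulate_phenotype(G2, tm2, seed = 1000 + s)
    fit <- summary(lm(y ~ G2$G[, j]))$coefficients[2, ]
    abs(fit["Estimate"] - tm2$theta[1]) < 3 * fit["Std. Error"]
  }, TRUE)
  expect_gte(mean(cover), 0.95)
})

test_that("association_scan equals lm per variant and is calibrated under the null", {
  cfg <- sim_config(n_test = 800, n_truth = 8000, M = 50, n_blocks = 1,
                    n_causal = 1, hsq = 0.05, seed = 48)
  G <- simulate_genotypes(cfg)
  tm <- assign_effects(G, cfg)
  y <- simulate_phenotype(G, tm, seed = 3)
  ss <- association_scan(G, y)
  expect_s3_class(ss, "sumstats")
  expect_equal(ss$Z, ss$BETA / ss$SE, tolerance = 1e-10)
  for (id in c(ss$SNP[1], tm$causal_ids[1], ss$SNP[50])) {
    fit <- summary(lm(y ~ G$G[, ld_index(G, id)]))$coefficients[2, ]
    i <- match(id, ss$SNP)
    expect_equal(ss$BETA[i], unname(fit["Estimate"]), tolerance = 1e-10)
    expect_equal(ss$SE[i], unname(fit["Std. Error"]), tolerance = 1e-10)
    expect_equal(ss$P[i], unname(fit["Pr(>|t|)"]), tolerance = 1e-10)
  }
  # perfect signal: y proportional to a dosage -> essentially zero P there
  yp <- 0.1 * G$G[, 10]
  ssp <- association_scan(G, yp)
  expect_lt(ssp$P[match(G$ids[10], ssp$SNP)], 1e-100)

  # null calibration on a larger scan (independent variants: the genomic
  # inflation factor's sampling noise grows with block correlation)
  cfgn <- sim_config(n_test = 2000, n_truth = 20000, M = 10000, n_blocks = 100,
                     n_causal = 0, rho = 0, seed = 49)
  Gn <- simulate_genotypes(cfgn)
  yn <- simulate_phenotype(Gn, assign_effects(Gn, cfgn), seed = 4)
  ssn <- association_scan(Gn, yn)
  frac <- mean(ssn$P < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 10000) + 0.01)
  lam <- lambda_gc(ssn)
  expect_gt(lam, 0.95); expect_lt(lam, 1.05)
})

test_that("null scans pass KS uniformity in nearly all seeds", {
  cfg <- sim_config(n_test = 600, n_truth = 6000, M = 300, n_blocks = 6,
                    n_causal = 0, rho = 0)
  pass <- vapply(1:40, function(s) {
    G <- simulate_genotypes(cfg, seed = 500 + s)
    y <- stats::rnorm(600)
    suppressWarnings(stats::ks.test(association_scan(G, y)$P, "punif")$p.value) > 0.01
  }, TRUE)
  expect_gte(mean(pass), 0.95)
})

test_that("multi-trait phenotypes carry the residual correlation into Z scores", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  # independent variants: LD inflates the Monte Carlo noise of the
  # cross-variant correlation estimate without changing its target
  cfg <- sim_config(n_test = 1500, n_truth = 15000, M = 4000, n_blocks = 80,
                    n_causal = 0, L = 2, sigma = S, rho = 0, seed = 50)
  G <- simulate_genotypes(cfg)
  tm <- assign_effects(G, cfg)
  Y <- simulate_phenotypes_multi(G, tm, seed = 6)
  expect_equal(dim(Y), c(1500, 2))
  expect_lt(abs(cor(Y[, 1], Y[, 2]) - 0.5), 0.06)
  z1 <- association_scan(G, Y[, 1])$Z
  z2 <- association_scan(G, Y[, 2])$Z
  # all variants are null here, so estimate on the full set (the default
  # |Z| < 2 mask truncates the tails and attenuates the estimate slightly)
  om <- estimate_trait_correlation(cbind(z1, z2),
                                   null_mask = rep(TRUE, length(z1)))
  expect_lt(abs(om$omega[1, 2] - 0.5), 0.05)
  # independent traits: near-zero cross-trait Z correlation at null variants
  cfg0 <- sim_config(n_test = 1500, n_truth = 15000, M = 2000, n_blocks = 40,
                     n_causal = 0, L = 2, seed = 51)
  G0 <- simulate_genotypes(cfg0)
  Y0 <- simulate_phenotypes_multi(G0, assign_effects(G0, cfg0), seed = 7)
  z0 <- cbind(association_scan(G0, Y0[, 1])$Z, association_scan(G0, Y0[, 2])$Z)
  expect_lt(abs(cor(z0)[1, 2]), 3 / sqrt(2000) + 0.02)
  # L = 1 multi-trait reduces to the single-trait generator
  cfg1 <- sim_config(n_test = 500, n_truth = 5000, M = 100, n_blocks = 2,
                     n_causal = 1, seed = 52)
  G1 <- simulate_genotypes(cfg1)
  tm1 <- assign_effects(G1, cfg1)
  expect_equal(drop(simulate_phenotypes_multi(G1, tm1, seed = 8)),
               simulate_phenotype(G1, tm1, seed = 8), tolerance = 1e-12)
})

test_that("paired studies are reproducible and the truth study dominates the test", {
  cfg <- sim_config(n_test = 1500, n_truth = 15000, M = 600, n_blocks = 12,
                    n_causal = 4, hsq = 0.3, seed = 53)
  ps1 <- make_paired_studies(cfg)
  ps2 <- make_paired_studies(cfg)
  expect_equal(as.data.frame(ps1$test), as.data.frame(ps2$test))
  expect_equal(as.data.frame(ps1$truth_stats), as.data.frame(ps2$truth_stats))
  # power ordering across seeds: truth-significant set contains the
  # test-significant set at 5e-8 in >= 90% of seeds
  dominated <- vapply(1:10, function(s) {
    ps <- make_paired_studies(sim_config(n_test = 1500, n_truth = 15000,
                                         M = 600, n_blocks = 12, n_causal = 4,
                                         hsq = 0.3, seed = 600 + s))
    sig_test <- ps$test$SNP[ps$test$P < 5e-8]
    sig_truth <- ps$truth_stats$SNP[ps$truth_stats$P < 5e-8]
    all(sig_test %in% sig_truth)
  }, TRUE)
  expect_gte(mean(dominated), 0.9)
  # analytic truth study: causal Z near sqrt(n * explained variance),
  # genomic inflation close to 1 on a null architecture
  ps <- ps1
  i <- match(ps$truth_model$causal_ids, ps$truth_stats$SNP)
  eaf <- ps$truth_stats$EAF[i]
  expected_z <- sqrt(cfg$n_truth * 2 * eaf * (1 - eaf)) * ps$truth_model$theta
  expect_gt(cor(abs(ps$truth_stats$Z[i]), abs(expected_z)), 0.95)
  cfg0 <- sim_config(n_test = 1500, n_truth = 15000, M = 600, n_blocks = 12,
                     n_causal = 0, rho = 0, seed = 54)
  ps0 <- make_paired_studies(cfg0)
  lam <- lambda_gc(ps0$truth_stats)
  expect_gt(lam, 0.9); expect_lt(lam, 1.1)
})
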