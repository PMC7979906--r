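test_that("population allele frequencies are hand-countable", {
  calls <- rbind(a = c(0L, 2L), b = c(1L, NA), c = c(2L, 0L), d = c(1L, 0L))
  gm <- make_gm(calls, samples = letters[1:4])
  pm <- population_map(letters[1:4], c("X", "X", "X", "Y"))
  pf <- pop_allele_freqs(gm, pm)
  expect_equal(unname(pf$freq["X", ]), c(3 / 6, 2 / 4))
  expect_equal(unname(pf$freq["Y", ]), c(0.5, 0))
  expect_equal(unname(pf$n_ind["X", ]), c(3, 2))
  # all-missing site in a population is flagged by NaN / zero calls
  calls2 <- rbind(a = c(0L, NA), b = c(1L, NA), c = c(2L, 0L), d = c(1L, 0L))
  gm2 <- make_gm(calls2, samples = letters[1:4])
  pm2 <- population_map(letters[1:4], c("X", "X", "Y", "Y"))
  pf2 <- pop_allele_freqs(gm2, pm2)
  expect_true(is.nan(pf2$freq["X", 2]))
  expect_equal(unname(pf2$n_ind["X", ]), c(2, 0))
  expect_error(pop_allele_freqs(gm2, pm2[1:3]), "lacks sample")
})

test_that("Fis is strongly negative for heterozygote excess and ~0 under HWE", {
  # population entirely heterozygous at every site: Ho = 1 > He
  het <- make_gm(matrix(1L, nrow = 6, ncol = 40))
  pm <- population_map(het$samples, rep("P", 6))
  expect_lt(heterozygosity_fis(het, pm)$fis, -0.5)

  cfg <- sim_config(c(P = 200), 0.1, 4000, seed = 91, missing_rate = 0)
  s <- simulate_genotypes(cfg)
  pmp <- population_map(s$truth$samples$sample_id, s$truth$samples$population)
  expect_lt(abs(heterozygosity_fis(s$gm, pmp)$fis), 0.02)

  mono <- make_gm(matrix(0L, nrow = 3, ncol = 5))
  expect_true(is.na(heterozygosity_fis(mono, population_map(mono$samples, rep("P", 3)))$fis))
})

test_that("null Fst is near zero and fixed differences give Fst = 1", {
  cfg <- sim_config(c(P = 100), 0.1, 4000, seed = 95, missing_rate = 0)
  s <- simulate_genotypes(cfg)
  pm <- population_map(s$truth$samples$sample_id,
                       rep(c("X", "Y"), length.out = 100))
  expect_lt(abs(pairwise_fst(s$gm, pm)$fst["X", "Y"]), 0.01)

  fixed <- make_gm(rbind(matrix(0L, 4, 30), matrix(2L, 4, 30)))
  pmf <- population_map(fixed$samples, rep(c("X", "Y"), each = 4))
  expect_equal(unname(pairwise_fst(fixed, pmf)$fst["X", "Y"]), 1)
})

test_that("Fst recovers Balding-Nichols divergence within the Monte-Carlo oracle", {
  cfg <- sim_config(c(P1 = 50, P2 = 50, P3 = 50), c(0.05, 0.1, 0.2), 5000,
                    seed = 11, missing_rate = 0)
  s <- simulate_genotypes(cfg)
  pm <- population_map(s$truth$samples$sample_id, s$truth$samples$population)
  fst <- pairwise_fst(s$gm, pm)$fst
  Fv <- c(P1 = 0.05, P2 = 0.1, P3 = 0.2)
  for (pair in list(c("P1", "P2"), c("P1", "P3"), c("P2", "P3"))) {
    expect_equal(fst[pair[1], pair[2]],
                 fst_bn_oracle(Fv[pair[1]], Fv[pair[2]]),
                 tolerance = 0.02, ignore_attr = TRUE)
  }
})

test_that("Fst is symmetric, sample-order invariant, and ranks follow divergence", {
  cfg <- sim_config(c(P1 = 40, P2 = 40, P3 = 40, P4 = 40),
                    c(0.05, 0.10, 0.15, 0.25), 4000, seed = 14, missing_rate = 0.05)
  s <- simulate_genotypes(cfg)
  pm <- population_map(s$truth$samples$sample_id, s$truth$samples$population)
  fst <- pairwise_fst(s$gm, pm)$fst
  expect_true(isSymmetric(fst))
  perm <- sample(s$gm$samples)
  fst_perm <- pairwise_fst(subset_gm(s$gm, samples = perm), pm)$fst
  expect_equal(fst_perm[rownames(fst), colnames(fst)], fst, tolerance = 1e-12)

  Fv <- c(P1 = 0.05, P2 = 0.10, P3 = 0.15, P4 = 0.25)
  pairs <- t(combn(names(Fv), 2))
  observed <- fst[pairs]
  expected <- mapply(function(a, b) fst_bn_oracle(Fv[a], Fv[b]), pairs[, 1], pairs[, 2])
  expect_equal(cor(observed, expected, method = "spearman"), 1)
})

test_that("f3 equals the brute-force sum on a tiny frequency table", {
  freq <- rbind(A = c(0.5, 0.1, 0.9, 0.3, 0.6, 0.2),
                B = c(0.4, 0.3, 0.8, 0.1, 0.7, 0.25),
                C = c(0.7, 0.2, 0.95, 0.5, 0.5, 0.15))
  res <- f3(freq, "A", "B", "C", block_size = 6)
  expect_equal(res$estimate, naive_f3(freq, "A", "B", "C"))
  expect_true(is.na(res$se))  # single block: no jackknife SE
  expect_equal(res$n_blocks, 1)
})

test_that("f3 detects admixture with a negative Z and is positive for a drifted target", {
  ad <- lapply(1:30, function(i) list(id = sprintf("MIX_%02d", i),
                                      q = c(B = 0.5, C = 0.5)))
  cfg <- sim_config(c(B = 30, C = 30, O = 30), c(0.2, 0.2, 0.1), 5000,
                    admixed = ad, missing_rate = 0, seed = 13)
  s <- simulate_genotypes(cfg)
  pm <- population_map(s$truth$samples$sample_id, s$truth$samples$population)
  adm <- f3(s$gm, "admixed", "B", "C", pm = pm)
  expect_lt(adm$estimate, 0)
  expect_lt(adm$z, -3)
  ctrl <- f3(s$gm, "O", "B", "C", pm = pm)
  expect_gt(ctrl$estimate, 0)
  expect_error(f3(s$gm, "O", "B", "B", pm = pm), "distinct")
})

test_that("f3(A; B, B) computed on frequencies is non-negative", {
  cfg <- sim_config(c(A = 25, B = 25), c(0.1, 0.15), 4000, seed = 44, missing_rate = 0)
  s <- simulate_genotypes(cfg)
  pm <- population_map(s$truth$samples$sample_id, s$truth$samples$population)
  freq <- pop_allele_freqs(s$gm, pm)$freq
  freq2 <- rbind(freq, B2 = freq["B", ])
  res <- f3(freq2, "A", "B", "B2", block_size = 500)
  expect_gte(res$estimate, 0)
})

test_that("f4 identities hold exactly and gene flow moves Z monotonically", {
  cfg <- sim_config(c(A = 20, B = 20, C = 20, D = 20), 0.15, 4000,
                    seed = 47, missing_rate = 0)
  s <- simulate_genotypes(cfg)
  pm <- population_map(s$truth$samples$sample_id, s$truth$samples$population)
  expect_equal(f4(s$gm, "A", "B", "C", "C", pm = pm)$estimate, 0)
  ab_cd <- f4(s$gm, "A", "B", "C", "D", pm = pm)
  ab_dc <- f4(s$gm, "A", "B", "D", "C", pm = pm)
  expect_equal(ab_cd$estimate, -ab_dc$estimate)
  expect_equal(ab_cd$se, ab_dc$se)

  # additivity on a shared frequency table: f4(A,B;C,D) = f4(A,B;C,E) + f4(A,B;E,D)
  set.seed(3)
  freq <- matrix(runif(5 * 200), nrow = 5,
                 dimnames = list(c("A", "B", "C", "D", "E"), NULL))
  expect_equal(f4(freq, "A", "B", "C", "D", block_size = 50)$estimate,
               f4(freq, "A", "B", "C", "E", block_size = 50)$estimate +
                 f4(freq, "A", "B", "E", "D", block_size = 50)$estimate)

  # unadmixed independent drift: |Z| small; B->C gene flow raises |Z| with dose
  zs <- vapply(c(0, 0.2, 0.4), function(alpha) {
    ad <- if (alpha == 0) list() else
      lapply(1:20, function(i) list(id = sprintf("CM_%02d", i),
                                    q = c(C = 1 - alpha, B = alpha)))
    cfgm <- sim_config(c(A = 20, B = 20, C = 20, D = 20), 0.15, 4000,
                       seed = 53, admixed = ad, missing_rate = 0)
    sm <- simulate_genotypes(cfgm)
    pmm <- population_map(sm$truth$samples$sample_id, sm$truth$samples$population)
    cpop <- if (alpha == 0) "C" else "admixed"
    abs(f4(sm$gm, "A", "B", cpop, "D", pm = pmm)$z)
  }, 0)
  expect_lt(zs[1], 3)
  expect_true(all(diff(zs) > 0))
  expect_gt(zs[3], 3)
})

test_that("weighted block jackknife reduces to the delete-one jackknife at block size 1", {
  set.seed(77)
  values <- rnorm(150)
  jk <- block_jackknife(values, block_size = 1)
  expect_equal(jk$estimate, mean(values))
  expect_equal(jk$se, naive_jackknife_se(values))
  expect_equal(jk$n_blocks, 150)
  # trailing partial block is kept
  jk2 <- block_jackknife(values, block_size = 40)
  expect_equal(jk2$n_blocks, 4)
  expect_equal(jk2$estimate, mean(values))
  expect_error(block_jackknife(numeric(0)), "no values")
})
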