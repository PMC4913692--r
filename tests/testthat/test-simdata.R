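test_that("genotype dimensions, map layout and SNP-per-chromosome split", {
  cfg <- sim_config(n_individuals = 200, n_snps = 500, n_chromosomes = 5,
                    n_traits = 2, n_qtl = 4, n_major_qtl = 0, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g$dosages), c(200, 500))
  expect_equal(as.vector(table(g$map$chrom)[as.character(1:5)]),
               rep(100L, 5))
  # map sorted by (chromosome, position)
  expect_true(all(unlist(tapply(g$map$pos_bp, g$map$chrom,
                                function(x) !is.unsorted(x)))))
  expect_true(all(g$dosages %in% 0:2))

  # remainder SNPs go to the first chromosomes
  cfg2 <- sim_config(n_individuals = 20, n_snps = 11, n_chromosomes = 3,
                     n_traits = 1, n_qtl = 1, n_major_qtl = 0, seed = 1)
  g2 <- simulate_genotypes(cfg2)
  expect_equal(as.vector(table(g2$map$chrom)[as.character(1:3)]),
               c(4L, 4L, 3L))
})

test_that("realized allele frequencies respect maf_range at large n", {
  # near-unrelated design (2 offspring per sire) so the realized frequency
  # spread is governed by binomial sampling error alone
  cfg <- sim_config(n_individuals = 5000, n_sires = 2500, n_snps = 100,
                    n_chromosomes = 2, maf_range = c(0.3, 0.3),
                    n_traits = 1, n_qtl = 2, n_major_qtl = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$allele_freq >= 0.27 & g$allele_freq <= 0.33))
})

test_that("LD decays with ld_decay: independence in the fast-decay limit", {
  base <- list(n_individuals = 2000, n_sires = 200, n_snps = 60,
               n_chromosomes = 1, chrom_length_bp = 3e6,
               n_traits = 1, n_qtl = 2, n_major_qtl = 0,
               maf_range = c(0.3, 0.5))
  g_indep <- simulate_genotypes(do.call(sim_config, c(base, ld_decay = 1, seed = 2)))
  g_ld <- simulate_genotypes(do.call(sim_config, c(base, ld_decay = 1e-7, seed = 2)))
  adj_cor <- function(g) {
    d <- g$dosages
    sapply(seq_len(ncol(d) - 1), function(j) cor(d[, j], d[, j + 1]))
  }
  expect_lt(max(abs(adj_cor(g_indep))), 0.1)
  expect_gt(mean(adj_cor(g_ld)), 0.5)
})

test_that("identical seed gives bit-identical genotypes and phenotypes", {
  cfg <- sim_config(n_individuals = 100, n_snps = 120, n_chromosomes = 3,
                    n_traits = 2, n_qtl = 5, n_major_qtl = 2, seed = 9)
  a <- simulate_genotypes(cfg); b <- simulate_genotypes(cfg)
  expect_identical(a$dosages, b$dosages)
  pa <- simulate_phenotypes(a, cfg); pb <- simulate_phenotypes(b, cfg)
  expect_identical(pa$phenotypes, pb$phenotypes)
  expect_identical(pa$truth$qtl_effects, pb$truth$qtl_effects)
})

test_that("half-sib families share more genotype than unrelated pairs", {
  s <- small_sim()
  d <- sweep(s$geno$dosages, 2, colMeans(s$geno$dosages))
  sire <- s$geno$pedigree$sire
  K <- tcrossprod(d) / ncol(d)  # raw genomic covariance between individuals
  same <- outer(sire, sire, "==") & upper.tri(K)
  diff <- outer(sire, sire, "!=") & upper.tri(K)
  expect_gt(mean(K[same]), mean(K[diff]))
})

test_that("h2 = 0 traits carry no QTL signal", {
  cfg <- sim_config(n_individuals = 500, n_snps = 100, n_chromosomes = 2,
                    n_traits = 2, n_qtl = 4, n_major_qtl = 0,
                    h2_per_trait = c(0.5, 0), seed = 3)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  expect_equal(unname(ph$truth$qtl_effects["trait02", ]),
               rep(0, 4))
  # regression of the null trait on any QTL dosage is ~0
  for (q in ph$truth$qtl$snp_id) {
    b <- coef(lm(ph$phenotypes$trait02 ~ g$dosages[, q]))[2]
    expect_lt(abs(b), 3 * sd(ph$phenotypes$trait02) / sqrt(500) * 2)
  }
})

test_that("single-QTL genetic variance matches 2p(1-p)a^2 at large n", {
  cfg <- sim_config(n_individuals = 5000, n_sires = 500, n_snps = 50,
                    n_chromosomes = 1, maf_range = c(0.5, 0.5),
                    n_traits = 1, n_qtl = 1, n_major_qtl = 0,
                    h2_per_trait = 0.5, seed = 21)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  a <- ph$truth$qtl_effects[1, 1]
  p <- g$allele_freq[ph$truth$qtl$snp_id]
  expect_equal(unname(ph$truth$var_genetic[1]), snp_variance(p, a)[[1]],
               tolerance = 0.1)
})

test_that("fully shared architecture gives +/-1 cross-trait effect correlation", {
  cfg <- sim_config(n_individuals = 200, n_snps = 100, n_chromosomes = 2,
                    n_traits = 2, n_qtl = 6, n_major_qtl = 2,
                    qtl_sharing = 1, n_pleio_factors = 1, seed = 4)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  r <- cor(ph$truth$qtl_effects[1, ], ph$truth$qtl_effects[2, ])
  expect_equal(abs(r), 1, tolerance = 1e-12)
})

test_that("realized heritability is close to target at n >= 2000", {
  cfg <- sim_config(n_individuals = 2000, n_sires = 150, n_snps = 400,
                    n_chromosomes = 4, n_traits = 3, n_qtl = 12,
                    n_major_qtl = 3, h2_per_trait = c(0.3, 0.5, 0.8),
                    seed = 8)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  expect_true(all(abs(ph$truth$h2_realized - c(0.3, 0.5, 0.8)) < 0.05))
})

test_that("unachievable heritability is rejected", {
  cfg <- sim_config(n_individuals = 50, n_snps = 40, n_chromosomes = 1,
                    n_traits = 1, n_qtl = 0, n_major_qtl = 0,
                    h2_per_trait = 1, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_phenotypes(g, cfg), "unachievable")
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(n_snps = 10, n_qtl = 20), "n_qtl")
})

test_that("true window fractions are a valid decomposition and hit the major-window target", {
  s <- small_sim()
  tf <- s$truth$true_window_fractions
  expect_true(all(abs(colSums(tf) - 1) < 1e-8))
  expect_true(all(tf >= 0))
  # the designated major window carries roughly its configured share
  expect_gt(tf[s$truth$major_window, "trait01"], 0.15)
})
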