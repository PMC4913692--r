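# small synthetic regression problem built directly (not via simdata) so the
# sampler is tested against a known architecture
make_gwas_problem <- function(n = 500, m = 200, qtl = 25, h2 = 0.5,
                              groups = 4, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.5)
  X <- sapply(p, function(pp) rbinom(n, 2, pp))
  colnames(X) <- sprintf("s%03d", seq_len(m))
  rownames(X) <- sprintf("i%03d", seq_len(n))
  map <- data.frame(snp_id = colnames(X), chrom = "1",
                    pos_bp = seq(1e4, by = 1e4, length.out = m))
  geno <- structure(list(dosages = X, map = map,
                         allele_freq = colMeans(X) / 2,
                         monomorphic = colMeans(X) %in% c(0, 2),
                         pedigree = NULL), class = "genotype_data")
  grp <- paste0("g", sample.int(groups, n, replace = TRUE))
  g <- if (h2 > 0) {
    a <- 1
    gv <- (X[, qtl] - mean(X[, qtl])) * a
    gv * sqrt(1 / var(gv))  # unit genetic variance
  } else 0
  ve <- if (h2 > 0) (1 - h2) / h2 else 1
  y <- g + rnorm(n, sd = sqrt(ve)) + c(0, 1, -1, 2)[as.integer(factor(grp))]
  pheno <- data.frame(id = rownames(X), group = grp, y = y)
  list(geno = geno, pheno = pheno, qtl = colnames(X)[qtl])
}

test_that("default chain configuration uses the standard burn-in and length", {
  cfg <- bayesb_config()
  expect_equal(cfg$burn_in, 1000L)
  expect_equal(cfg$chain_length, 40000L)
  expect_equal(cfg$pi, 0.99)
})

test_that("default_pi strategies", {
  s <- small_sim()
  expect_equal(default_pi(s$geno, "fixed", pi = 0.95), 0.95)
  fake <- list(dosages = matrix(0, 1, 3000))
  expect_equal(default_pi(fake, "markers-based", k = 300), 0.9)
  expect_equal(default_pi(fake, "markers-based", k = 5000), 0)
  expect_error(default_pi(fake, "markers-based", k = 0), "k > 0")
})

test_that("sampler is deterministic given the seed", {
  pr <- make_gwas_problem(n = 120, m = 60, seed = 2)
  cfg <- bayesb_config(pi = 0.9, chain_length = 200, burn_in = 50, seed = 7)
  f1 <- fit_bayesb(pr$geno, pr$pheno, "y", cfg)
  f2 <- fit_bayesb(pr$geno, pr$pheno, "y", cfg)
  expect_identical(f1$snp_effect_mean, f2$snp_effect_mean)
  expect_identical(f1$effect_samples, f2$effect_samples)
  f3 <- fit_bayesb(pr$geno, pr$pheno, "y", bayesb_config(pi = 0.9,
                   chain_length = 200, burn_in = 50, seed = 8))
  expect_false(identical(f1$snp_effect_mean, f3$snp_effect_mean))
})

test_that("null phenotypes yield shrunken effects and prior-level inclusion", {
  for (seed in 1:3) {
    pr <- make_gwas_problem(n = 500, m = 200, h2 = 0, seed = seed)
    fit <- fit_bayesb(pr$geno, pr$pheno, "y",
                      bayesb_config(pi = 0.9, chain_length = 600,
                                    burn_in = 150, seed = seed))
    expect_lt(max(abs(fit$snp_effect_mean)), 0.1 * sd(pr$pheno$y))
    # inclusion hovers at the prior level 1 - pi; the band reflects the
    # seed-to-seed spread of marginal inclusion on finite null data
    expect_lt(abs(mean(fit$snp_inclusion_freq) - 0.1), 0.1)
  }
})

test_that("a large single QTL is recovered with high inclusion", {
  for (seed in 1:3) {
    pr <- make_gwas_problem(n = 1000, m = 200, qtl = 50, h2 = 0.5,
                            seed = seed)
    fit <- fit_bayesb(pr$geno, pr$pheno, "y",
                      bayesb_config(pi = 0.99, chain_length = 800,
                                    burn_in = 200, seed = seed))
    top <- names(which.max(abs(fit$snp_effect_mean)))
    expect_equal(top, pr$qtl)
    expect_gt(fit$snp_inclusion_freq[pr$qtl], 0.8)
  }
})

test_that("stronger mixture prior shrinks mean absolute effects monotonically", {
  pr <- make_gwas_problem(n = 400, m = 150, qtl = 10, h2 = 0.4, seed = 3)
  mean_abs <- sapply(c(0.5, 0.9, 0.99), function(pi) {
    reps <- sapply(1:3, function(s)
      mean(abs(fit_bayesb(pr$geno, pr$pheno, "y",
                          bayesb_config(pi = pi, chain_length = 400,
                                        burn_in = 100,
                                        seed = s))$snp_effect_mean)))
    mean(reps)
  })
  # Monte-Carlo slack: each step down must hold up to a small tolerance
  expect_lt(mean_abs[2], mean_abs[1] * 1.05)
  expect_lt(mean_abs[3], mean_abs[2] * 1.05)
})

test_that("residual variance samples are positive at every stored iteration", {
  fit <- small_fit()
  expect_true(all(fit$resid_var_samples > 0))
})

test_that("missing phenotypes drop individuals; tiny groups are dropped with a warning", {
  pr <- make_gwas_problem(n = 100, m = 40, seed = 4)
  pr$pheno$y[1:10] <- NA
  fit <- fit_bayesb(pr$geno, pr$pheno, "y",
                    bayesb_config(pi = 0.9, chain_length = 100, burn_in = 20))
  expect_equal(fit$n_individuals, 90)

  pr$pheno$group[11] <- "lonely"
  expect_warning(
    fit2 <- fit_bayesb(pr$geno, pr$pheno, "y",
                       bayesb_config(pi = 0.9, chain_length = 100,
                                     burn_in = 20)),
    "lonely")
  expect_equal(fit2$n_individuals, 89)
  expect_false("lonely" %in% names(fit2$fixed_effect_means))

  pr$pheno$y <- NA_real_
  expect_error(fit_bayesb(pr$geno, pr$pheno, "y"), "entirely missing")
  expect_error(fit_bayesb(pr$geno, pr$pheno, "nope"), "not in phenotype")
})
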