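# Independent brute-force references used to check the fast implementations.

# PCIT reference: literal trio enumeration with the partial correlation and
# tolerance spelled out inline. Returns the symmetric elimination matrix.
pcit_reference <- function(r) {
  n <- nrow(r)
  elim <- matrix(FALSE, n, n)
  part <- function(a, b, c) {
    if (abs(r[a, c]) >= 1 - 1e-12 || abs(r[b, c]) >= 1 - 1e-12) return(0)
    (r[a, b] - r[a, c] * r[b, c]) /
      sqrt((1 - r[a, c]^2) * (1 - r[b, c]^2))
  }
  for (x in seq_len(n - 2)) {
    for (y in seq(x + 1, n - 1)) {
      for (z in seq(y + 1, n)) {
        pairs <- list(c(x, y, z), c(x, z, y), c(y, z, x))
        ratios <- numeric(0)
        for (p in pairs) {
          if (r[p[1], p[2]] != 0)
            ratios <- c(ratios, abs(part(p[1], p[2], p[3]) / r[p[1], p[2]]))
        }
        if (!length(ratios)) next
        tol <- mean(ratios)
        for (p in pairs) {
          i <- p[1]; j <- p[2]; k <- p[3]
          if (abs(r[i, j]) <= tol * abs(r[i, k]) &&
              abs(r[i, j]) <= tol * abs(r[j, k])) {
            elim[i, j] <- TRUE; elim[j, i] <- TRUE
          }
        }
      }
    }
  }
  elim
}

# significant edge set (as "i-j" strings over upper triangle) from a
# correlation matrix via the reference
pcit_reference_edges <- function(r) {
  elim <- pcit_reference(r)
  ut <- which(upper.tri(r) & r != 0 & !elim, arr.ind = TRUE)
  ids <- rownames(r)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(r)))
  a <- ids[ut[, 1]]; b <- ids[ut[, 2]]
  sort(paste(pmin(a, b), pmax(a, b), sep = "|"))
}

# a correlation matrix from correlated-data draws: a few latent factors plus
# noise, so off-diagonals span weak to strong
random_corr <- function(p, n = 40, n_factors = 3, seed = 1) {
  set.seed(seed)
  L <- matrix(rnorm(p * n_factors), p, n_factors)
  X <- L %*% matrix(rnorm(n_factors * n), n_factors, n) +
    matrix(rnorm(p * n), p, n)
  r <- cor(t(X))
  dimnames(r) <- list(paste0("v", seq_len(p)), paste0("v", seq_len(p)))
  r
}

# exhaustive hypergeometric upper-tail sum P(X >= x)
hyper_tail <- function(x, K, N, n) {
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  supp <- lo:hi
  sum(stats::dhyper(supp[supp >= x], K, N - K, n))
}

# plain one-sided Fisher exact p for the same margins: P(X >= k)
fisher_upper <- function(k, n, K, N) hyper_tail(k, K, N, n)

# EASE oracle: tail evaluated at k - 1
ease_oracle <- function(k, n, K, N) {
  if (k == 0) return(1)
  min(1, hyper_tail(k - 1, K, N, n))
}

# small genotype/phenotype fixture shared across tests (memoized per session)
.fixture_env <- new.env()
small_sim <- function() {
  if (!is.null(.fixture_env$sim)) return(.fixture_env$sim)
  cfg <- sim_config(n_individuals = 250, n_sires = 25, n_groups = 5,
                    n_chromosomes = 4, chrom_length_bp = 5e6, n_snps = 300,
                    n_traits = 3, n_qtl = 6, n_major_qtl = 2,
                    qtl_sharing = 0.5, h2_per_trait = 0.5, seed = 42)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(geno, cfg)
  .fixture_env$sim <- list(cfg = cfg, geno = geno,
                           phenotypes = ph$phenotypes, truth = ph$truth)
  .fixture_env$sim
}

small_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  s <- small_sim()
  .fixture_env$fit <- fit_bayesb(s$geno, s$phenotypes, "trait01",
                                 bayesb_config(pi = 0.95, chain_length = 500,
                                               burn_in = 100, thin = 2,
                                               seed = 11))
  .fixture_env$fit
}
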