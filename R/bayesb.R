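#' Bayes-B sampler configuration
#'
#' The mixture prior puts probability `pi` on a SNP having exactly zero
#' effect; included effects are normal with locus-specific variances drawn
#' from a scaled inverse chi-square prior. Chain defaults follow common
#' dense-panel practice: 1,000 burn-in iterations, 40,000 post-burn-in
#' iterations, pi = 0.99. The locus-variance prior scale is derived at fit
#' time from an assumed genetic-variance fraction of the phenotypic
#' variance (`h2_prior`) unless given explicitly.
#'
#' @param pi prior probability of a zero SNP effect, in \[0, 1).
#' @param chain_length post-burn-in iterations.
#' @param burn_in burn-in iterations.
#' @param nu prior degrees of freedom for the locus-effect variance.
#' @param scale prior scale for the locus-effect variance, or NULL to derive
#'   it from `h2_prior` and the data at fit time.
#' @param h2_prior assumed genetic fraction of phenotypic variance used to
#'   derive `scale` (and the residual prior scale) when `scale` is NULL.
#' @param nu_e prior degrees of freedom for the residual variance.
#' @param thin stride at which post-burn-in effect vectors are stored for
#'   window-variance posteriors.
#' @param seed RNG seed; the fit is deterministic given data and seed.
#' @return a `bayesb_config` object.
#' @export
bayesb_config <- function(pi = 0.99, chain_length = 40000, burn_in = 1000,
                          nu = 4, scale = NULL, h2_prior = 0.5, nu_e = 4,
                          thin = 10, seed = 1) {
  stopifnot(pi >= 0, pi < 1, chain_length > 0, burn_in >= 0, nu > 2,
            nu_e > 2, thin >= 1, h2_prior > 0, h2_prior < 1)
  structure(list(pi = pi, chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), nu = nu, scale = scale,
                 h2_prior = h2_prior, nu_e = nu_e, thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "bayesb_config")
}

#' Choose the mixture prior pi
#'
#' `"fixed"` returns the supplied value unchanged. `"markers-based"`
#' targets an expected count `k` of nonzero SNPs:
#' `pi = 1 - min(1, k / n_snps)` (clamped to 0 when k exceeds the panel
#' size).
#'
#' @param geno a `genotype_data`.
#' @param strategy `"fixed"` or `"markers-based"`.
#' @param pi value returned under `"fixed"`.
#' @param k target number of nonzero SNPs under `"markers-based"`.
#' @return pi in \[0, 1).
#' @export
default_pi <- function(geno, strategy = c("fixed", "markers-based"),
                       pi = 0.99, k = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") return(pi)
  if (is.null(k) || k <= 0) stop("markers-based strategy needs k > 0")
  1 - min(1, k / ncol(geno$dosages))
}

#' Fit the Bayes-B model for one trait
#'
#' Gibbs sampling over contemporary-group fixed effects (flat prior),
#' per-SNP indicator/effect pairs (indicator drawn with the effect
#' integrated out, then the effect from its normal full conditional), locus
#' variances and the residual variance. Genotype columns are centered by
#' twice the allele frequency, so a locus with frequency p and effect a
#' contributes 2p(1-p)a^2 of genetic variance under linkage equilibrium.
#' Individuals with a missing value for the trait are dropped from this fit
#' only; groups left with fewer than 2 individuals are dropped with a
#' warning.
#'
#' @param geno a `genotype_data`.
#' @param pheno phenotype data.frame (`id`, `group`, trait columns).
#' @param trait trait column name.
#' @param config a [bayesb_config()].
#' @return a `posterior_summary`: per-SNP posterior mean effects and
#'   inclusion frequencies, per-group fixed-effect means, the thinned
#'   SNP-effect samples (SNPs x stored iterations) and residual-variance
#'   samples.
#' @export
fit_bayesb <- function(geno, pheno, trait, config = bayesb_config()) {
  stopifnot(inherits(geno, "genotype_data"), inherits(config, "bayesb_config"))
  if (!trait %in% names(pheno)) stop("trait '", trait, "' not in phenotype table")
  ids <- intersect(rownames(geno$dosages), pheno$id)
  if (!length(ids)) stop("no overlap between genotype and phenotype ids")
  ph <- pheno[match(ids, pheno$id), ]
  y <- ph[[trait]]
  keep <- !is.na(y)
  if (!any(keep)) stop("trait '", trait, "' is entirely missing")
  if (any(!is.finite(y[keep]))) stop("non-finite phenotype value for '", trait, "'")
  ph <- ph[keep, ]; y <- y[keep]; ids <- ids[keep]

  cnt <- table(ph$group)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warning("dropping group(s) with fewer than 2 individuals: ",
            paste(small, collapse = ", "))
    ok <- !(ph$group %in% small)
    ph <- ph[ok, ]; y <- y[ok]; ids <- ids[ok]
  }
  if (length(y) < 3) stop("too few individuals after filtering")

  X <- geno$dosages[ids, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))  # column mean = 2p, the standard centering
  storage.mode(Xc) <- "double"

  grp <- factor(ph$group)
  vy <- var(y)
  sum2pq <- sum(2 * geno$allele_freq * (1 - geno$allele_freq))
  scale <- config$scale
  if (is.null(scale)) {
    denom <- max((1 - config$pi) * sum2pq, .Machine$double.eps)
    scale <- config$h2_prior * vy / denom * (config$nu - 2) / config$nu
  }
  scale_e <- (1 - config$h2_prior) * vy * (config$nu_e - 2) / config$nu_e

  set.seed(config$seed)
  fit <- bayesb_mcmc(Xc, y, as.integer(grp) - 1L, nlevels(grp),
                     config$pi, config$nu, scale, config$nu_e, scale_e,
                     config$burn_in, config$chain_length, config$thin)

  snp_ids <- geno$map$snp_id
  rownames(fit$samples) <- snp_ids
  structure(list(trait = trait,
                 snp_effect_mean = setNames(fit$effect_mean, snp_ids),
                 snp_inclusion_freq = setNames(fit$inclusion_freq, snp_ids),
                 fixed_effect_means = setNames(fit$group_mean, levels(grp)),
                 effect_samples = fit$samples,
                 resid_var_samples = fit$vare_samples,
                 n_individuals = length(y),
                 config = config),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("posterior_summary for trait '", x$trait, "': ",
      length(x$snp_effect_mean), " SNPs, ", x$n_individuals,
      " individuals, ", ncol(x$effect_samples), " stored samples\n", sep = "")
  invisible(x)
}

#' Write a posterior summary as CSV
#' @param summary a `posterior_summary`.
#' @param path output CSV (columns snp_id, effect_mean, inclusion_freq).
#' @export
write_posterior_summary <- function(summary, path) {
  write.table(data.frame(snp_id = names(summary$snp_effect_mean),
                         effect_mean = unname(summary$snp_effect_mean),
                         inclusion_freq = unname(summary$snp_inclusion_freq)),
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
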