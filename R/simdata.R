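#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic genotype/phenotype
#' generator. Defaults describe a desk-scale half-sib design: 1,000
#' offspring of 80 sires in 33 contemporary groups, 3,000 SNPs on 10
#' chromosomes of 10 Mb, and 10 traits driven by a sparse architecture in
#' which a handful of major QTL confined to one 1-Mb window carry a large
#' share of the genetic variance against a polygenic background. A
#' full-scale design (1,833 individuals, 54k SNPs, 39 traits) is a
#' configuration choice, not a default.
#'
#' @param n_individuals number of genotyped offspring.
#' @param n_sires number of sires; offspring are assigned to sires nearly
#'   evenly, giving paternal half-sib families.
#' @param n_groups number of contemporary groups (e.g. gender x location x
#'   harvest-date cells), fit later as fixed effects.
#' @param n_chromosomes,chrom_length_bp genome layout; chromosome length in
#'   base pairs.
#' @param n_snps total marker count, split across chromosomes (remainder
#'   SNPs go to the first chromosomes).
#' @param ld_decay per-bp decay rate of the haplotype allele correlation
#'   between adjacent markers, `exp(-ld_decay * distance_bp)`. The
#'   default 3e-6 gives r ~ 0.9 at the default ~33 kb marker spacing and
#'   near-zero correlation beyond ~1 Mb.
#' @param maf_range two-element range from which per-SNP allele frequencies
#'   are drawn uniformly; must lie in (0, 0.5].
#' @param n_traits number of traits.
#' @param trait_names optional character vector of trait names; defaults to
#'   `trait01`, `trait02`, ...
#' @param n_qtl number of causal SNPs (drawn among simulated markers).
#' @param n_major_qtl how many of the QTL are "major" and co-located in a
#'   single randomly chosen 1-Mb window; their effects are rescaled so that
#'   window carries `qtl_variance_fraction` of the genetic variance.
#' @param qtl_sharing probability that a QTL affects all traits (through
#'   the +/-1 trait loadings of its pleiotropy factor) rather than a
#'   single trait.
#' @param n_pleio_factors number of distinct trait-loading patterns
#'   (pleiotropy factors) among which shared QTL are divided. With one
#'   factor every shared QTL acts through the same pattern and all traits
#'   collapse onto a single genetic axis; several factors give the
#'   block-structured co-association real multi-trait panels show.
#' @param h2_per_trait narrow-sense heritability target per trait, each in
#'   \[0, 1\]; recycled to `n_traits`. A trait with h2 = 0 is pure noise.
#' @param qtl_variance_fraction fraction of each trait's genetic variance
#'   attributed to the major-QTL window (default 0.3, in the range major
#'   windows explain in dense-panel cattle GWAS).
#' @param group_effect_sd standard deviation of the simulated contemporary
#'   group effects (trait units).
#' @param seed RNG seed governing the whole simulation.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 1000, n_sires = 80, n_groups = 33,
                       n_chromosomes = 10, chrom_length_bp = 10e6,
                       n_snps = 3000, ld_decay = 3e-6,
                       maf_range = c(0.1, 0.5),
                       n_traits = 10, trait_names = NULL,
                       n_qtl = 30, n_major_qtl = 3, qtl_sharing = 0.3,
                       n_pleio_factors = 3,
                       h2_per_trait = 0.5, qtl_variance_fraction = 0.3,
                       group_effect_sd = 1, seed = 1) {
  stopifnot(n_individuals >= 1, n_sires >= 1, n_groups >= 1,
            n_chromosomes >= 1, chrom_length_bp >= 1, n_snps >= 1,
            ld_decay >= 0, length(maf_range) == 2,
            n_traits >= 1, n_qtl >= 0, n_major_qtl >= 0,
            qtl_sharing >= 0, qtl_sharing <= 1, n_pleio_factors >= 1,
            qtl_variance_fraction >= 0, qtl_variance_fraction < 1,
            group_effect_sd >= 0)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must satisfy 0 < low <= high <= 0.5")
  if (n_qtl > n_snps) stop("n_qtl cannot exceed n_snps")
  if (n_major_qtl > n_qtl) stop("n_major_qtl cannot exceed n_qtl")
  h2 <- rep_len(h2_per_trait, n_traits)
  if (any(h2 < 0 | h2 > 1)) stop("heritabilities must lie in [0, 1]")
  if (is.null(trait_names)) trait_names <- sprintf("trait%02d", seq_len(n_traits))
  if (length(trait_names) != n_traits) stop("trait_names length must equal n_traits")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_sires = as.integer(n_sires),
                 n_groups = as.integer(n_groups),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 n_snps = as.integer(n_snps), ld_decay = ld_decay,
                 maf_range = maf_range, n_traits = as.integer(n_traits),
                 trait_names = trait_names, n_qtl = as.integer(n_qtl),
                 n_major_qtl = as.integer(n_major_qtl),
                 qtl_sharing = qtl_sharing,
                 n_pleio_factors = as.integer(n_pleio_factors),
                 h2_per_trait = h2,
                 qtl_variance_fraction = qtl_variance_fraction,
                 group_effect_sd = group_effect_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# sample H haplotypes for one chromosome as a first-order Markov chain:
# marginal allele frequency p[j] per marker, correlation between adjacent
# markers exp(-ld_decay * distance)
.sim_haplotypes <- function(H, p, pos, ld_decay) {
  m <- length(p)
  hap <- matrix(0L, H, m)
  hap[, 1] <- rbinom(H, 1L, p[1])
  if (m == 1) return(hap)
  for (j in 2:m) {
    r <- exp(-ld_decay * (pos[j] - pos[j - 1]))
    p0 <- p[j - 1]; p1 <- p[j]
    cv <- r * sqrt(p0 * (1 - p0) * p1 * (1 - p1))
    p11 <- p0 * p1 + cv
    # Frechet bounds keep conditionals in [0, 1]
    p11 <- min(max(p11, max(0, p0 + p1 - 1)), min(p0, p1))
    cond1 <- p11 / p0
    cond0 <- (p1 - p11) / (1 - p0)
    prev <- hap[, j - 1]
    hap[, j] <- rbinom(H, 1L, ifelse(prev == 1L, cond1, cond0))
  }
  hap
}

# recombine a sire's two chromosome haplotypes into one gamete (Haldane,
# 1 cM/Mb): switch probability between adjacent markers 0.5*(1 - exp(-2*c*d))
.sim_gamete <- function(h1, h2, pos, rate = 1e-8) {
  m <- length(h1)
  take <- integer(m)
  take[1] <- sample.int(2L, 1L) - 1L
  if (m > 1) {
    pr <- 0.5 * (1 - exp(-2 * rate * diff(pos)))
    sw <- rbinom(m - 1, 1L, pr)
    take <- cumsum(c(take[1], sw)) %% 2L
  }
  ifelse(take == 0L, h1, h2)
}

#' Simulate half-sib genotypes with marker LD
#'
#' Draws per-SNP allele frequencies, lays markers along chromosomes, samples
#' sire haplotypes from a first-order Markov process (so allele correlation
#' decays as `exp(-ld_decay * distance_bp)`), and builds each offspring
#' genotype as one recombined sire gamete plus one fresh population
#' haplotype — yielding paternal half-sib relatedness. Dosages are coded
#' 0/1/2 copies of the counted allele.
#'
#' @param config a [sim_config()].
#' @return a `genotype_data` object: list with `dosages` (individuals x
#'   SNPs integer matrix), `map` (data.frame `snp_id`, `chrom`, `pos_bp`),
#'   `allele_freq` (mean dosage / 2), `monomorphic` (logical flag per SNP)
#'   and `pedigree` (data.frame `id`, `sire`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_individuals < 1) stop("need at least one individual")
  set.seed(config$seed)

  n_chr <- config$n_chromosomes
  per_chr <- rep(config$n_snps %/% n_chr, n_chr)
  rem <- config$n_snps %% n_chr
  if (rem > 0) per_chr[seq_len(rem)] <- per_chr[seq_len(rem)] + 1L

  map <- do.call(rbind, lapply(seq_len(n_chr), function(cc) {
    pos <- sort(sample.int(config$chrom_length_bp, per_chr[cc]))
    data.frame(chrom = as.character(cc), pos_bp = pos)
  }))
  map$snp_id <- sprintf("snp%05d", seq_len(nrow(map)))
  map <- map[, c("snp_id", "chrom", "pos_bp")]

  p <- runif(nrow(map), config$maf_range[1], config$maf_range[2])

  n <- config$n_individuals
  sire_of <- sort(rep_len(seq_len(config$n_sires), n))
  dos <- matrix(0L, n, nrow(map))
  col0 <- 0L
  for (cc in seq_len(n_chr)) {
    idx <- col0 + seq_len(per_chr[cc])
    pos <- map$pos_bp[idx]
    sire_h <- .sim_haplotypes(2L * config$n_sires, p[idx], pos, config$ld_decay)
    dam_h <- .sim_haplotypes(n, p[idx], pos, config$ld_decay)
    for (i in seq_len(n)) {
      s <- sire_of[i]
      gam <- .sim_gamete(sire_h[2 * s - 1, ], sire_h[2 * s, ], pos)
      dos[i, idx] <- gam + dam_h[i, ]
    }
    col0 <- col0 + per_chr[cc]
  }
  rownames(dos) <- sprintf("ind%05d", seq_len(n))
  colnames(dos) <- map$snp_id

  freq <- colMeans(dos) / 2
  structure(list(dosages = dos, map = map, allele_freq = freq,
                 monomorphic = freq == 0 | freq == 1,
                 pedigree = data.frame(id = rownames(dos),
                                       sire = sprintf("sire%03d", sire_of))),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", nrow(x$dosages), "individuals x", ncol(x$dosages),
      "SNPs on", length(unique(x$map$chrom)), "chromosomes;",
      sum(x$monomorphic), "monomorphic\n")
  invisible(x)
}

#' Simulate multi-trait phenotypes with sparse shared QTL
#'
#' Chooses `n_qtl` causal SNPs among the simulated markers, places the
#' `n_major_qtl` largest ones inside a single 1-Mb window and rescales them
#' so that window carries `qtl_variance_fraction` of the trait's genetic
#' variance. Each QTL is either shared across all traits (probability
#' `qtl_sharing`, acting through per-trait loadings of +/-1) or private to
#' one trait. Residual noise is scaled from the realized genetic variance to
#' hit each trait's target heritability exactly, and contemporary-group
#' effects are added on top (groups are assigned uniformly at random).
#' Residual correlations between traits are zero: only the genetic
#' architecture is shared.
#'
#' @param geno a `genotype_data` from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `phenotypes` (data.frame `id`, `group`, one column per
#'   trait) and `truth` (a `truth_record`: QTL positions and effects, true
#'   per-window genetic-variance fractions, group effects, realized h2).
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(geno, "genotype_data"), inherits(config, "sim_config"))
  h2 <- config$h2_per_trait
  if (any(h2 == 1) && config$n_qtl == 0)
    stop("h2 = 1 with zero QTL is unachievable")
  set.seed(config$seed + 1L)

  n <- nrow(geno$dosages)
  n_traits <- config$n_traits
  poly <- which(!geno$monomorphic)
  if (length(poly) < config$n_qtl) stop("not enough polymorphic SNPs for n_qtl")

  win <- assign_windows(geno$map)

  # major QTL: co-located in one window with enough polymorphic members
  major_idx <- integer(0)
  if (config$n_major_qtl > 0) {
    tab <- table(win[poly])
    ok <- names(tab)[tab >= config$n_major_qtl]
    if (!length(ok)) stop("no window has enough SNPs for n_major_qtl")
    major_win <- ok[sample.int(length(ok), 1)]
    cand <- poly[win[poly] == major_win]
    major_idx <- sort(cand[sample.int(length(cand), config$n_major_qtl)])
  } else major_win <- NA_character_
  # minor QTL stay out of the major window so its variance share is
  # controlled by the major effects alone
  minor_pool <- if (is.na(major_win)) setdiff(poly, major_idx)
                else poly[win[poly] != major_win]
  minor_idx <- sort(minor_pool[sample.int(length(minor_pool),
                                          config$n_qtl - config$n_major_qtl)])
  qtl_idx <- c(major_idx, minor_idx)
  is_major <- c(rep(TRUE, length(major_idx)), rep(FALSE, length(minor_idx)))

  active <- which(h2 > 0)
  shared <- runif(config$n_qtl) < config$qtl_sharing
  # each shared QTL acts through one of a few +/-1 trait-loading patterns
  loading <- matrix(sample(c(-1, 1), config$n_pleio_factors * n_traits,
                           replace = TRUE),
                    config$n_pleio_factors, n_traits)
  factor_of <- sample.int(config$n_pleio_factors, config$n_qtl,
                          replace = TRUE)
  base <- rnorm(config$n_qtl)
  base[is_major] <- rnorm(sum(is_major), mean = 0, sd = 2) +
    sign(rnorm(sum(is_major)))  # keep major effects away from zero

  # trait x QTL effect matrix before variance scaling
  beta <- matrix(0, n_traits, config$n_qtl,
                 dimnames = list(config$trait_names, geno$map$snp_id[qtl_idx]))
  if (length(active)) {
    private_trait <- active[sample.int(length(active), config$n_qtl,
                                       replace = TRUE)]
    for (q in seq_len(config$n_qtl)) {
      if (shared[q]) beta[active, q] <- base[q] * loading[factor_of[q], active]
      else beta[private_trait[q], q] <- base[q]
    }
  }

  Xq <- geno$dosages[, qtl_idx, drop = FALSE]
  Xq <- sweep(Xq, 2, colMeans(Xq))

  # rescale major effects per trait so the major window holds its target
  # share of the per-window variance decomposition (the same decomposition
  # the window posteriors use: within-window genomic variance, summed over
  # windows)
  f <- config$qtl_variance_fraction
  qwin_all <- win[qtl_idx]
  if (length(major_idx) && f > 0) {
    minor_wins <- setdiff(unique(qwin_all[!is_major]), major_win)
    for (t in active) {
      g_major <- Xq[, is_major, drop = FALSE] %*% beta[t, is_major]
      vm <- var(as.vector(g_major))
      vp <- sum(vapply(minor_wins, function(w) {
        j <- which(qwin_all == w & !is_major)
        var(as.vector(Xq[, j, drop = FALSE] %*% beta[t, j]))
      }, numeric(1)))
      if (vm > 0 && vp > 0)
        beta[t, is_major] <- beta[t, is_major] * sqrt(f / (1 - f) * vp / vm)
    }
  }

  group <- sample.int(config$n_groups, n, replace = TRUE)
  group_eff <- matrix(rnorm(config$n_groups * n_traits,
                            sd = config$group_effect_sd),
                      config$n_groups, n_traits,
                      dimnames = list(sprintf("group%02d", seq_len(config$n_groups)),
                                      config$trait_names))

  pheno <- matrix(NA_real_, n, n_traits,
                  dimnames = list(rownames(geno$dosages), config$trait_names))
  var_g_real <- var_e_used <- setNames(numeric(n_traits), config$trait_names)
  for (t in seq_len(n_traits)) {
    g <- as.vector(Xq %*% beta[t, ])
    vg <- var(g)
    if (h2[t] > 0 && vg == 0) {
      if (h2[t] == 1) stop("h2 = 1 with no genetic variance is unachievable")
      warning("trait '", config$trait_names[t],
              "' received no QTL variance; treating as pure noise")
    }
    if (h2[t] == 0 || vg == 0) {
      g <- g * 0; vg <- 0
      ve <- 1  # unit residual variance for pure-noise traits
    } else ve <- vg * (1 - h2[t]) / h2[t]
    var_g_real[t] <- vg; var_e_used[t] <- ve
    pheno[, t] <- group_eff[group, t] + g +
      if (ve > 0) rnorm(n, sd = sqrt(ve)) else 0
  }

  # true per-window genetic-variance fractions (within-window genomic
  # variance of the QTL component, normalized to sum to one)
  windows <- sort(unique(win))
  truth_frac <- matrix(0, length(windows), n_traits,
                       dimnames = list(windows, config$trait_names))
  qwin <- win[qtl_idx]
  for (t in seq_len(n_traits)) {
    vw <- vapply(windows, function(w) {
      j <- which(qwin == w)
      if (!length(j)) return(0)
      var(as.vector(Xq[, j, drop = FALSE] %*% beta[t, j]))
    }, numeric(1))
    if (sum(vw) > 0) truth_frac[, t] <- vw / sum(vw)
  }

  phenotypes <- data.frame(id = rownames(geno$dosages),
                           group = rownames(group_eff)[group],
                           pheno, check.names = FALSE)
  truth <- structure(list(
    qtl = data.frame(snp_id = geno$map$snp_id[qtl_idx],
                     chrom = geno$map$chrom[qtl_idx],
                     pos_bp = geno$map$pos_bp[qtl_idx],
                     window = qwin, major = is_major,
                     shared = shared, factor = factor_of),
    qtl_effects = beta,
    major_window = major_win,
    true_window_fractions = truth_frac,
    group_effects = group_eff,
    var_genetic = var_g_real, var_residual = var_e_used,
    h2_realized = ifelse(var_g_real + var_e_used > 0,
                         var_g_real / (var_g_real + var_e_used), 0)),
    class = "truth_record")
  list(phenotypes = phenotypes, truth = truth)
}

#' Simulate a gene interval map (synthetic)
#'
#' Scatters non-overlapping gene intervals uniformly along the simulated
#' genome for use in window-to-gene extraction and enrichment. Purely a
#' synthetic stand-in for a genome annotation.
#'
#' @param config a [sim_config()] (genome layout is taken from it).
#' @param n_genes number of genes.
#' @param mean_length_bp mean gene length (exponential).
#' @param seed RNG seed.
#' @return data.frame `gene_id`, `chrom`, `start_bp`, `end_bp` (1-based
#'   inclusive).
#' @export
simulate_gene_map <- function(config, n_genes = 500, mean_length_bp = 30000,
                              seed = config$seed + 2L) {
  set.seed(seed)
  chrom <- sample(as.character(seq_len(config$n_chromosomes)), n_genes,
                  replace = TRUE)
  start <- ceiling(runif(n_genes, 1, config$chrom_length_bp))
  len <- pmax(200, round(stats::rexp(n_genes, 1 / mean_length_bp)))
  gm <- data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                   chrom = chrom, start_bp = start,
                   end_bp = pmin(start + len, config$chrom_length_bp))
  gm[order(gm$chrom, gm$start_bp), ]
}

#' Simulate a gene-to-term annotation table (synthetic)
#'
#' Assigns each gene a handful of functional terms from a synthetic
#' vocabulary, with term sizes spread over orders of magnitude the way GO
#' term sizes are. A synthetic stand-in for an annotation database.
#'
#' @param gene_map a gene map as from [simulate_gene_map()].
#' @param n_terms vocabulary size.
#' @param terms_per_gene mean number of terms per gene (Poisson, min 0;
#'   genes drawing zero terms are absent from the table).
#' @param seed RNG seed.
#' @return an `annotation_table`: list with `gene2term` (named list of term
#'   id vectors), `term_name` and `term_category` (named character vectors).
#' @export
simulate_annotations <- function(gene_map, n_terms = 60, terms_per_gene = 3,
                                 seed = 99) {
  set.seed(seed)
  term_ids <- sprintf("TERM:%04d", seq_len(n_terms))
  w <- stats::rexp(n_terms)^2  # heavy-tailed term popularity
  g2t <- lapply(seq_len(nrow(gene_map)), function(i) {
    k <- stats::rpois(1, terms_per_gene)
    if (k == 0) return(character(0))
    sort(sample(term_ids, min(k, n_terms), prob = w))
  })
  names(g2t) <- gene_map$gene_id
  g2t <- g2t[lengths(g2t) > 0]
  structure(list(gene2term = g2t,
                 term_name = setNames(paste("synthetic process", seq_len(n_terms)),
                                      term_ids),
                 term_category = setNames(rep("BP_synthetic", n_terms), term_ids)),
            class = "annotation_table")
}
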