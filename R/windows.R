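#' Assign SNPs to 1-Mb genomic windows
#'
#' Window index is `floor(position_bp / 1e6)` and the window id is
#' `"chrom_index"`, so chromosome 19 at 51,500,000 bp falls in window
#' `"19_51"`. The rule is half-open: 999,999 bp is window 0, 1,000,000 bp
#' is window 1.
#'
#' @param marker_map data.frame with columns `chrom` and `pos_bp` (and
#'   usually `snp_id`).
#' @param size_bp window size, default 1 Mb.
#' @return character vector of window ids, one per map row, named by
#'   `snp_id` when present.
#' @export
assign_windows <- function(marker_map, size_bp = 1e6) {
  if (any(marker_map$pos_bp < 0)) stop("negative bp position")
  w <- paste(marker_map$chrom, floor(marker_map$pos_bp / size_bp), sep = "_")
  if (!is.null(marker_map$snp_id)) names(w) <- marker_map$snp_id
  w
}

#' Additive variance of a single biallelic locus
#'
#' Under linkage equilibrium a locus with counted-allele frequency `p` and
#' allele-substitution effect `a` contributes `2 p (1 - p) a^2` of additive
#' genetic variance. Vectorized.
#'
#' @param p allele frequency in \[0, 1\].
#' @param a effect in trait units per allele copy.
#' @return variance contribution(s).
#' @export
snp_variance <- function(p, a) {
  if (any(p < 0 | p > 1)) stop("allele frequency outside [0, 1]")
  2 * p * (1 - p) * a^2
}

#' Per-iteration window shares of genetic variance
#'
#' For each stored MCMC effect vector, the genetic value contributed by a
#' window is the centered-dosage combination of its members' effects; the
#' window's variance is the sample variance of that component (so
#' within-window LD is honored), and its share is that variance divided by
#' the sum of all window variances — shares therefore sum to exactly 1
#' whenever any genetic variance is present, and are all 0 in iterations
#' where every effect is zero. `approx = TRUE` replaces the genomic
#' variance by the linkage-equilibrium sum of per-SNP `2p(1-p)a^2` terms.
#'
#' @param summary a `posterior_summary` (or an SNP x iteration sample
#'   matrix).
#' @param geno the `genotype_data` the model was fit to.
#' @param assignment window ids per SNP from [assign_windows()].
#' @param approx use the independent-locus approximation.
#' @return matrix of window shares, windows x iterations, rownames = window
#'   ids (sorted).
#' @export
window_variance_posterior <- function(summary, geno, assignment,
                                      approx = FALSE) {
  samples <- if (inherits(summary, "posterior_summary"))
    summary$effect_samples else summary
  m <- nrow(samples)
  if (m != length(assignment))
    stop("sample rows and window assignment differ in length")
  windows <- sort(unique(assignment))
  if (!length(windows)) stop("empty window set")
  wf <- factor(assignment, levels = windows)
  nT <- ncol(samples)

  wvar <- matrix(0, length(windows), nT, dimnames = list(windows, NULL))
  if (approx) {
    pq2 <- 2 * geno$allele_freq * (1 - geno$allele_freq)
    contrib <- pq2 * samples^2
    for (k in seq_along(windows)) {
      j <- which(wf == windows[k])
      wvar[k, ] <- colSums(contrib[j, , drop = FALSE])
    }
  } else {
    X <- geno$dosages
    Xc <- sweep(X, 2, colMeans(X))
    n <- nrow(Xc)
    for (k in seq_along(windows)) {
      j <- which(wf == windows[k])
      G <- Xc[, j, drop = FALSE] %*% samples[j, , drop = FALSE]
      wvar[k, ] <- colSums(G^2) / (n - 1)  # columns are mean-zero by centering
    }
  }
  tot <- colSums(wvar)
  frac <- sweep(wvar, 2, ifelse(tot > 0, tot, 1), "/")
  frac[, tot == 0] <- 0
  frac
}

#' Summarize window posteriors
#'
#' `var_pct` is 100 times the posterior mean share of genetic variance.
#' The posterior probability of association (PPA) is the fraction of stored
#' iterations in which the window's share exceeds a threshold — by default
#' the uniform expectation `1 / n_windows`, i.e. the window beats an
#' average window's share.
#'
#' @param fractions windows x iterations share matrix from
#'   [window_variance_posterior()].
#' @param assignment optional window assignment used to count member SNPs.
#' @param trait optional trait label carried into the result.
#' @param threshold share threshold for the PPA; default `1/nrow(fractions)`.
#' @return data.frame `window_id`, `n_snp`, `var_pct`, `ppa`, `trait`,
#'   sorted by descending `var_pct`.
#' @export
summarize_windows <- function(fractions, assignment = NULL, trait = NA_character_,
                              threshold = NULL) {
  if (is.null(threshold)) threshold <- 1 / nrow(fractions)
  n_snp <- if (is.null(assignment)) NA_integer_ else
    as.integer(table(factor(assignment, levels = rownames(fractions))))
  res <- data.frame(window_id = rownames(fractions),
                    n_snp = n_snp,
                    var_pct = 100 * rowMeans(fractions),
                    ppa = rowMeans(fractions > threshold),
                    trait = trait)
  res <- res[order(-res$var_pct, res$window_id), ]
  rownames(res) <- NULL
  res
}

#' Top windows by posterior probability of association
#'
#' Sorts by PPA, breaking ties by posterior variance share and then
#' lexicographically by window id (for determinism), and returns the first
#' `K`. `by = "var_pct"` ranks on variance share first instead — useful
#' when many PPAs saturate at 1.
#'
#' @param results data.frame from [summarize_windows()].
#' @param K number of windows to return.
#' @param by primary ranking column, `"ppa"` (default) or `"var_pct"`.
#' @return the selected rows of `results`.
#' @export
top_windows <- function(results, K, by = c("ppa", "var_pct")) {
  by <- match.arg(by)
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(results)) {
    warning("K exceeds number of windows; returning all")
    K <- nrow(results)
  }
  o <- if (by == "ppa")
    order(-results$ppa, -results$var_pct, results$window_id)
  else
    order(-results$var_pct, -results$ppa, results$window_id)
  out <- results[o[seq_len(K)], ]
  rownames(out) <- NULL
  out
}

#' Write a window summary as CSV
#' @param results data.frame from [summarize_windows()].
#' @param path output CSV (Trait, Map Pos, # of SNP, var %, PPA layout).
#' @export
write_window_summary <- function(results, path) {
  out <- data.frame(trait = results$trait, map_pos = results$window_id,
                    n_snp = results$n_snp,
                    var_g_pct = round(results$var_pct, 2),
                    ppa = round(results$ppa, 2))
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
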