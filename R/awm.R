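#' Build the association weight matrix
#'
#' Rows are all SNPs inside the `K` windows with the largest posterior
#' probability of association for the key trait; columns are the key trait
#' first, then the remaining traits in input order; entries are posterior
#' mean SNP effects. Columns can be z-standardized (the default) so the
#' downstream SNP-pair correlations are scale-free across traits of
#' different units.
#'
#' @param summaries named list of `posterior_summary` objects, one per
#'   trait; names are trait names.
#' @param window_results [summarize_windows()] output for the key trait.
#' @param assignment window ids per SNP from [assign_windows()] (named by
#'   snp id).
#' @param key_trait trait whose windows drive SNP selection.
#' @param K number of top windows (default 20).
#' @param standardize z-score each trait column (default TRUE).
#' @param by ranking rule passed to [top_windows()].
#' @return an `awm` object: list with `effects` (SNP x trait matrix),
#'   `key_trait`, `windows` (the selected window summary rows) and
#'   `standardized`.
#' @export
build_awm <- function(summaries, window_results, assignment, key_trait,
                      K = 20, standardize = TRUE, by = "ppa") {
  if (!key_trait %in% names(summaries))
    stop("key trait '", key_trait, "' missing from summaries")
  sel <- top_windows(window_results, K, by = by)
  snps <- names(assignment)[assignment %in% sel$window_id]
  if (!length(snps)) stop("selected windows contain no SNPs")

  traits <- c(key_trait, setdiff(names(summaries), key_trait))
  eff <- vapply(traits, function(tr) {
    est <- summaries[[tr]]$snp_effect_mean
    if (!all(snps %in% names(est)))
      stop("trait '", tr, "' lacks estimates for ",
           sum(!snps %in% names(est)), " selected SNP(s)")
    est[snps]
  }, numeric(length(snps)))
  eff <- matrix(eff, nrow = length(snps), dimnames = list(snps, traits))

  if (standardize) {
    mu <- colMeans(eff); s <- apply(eff, 2, sd)
    if (any(s == 0)) stop("cannot standardize a zero-variance trait column")
    eff <- sweep(sweep(eff, 2, mu), 2, s, "/")
  }
  structure(list(effects = eff, key_trait = key_trait, windows = sel,
                 standardized = standardize),
            class = "awm")
}

#' @export
print.awm <- function(x, ...) {
  cat("awm: ", nrow(x$effects), " SNPs x ", ncol(x$effects),
      " traits (key trait '", x$key_trait, "', ",
      if (x$standardized) "standardized" else "raw", ")\n", sep = "")
  invisible(x)
}

#' Write an association weight matrix as CSV
#' @param awm an `awm` object.
#' @param path output CSV (snp_id row labels, trait column headers).
#' @export
write_awm <- function(awm, path) {
  write.table(data.frame(snp_id = rownames(awm$effects), awm$effects,
                         check.names = FALSE),
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
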