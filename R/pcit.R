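#' Pairwise correlations of SNP effect profiles
#'
#' Pearson correlation between AWM rows across traits. Rows with zero
#' variance across traits (SNPs whose posterior mean effect never moved)
#' are dropped with a warning since their correlation is undefined.
#'
#' @param awm an `awm` object or a numeric SNP x trait matrix.
#' @return symmetric correlation matrix with SNP ids as dimnames.
#' @export
correlate_awm <- function(awm) {
  mat <- if (inherits(awm, "awm")) awm$effects else awm
  if (ncol(mat) < 2) stop("need at least 2 traits to correlate")
  v <- apply(mat, 1, var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance SNP row(s)")
    mat <- mat[v > 0, , drop = FALSE]
  }
  if (nrow(mat) < 3) stop("PCIT needs at least 3 SNPs")
  r <- cor(t(mat))
  diag(r) <- 1
  r
}

#' First-order partial correlation
#'
#' Correlation of x and y after removing the linear contribution of z:
#' `(rxy - rxz*ryz) / sqrt((1 - rxz^2)(1 - ryz^2))`. When a conditioning
#' correlation has magnitude 1 (within 1e-12) the pair is treated as fully
#' explainable and 0 is returned.
#'
#' @param rxy,rxz,ryz pairwise correlations. Vectorized.
#' @return partial correlation(s).
#' @export
partial_correlation <- function(rxy, rxz, ryz) {
  out <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  out[abs(rxz) >= 1 - 1e-12 | abs(ryz) >= 1 - 1e-12] <- 0
  out
}

#' PCIT network filtering
#'
#' The partial-correlation-and-information-theory algorithm scans every
#' trio of SNPs: it computes the three first-order partial correlations,
#' forms a local tolerance as the average of |partial/direct| over the
#' pairs with nonzero direct correlation, and flags the pair (x, y) as
#' non-significant if for some third SNP z both `|r_xy| <= tol*|r_xz|` and
#' `|r_xy| <= tol*|r_yz|` — i.e. the direct association is fully
#' explainable through z. Pairs never flagged by any trio keep their edge;
#' exact-zero correlations carry no edge at all. SNPs left without any
#' significant edge are isolated and excluded from the network.
#'
#' @param corr symmetric correlation matrix (e.g. from [correlate_awm()]).
#' @param strict_ties if TRUE (default) ties eliminate (`<=` in the test);
#'   FALSE switches to strict `<`.
#' @return a `pcit_result`: list with `edges` (data.frame `snp_a`, `snp_b`
#'   in canonical order, `r`, `significant`), `nodes` (ids with at least
#'   one significant edge) and `n_input`.
#' @export
pcit_filter <- function(corr, strict_ties = TRUE) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("correlation input must be a square matrix")
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix not symmetric")
  n <- nrow(corr)
  if (n < 3) stop("PCIT needs at least 3 SNPs")
  ids <- rownames(corr)
  if (is.null(ids)) ids <- paste0("v", seq_len(n))

  elim <- pcit_scan(corr, strict_ties)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  r <- corr[ut]
  keep <- r != 0
  a <- ids[ut[keep, 1]]; b <- ids[ut[keep, 2]]
  swap <- a > b  # canonical lexicographic order within each pair
  edges <- data.frame(snp_a = ifelse(swap, b, a),
                      snp_b = ifelse(swap, a, b),
                      r = r[keep], significant = !elim[ut][keep])
  nodes <- sort(unique(c(edges$snp_a[edges$significant],
                         edges$snp_b[edges$significant])))
  structure(list(edges = edges, nodes = nodes, n_input = n),
            class = "pcit_result")
}

#' @export
print.pcit_result <- function(x, ...) {
  cat("pcit_result:", sum(x$edges$significant), "significant /",
      nrow(x$edges), "candidate edges;", length(x$nodes), "of", x$n_input,
      "SNPs connected\n")
  invisible(x)
}

#' Significant co-association network as an igraph object
#'
#' @param result a `pcit_result`.
#' @return undirected `igraph` graph with edge attribute `weight` (the
#'   signed correlation); isolated SNPs are absent.
#' @export
coassociation_graph <- function(result) {
  ed <- result$edges[result$edges$significant, , drop = FALSE]
  g <- igraph::graph_from_data_frame(ed[, c("snp_a", "snp_b")],
                                     directed = FALSE)
  igraph::E(g)$weight <- ed$r
  g
}

#' Export the significant network
#'
#' Formats: `"sif"` (Cytoscape simple-interaction lines
#' `a coassoc b`), `"graphml"` (via igraph, with the signed correlation as
#' edge weight) and `"tsv"` (snp_a, snp_b, r). An empty network yields a
#' valid empty file with a warning.
#'
#' @param result a `pcit_result`.
#' @param path output file.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @export
export_network <- function(result, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  ed <- result$edges[result$edges$significant, , drop = FALSE]
  if (!nrow(ed)) warning("network is empty")
  if (format == "sif") {
    writeLines(if (nrow(ed)) paste(ed$snp_a, "coassoc", ed$snp_b) else character(0),
               path)
  } else if (format == "tsv") {
    write.table(ed[, c("snp_a", "snp_b", "r")], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    g <- coassociation_graph(result)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
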