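#' Genes overlapping selected 1-Mb windows
#'
#' A gene is extracted when its interval overlaps any selected window on
#' the same chromosome (any-overlap rule; window `"19_51"` spans
#' 51,000,001..52,000,000 bp in 1-based inclusive coordinates, matching
#' [assign_windows()]'s floor rule on 0-based-per-Mb indices).
#'
#' @param windows character vector of window ids (`"chrom_index"`).
#' @param gene_map data.frame `gene_id`, `chrom`, `start_bp`, `end_bp`.
#' @param size_bp window size, default 1 Mb.
#' @return sorted, deduplicated character vector of gene ids (empty with a
#'   warning when nothing overlaps).
#' @export
genes_in_windows <- function(windows, gene_map, size_bp = 1e6) {
  parts <- strsplit(windows, "_")
  hit <- rep(FALSE, nrow(gene_map))
  for (p in parts) {
    idx <- as.numeric(p[length(p)])
    chrom <- paste(p[-length(p)], collapse = "_")
    lo <- idx * size_bp + 1
    hi <- (idx + 1) * size_bp
    hit <- hit | (gene_map$chrom == chrom &
                  gene_map$start_bp <= hi & gene_map$end_bp >= lo)
  }
  genes <- sort(unique(gene_map$gene_id[hit]))
  if (!length(genes)) warning("no genes overlap the selected windows")
  genes
}

#' EASE score (penalized one-sided Fisher exact test)
#'
#' The upper-tail hypergeometric probability of the observed term overlap,
#' computed after removing one gene from the overlap: with `k` list genes
#' carrying the term, the reported p is P(X >= k - 1) for X hypergeometric
#' with `K` term genes among `N` background genes and `n` draws. The
#' penalization makes single-gene overlaps non-significant (k = 1 gives
#' p = 1) and is never smaller than the plain Fisher p.
#'
#' @param k list genes with the term.
#' @param n list size.
#' @param K background genes with the term.
#' @param N background size.
#' @return p-value in \[0, 1\]. Vectorized.
#' @export
ease_score <- function(k, n, K, N) {
  if (any(k > n | n > N | k > K | K > N | k < 0))
    stop("inconsistent contingency counts")
  # P(X >= k - 1) = 1 - P(X <= k - 2)
  p <- phyper(k - 2, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Fold enrichment
#'
#' Ratio of the term's frequency in the gene list to its frequency in the
#' background: `(k/n) / (K/N)`.
#'
#' @inheritParams ease_score
#' @return fold enrichment. Vectorized.
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (any(n == 0 | K == 0)) stop("fold enrichment undefined: n and K must be > 0")
  (k / n) / (K / N)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values in the input order.
#'
#' @param p_values numeric vector of p-values.
#' @param method adjustment method passed to [stats::p.adjust()] (default
#'   `"BH"`).
#' @return q-values aligned with the input.
#' @export
fdr_adjust <- function(p_values, method = "BH") {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  p.adjust(p_values, method = method)
}

#' Term enrichment table for a gene list
#'
#' For every term annotated to at least one list gene: the member count,
#' percentage of the list, EASE p-value, fold enrichment and BH FDR. The
#' background defaults to all genes with at least one annotation. Rows at
#' p <= 0.05 carry `significant = TRUE`.
#'
#' @param genes character vector of list gene ids.
#' @param annotations an `annotation_table`.
#' @param background optional character vector of background gene ids;
#'   defaults to all annotated genes.
#' @param p_cutoff significance cutoff on the EASE p (default 0.05).
#' @return data.frame `category`, `term_id`, `term`, `count`, `percent`,
#'   `p_value`, `fold_enrichment`, `fdr`, `significant`, sorted by
#'   `p_value`; attribute `"gene_sets"` holds each term's list-gene
#'   members (used by [cluster_terms()]).
#' @export
enrich_terms <- function(genes, annotations, background = NULL,
                         p_cutoff = 0.05) {
  stopifnot(inherits(annotations, "annotation_table"))
  if (is.null(background)) background <- names(annotations$gene2term)
  background <- unique(background)
  genes <- unique(intersect(genes, background))
  n <- length(genes); N <- length(background)
  if (n == 0) stop("no list genes present in the background")

  g2t <- annotations$gene2term
  term_of <- function(gs) unlist(g2t[intersect(gs, names(g2t))], use.names = FALSE)
  bg_tab <- table(term_of(background))
  list_terms <- lapply(genes, function(g) g2t[[g]])
  names(list_terms) <- genes
  lt <- table(unlist(list_terms, use.names = FALSE))
  if (!length(lt)) stop("no annotated genes in the list")

  terms <- names(lt)
  k <- as.integer(lt)
  K <- as.integer(bg_tab[terms])
  p <- ease_score(k, n, K, N)
  out <- data.frame(category = unname(annotations$term_category[terms]),
                    term_id = terms,
                    term = unname(annotations$term_name[terms]),
                    count = k,
                    percent = 100 * k / n,
                    p_value = p,
                    fold_enrichment = fold_enrichment(k, n, K, N),
                    fdr = fdr_adjust(p))
  out$significant <- out$p_value <= p_cutoff
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  gene_sets <- lapply(terms, function(tt)
    sort(genes[vapply(list_terms, function(x) tt %in% x, TRUE)]))
  names(gene_sets) <- terms
  attr(out, "gene_sets") <- gene_sets
  out
}

# Cohen's kappa between two binary membership vectors
.kappa <- function(a, b) {
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Cluster enriched terms by gene-membership agreement
#'
#' Terms whose list-gene memberships agree with Cohen's kappa at or above
#' the threshold are linked; clusters are the connected components of that
#' link graph (single linkage). Each cluster's enrichment score is the
#' -log10 of the geometric mean of its members' EASE p-values (computed in
#' log space); clusters scoring >= 1.3 — geometric mean p below 0.05 — are
#' flagged significant.
#'
#' @param rows an enrichment table from [enrich_terms()] (its `gene_sets`
#'   attribute supplies term memberships).
#' @param kappa_threshold linkage threshold (default 0.5).
#' @param score_cutoff significance cutoff on the enrichment score
#'   (default 1.3).
#' @return list of `annotation_cluster` objects: `terms`, `enrichment_score`,
#'   `significant`; sorted by descending score.
#' @export
cluster_terms <- function(rows, kappa_threshold = 0.5, score_cutoff = 1.3) {
  gene_sets <- attr(rows, "gene_sets")
  if (is.null(gene_sets)) stop("enrichment table lacks its gene_sets attribute")
  terms <- rows$term_id
  universe <- sort(unique(unlist(gene_sets[terms])))
  memb <- vapply(terms, function(tt) universe %in% gene_sets[[tt]],
                 logical(length(universe)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(universe))
  nt <- length(terms)
  comp <- seq_len(nt)
  if (nt > 1) {
    g <- igraph::make_empty_graph(nt, directed = FALSE)
    links <- which(upper.tri(diag(nt)), arr.ind = TRUE)
    kap <- apply(links, 1, function(ij) .kappa(memb[, ij[1]], memb[, ij[2]]))
    keep <- kap >= kappa_threshold
    if (any(keep))
      g <- igraph::add_edges(g, t(links[keep, , drop = FALSE]))
    comp <- igraph::components(g)$membership
  }
  p_of <- setNames(rows$p_value, rows$term_id)
  clusters <- lapply(split(terms, comp), function(ts) {
    score <- -mean(log10(p_of[ts]))
    structure(list(terms = sort(ts), enrichment_score = score,
                   significant = score >= score_cutoff),
              class = "annotation_cluster")
  })
  clusters <- unname(clusters)
  clusters[order(-vapply(clusters, `[[`, 0, "enrichment_score"))]
}

#' Write an enrichment table as CSV
#' @param rows data.frame from [enrich_terms()].
#' @param path output CSV.
#' @param significant_only keep rows at p <= 0.05 only (default FALSE).
#' @export
write_enrichment <- function(rows, path, significant_only = FALSE) {
  if (significant_only) rows <- rows[rows$significant, , drop = FALSE]
  write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
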