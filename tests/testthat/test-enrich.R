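toy_annotations <- function() {
  g2t <- list(g1 = c("T1", "T2"), g2 = c("T1"), g3 = c("T1", "T3"),
              g4 = c("T2"), g5 = c("T3"), g6 = c("T1"), g7 = c("T2", "T3"),
              g8 = c("T1"), g9 = c("T3"), g10 = c("T1", "T2"))
  terms <- c("T1", "T2", "T3")
  structure(list(gene2term = g2t,
                 term_name = setNames(paste("term", terms), terms),
                 term_category = setNames(rep("BP", 3), terms)),
            class = "annotation_table")
}

test_that("window gene extraction uses any-overlap on the right chromosome", {
  gm <- data.frame(gene_id = c("inside", "spanning", "other_chrom", "far"),
                   chrom = c("19", "19", "2", "19"),
                   start_bp = c(51100000, 50900000, 51100000, 53000000),
                   end_bp = c(51200000, 51100000, 51200000, 53100000))
  expect_equal(genes_in_windows("19_51", gm), c("inside", "spanning"))
  expect_equal(genes_in_windows(c("19_51", "19_53"), gm),
               c("far", "inside", "spanning"))
  expect_warning(none <- genes_in_windows("5_0", gm), "no genes")
  expect_equal(none, character(0))
})

test_that("EASE equals the exhaustive hypergeometric tail at k - 1", {
  expect_equal(ease_score(1, 10, 10, 100), 1)  # single-gene overlap
  expect_equal(ease_score(4, 10, 10, 100), hyper_tail(3, 10, 100, 10),
               tolerance = 1e-12)
  # degenerate full table
  expect_equal(ease_score(5, 5, 5, 5), ease_oracle(5, 5, 5, 5),
               tolerance = 1e-12)
  # vectorized over k
  expect_equal(ease_score(1:4, 10, 10, 100),
               sapply(1:4, ease_oracle, n = 10, K = 10, N = 100),
               tolerance = 1e-12)
  expect_error(ease_score(11, 10, 10, 100), "inconsistent")
})

test_that("EASE is never more significant than plain Fisher", {
  for (N in c(20, 60)) {
    for (n in c(5, 10)) {
      for (K in c(3, 8)) {
        for (k in 0:min(n, K)) {
          expect_gte(ease_score(k, n, K, N) + 1e-15,
                     fisher_upper(k, n, K, N))
        }
      }
    }
  }
})

test_that("fold enrichment is the ratio of frequencies", {
  expect_equal(fold_enrichment(6, 50, 104, 10000), 11.538462,
               tolerance = 1e-6)
  expect_equal(fold_enrichment(2, 10, 20, 100), 1)
  expect_equal(fold_enrichment(1, 10, 10, 100), 1)
  expect_error(fold_enrichment(1, 0, 10, 100), "undefined")
})

test_that("higher overlap means lower p and higher fold enrichment", {
  p <- ease_score(2:8, 10, 10, 100)
  expect_true(all(diff(p) < 0))
  fe <- fold_enrichment(2:8, 10, 10, 100)
  expect_true(all(diff(fe) > 0))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(c(0.04, 0.01)), c(0.04, 0.02))  # order preserved
  expect_error(fdr_adjust(c(0.5, 1.2)), "outside")
})

test_that("enrichment table reports count, percent, p, FE and FDR per term", {
  an <- toy_annotations()
  genes <- c("g1", "g2", "g3", "g6", "g8")  # T1-heavy list
  tab <- enrich_terms(genes, an)
  expect_equal(sort(tab$term_id), c("T1", "T2", "T3"))
  t1 <- tab[tab$term_id == "T1", ]
  expect_equal(t1$count, 5L)
  expect_equal(t1$percent, 100)
  expect_equal(t1$p_value, ease_oracle(5, 5, 6, 10), tolerance = 1e-12)
  expect_equal(t1$fold_enrichment, (5 / 5) / (6 / 10), tolerance = 1e-12)
  expect_equal(tab$fdr, fdr_adjust(tab$p_value))
  expect_true(all(tab$count >= 1))
  # the significance flag follows the p <= 0.05 reporting rule
  expect_equal(tab$significant, tab$p_value <= 0.05)
})

test_that("term clustering groups by kappa and scores by geometric-mean p", {
  an <- toy_annotations()
  tab <- enrich_terms(c("g1", "g2", "g3", "g6", "g8"), an)
  # single term alone in a cluster at p = 0.05 sits at the 1.3 boundary
  fake <- tab[1, , drop = FALSE]
  fake$p_value <- 0.05
  attr(fake, "gene_sets") <- attr(tab, "gene_sets")[fake$term_id]
  cl <- cluster_terms(fake)
  expect_equal(cl[[1]]$enrichment_score, -log10(0.05), tolerance = 1e-12)
  expect_true(cl[[1]]$significant)

  # two terms with identical gene sets (kappa 1) always co-cluster, and the
  # score is -log10 of the geometric mean of their p-values
  tab2 <- data.frame(category = "BP", term_id = c("A", "B"),
                     term = c("A", "B"), count = 3L, percent = 50,
                     p_value = c(0.01, 0.0001), fold_enrichment = 2,
                     fdr = 0.05, significant = TRUE)
  attr(tab2, "gene_sets") <- list(A = c("g1", "g2", "g3"),
                                  B = c("g1", "g2", "g3"))
  cl2 <- cluster_terms(tab2)
  expect_equal(length(cl2), 1)
  expect_equal(cl2[[1]]$terms, c("A", "B"))
  expect_equal(cl2[[1]]$enrichment_score, 3, tolerance = 1e-12)

  # disjoint gene sets do not cluster together
  tab3 <- tab2
  attr(tab3, "gene_sets") <- list(A = c("g1", "g2"), B = c("g3", "g4"))
  cl3 <- cluster_terms(tab3)
  expect_equal(length(cl3), 2)
})
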