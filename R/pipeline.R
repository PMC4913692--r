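#' Pipeline run configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. A single `seed`
#' governs all stochastic stages: the simulator runs at `seed` and each
#' trait's MCMC chain at `seed + trait index`, so a rerun with the same
#' configuration reproduces every output.
#'
#' @param out_dir output directory (created if absent).
#' @param sim a [sim_config()] describing the synthetic dataset.
#' @param traits traits to analyze (default: all simulated traits).
#' @param key_trait trait whose top windows select the AWM SNPs (default:
#'   the first trait).
#' @param K number of top windows for the AWM (default 20).
#' @param bayesb a [bayesb_config()] (its seed is overridden per trait).
#' @param standardize z-standardize AWM columns (default TRUE).
#' @param rank_by window ranking rule, `"ppa"` or `"var_pct"`.
#' @param strict_ties PCIT tie handling (see [pcit_filter()]).
#' @param vwp,haircut,min_size complex-detection parameters
#'   (see [find_complexes()]).
#' @param gene_map,annotations gene intervals and term annotations for the
#'   enrichment stage; when NULL, synthetic ones are generated from the
#'   simulation layout.
#' @param kappa_threshold term-clustering threshold (see [cluster_terms()]).
#' @param seed master seed.
#' @return a `run_config` object.
#' @export
run_config <- function(out_dir, sim = sim_config(), traits = NULL,
                       key_trait = NULL, K = 20,
                       bayesb = bayesb_config(), standardize = TRUE,
                       rank_by = "ppa", strict_ties = TRUE,
                       vwp = 0.2, haircut = TRUE, min_size = 3,
                       gene_map = NULL, annotations = NULL,
                       kappa_threshold = 0.5, seed = 1) {
  if (is.null(traits)) traits <- sim$trait_names
  if (is.null(key_trait)) key_trait <- traits[1]
  if (!key_trait %in% traits) stop("key_trait must be among the analyzed traits")
  structure(list(out_dir = out_dir, sim = sim, traits = traits,
                 key_trait = key_trait, K = K, bayesb = bayesb,
                 standardize = standardize, rank_by = rank_by,
                 strict_ties = strict_ties, vwp = vwp, haircut = haircut,
                 min_size = min_size, gene_map = gene_map,
                 annotations = annotations,
                 kappa_threshold = kappa_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Demo-scale run configuration
#'
#' A bundled configuration sized for a laptop run of the full pipeline:
#' 600 individuals, 1,500 SNPs on 10 chromosomes, 8 fatty-acid-style traits
#' keyed on "16:0", shortened MCMC chains. Completes in minutes on one CPU.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @return a `run_config`.
#' @export
demo_run_config <- function(out_dir, seed = 1) {
  traits <- c("16:0", "14:0", "16:1", "18:0", "18:1", "18:2", "SFA", "MUFA")
  run_config(
    out_dir,
    sim = sim_config(n_individuals = 600, n_sires = 50, n_groups = 12,
                     n_chromosomes = 10, chrom_length_bp = 10e6,
                     n_snps = 1500, n_traits = length(traits),
                     trait_names = traits, n_qtl = 20, n_major_qtl = 4,
                     qtl_sharing = 0.5, h2_per_trait = 0.5,
                     qtl_variance_fraction = 0.3, seed = seed),
    key_trait = "16:0", K = 20,
    bayesb = bayesb_config(pi = 0.98, chain_length = 1500, burn_in = 300,
                           thin = 5),
    seed = seed)
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; `sim` and `bayesb` are
#' nested blocks passed to [sim_config()] and [bayesb_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$maf_range)) y$sim$maf_range <- as.numeric(y$sim$maf_range)
    y$sim <- do.call(sim_config, y$sim)
  }
  if (!is.null(y$bayesb)) y$bayesb <- do.call(bayesb_config, y$bayesb)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' simulate -> per-trait Bayes-B GWAS -> 1-Mb window posteriors -> AWM ->
#' PCIT network -> complex detection -> term enrichment, writing every
#' stage's output files plus a manifest (seed, versions, timings, file
#' checksums) under `config$out_dir`. A stage failure aborts with the stage
#' name and leaves a `.partial` marker in the output directory.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all in-memory stage results: `geno`,
#'   `phenotypes`, `truth`, `summaries`, `window_tables`, `awm`, `pcit`,
#'   `graph`, `complexes`, `enrichment`, `clusters`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  partial <- file.path(config$out_dir, ".partial")
  file.create(partial)
  say <- function(...) if (!quiet) message(...)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    say("stage ", name, " done (", timings[[name]], "s)")
    out
  }
  fp <- function(...) file.path(config$out_dir, ...)

  sim <- config$sim
  sim$seed <- config$seed
  geno <- stage("simulate_genotypes", simulate_genotypes(sim))
  ph <- stage("simulate_phenotypes", simulate_phenotypes(geno, sim))
  stage("write_inputs", {
    write_genotypes(geno, fp("genotypes.tsv"), fp("markers.map.tsv"))
    write_phenotypes(ph$phenotypes, fp("phenotypes.csv"))
    jsonlite::write_json(list(qtl = ph$truth$qtl,
                              major_window = ph$truth$major_window,
                              h2_realized = ph$truth$h2_realized),
                         fp("truth.json"), auto_unbox = TRUE, digits = NA)
  })

  assignment <- assign_windows(geno$map)
  summaries <- list()
  window_tables <- list()
  for (i in seq_along(config$traits)) {
    tr <- config$traits[i]
    cfg <- config$bayesb
    cfg$seed <- config$seed + i
    fit <- stage(paste0("bayesb[", tr, "]"),
                 fit_bayesb(geno, ph$phenotypes, tr, cfg))
    summaries[[tr]] <- fit
    frac <- window_variance_posterior(fit, geno, assignment)
    window_tables[[tr]] <- summarize_windows(frac, assignment, trait = tr)
    write_posterior_summary(fit, fp(paste0("posterior_", make.names(tr), ".csv")))
  }
  stage("window_summary", {
    all_win <- do.call(rbind, window_tables)
    write_window_summary(all_win[order(all_win$trait, -all_win$var_pct), ],
                         fp("window_summary.csv"))
  })

  awm <- stage("awm", build_awm(summaries, window_tables[[config$key_trait]],
                                assignment, config$key_trait, K = config$K,
                                standardize = config$standardize,
                                by = config$rank_by))
  stage("write_awm", write_awm(awm, fp("awm.csv")))

  pc <- stage("pcit", {
    r <- correlate_awm(awm)
    pcit_filter(r, strict_ties = config$strict_ties)
  })
  stage("export_network", {
    export_network(pc, fp("network.sif"), "sif")
    export_network(pc, fp("network.tsv"), "tsv")
    export_network(pc, fp("network.graphml"), "graphml")
  })

  graph <- coassociation_graph(pc)
  complexes <- stage("complexes",
                     find_complexes(graph, vwp = config$vwp,
                                    haircut = config$haircut,
                                    min_size = config$min_size))
  stage("write_complexes", {
    write.table(complex_table(complexes, label = config$key_trait),
                fp("complexes.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
    members <- do.call(rbind, lapply(complexes, function(cx)
      data.frame(rank = cx$rank, snp_id = cx$node_ids)))
    if (is.null(members)) members <- data.frame(rank = integer(0),
                                                snp_id = character(0))
    write.table(members, fp("complex_members.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  gene_map <- config$gene_map
  if (is.null(gene_map)) gene_map <- simulate_gene_map(sim, seed = config$seed + 1000)
  annotations <- config$annotations
  if (is.null(annotations))
    annotations <- simulate_annotations(gene_map, seed = config$seed + 2000)
  enr <- stage("enrichment", {
    genes <- genes_in_windows(awm$windows$window_id, gene_map)
    enrich_terms(genes, annotations)
  })
  clusters <- stage("cluster_terms",
                    cluster_terms(enr, kappa_threshold = config$kappa_threshold))
  stage("write_enrichment", {
    write_enrichment(enr, fp("enrichment.csv"))
    cl <- do.call(rbind, lapply(seq_along(clusters), function(i)
      data.frame(cluster = i,
                 enrichment_score = clusters[[i]]$enrichment_score,
                 significant = clusters[[i]]$significant,
                 terms = paste(clusters[[i]]$terms, collapse = ";"))))
    if (is.null(cl)) cl <- data.frame(cluster = integer(0),
                                      enrichment_score = numeric(0),
                                      significant = logical(0),
                                      terms = character(0))
    write.table(cl, fp("annotation_clusters.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  })

  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   c(partial, fp("manifest.json")))
  manifest <- list(
    package = "coassocnet",
    version = as.character(utils::packageVersion("coassocnet")),
    seed = config$seed,
    key_trait = config$key_trait,
    traits = config$traits,
    timings_sec = as.list(timings),
    files = lapply(setNames(files, basename(files)), function(f)
      list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  file.remove(partial)

  invisible(list(geno = geno, phenotypes = ph$phenotypes, truth = ph$truth,
                 assignment = assignment, summaries = summaries,
                 window_tables = window_tables, awm = awm, pcit = pc,
                 graph = graph, complexes = complexes, enrichment = enr,
                 clusters = clusters, manifest = manifest))
}
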