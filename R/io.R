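#' Read a genotype file
#'
#' Two dialects are supported. `"dosage"`: a tab-delimited matrix with a
#' header of SNP ids and one row per individual (first column = individual
#' id), entries in \{0, 1, 2\}, accompanied by a map file. `"ped-map"`:
#' PLINK-style .ped/.map text files where each .ped row is
#' `fid iid pat mat sex phe` followed by two allele columns (coded 1/2) per
#' SNP; dosage counts allele "2". Monomorphic SNPs are flagged, never
#' dropped. Allele frequency is computed as mean dosage / 2.
#'
#' @param path genotype file (.tsv dosage matrix, or .ped).
#' @param map_path marker map: tab-delimited with columns
#'   `snp_id`, `chrom`, `pos_bp` (dosage dialect) or the 4-column PLINK .map
#'   layout `chrom snp_id cm pos_bp`.
#' @param dialect `"dosage"` or `"ped-map"`.
#' @return a `genotype_data` object (see [simulate_genotypes()]).
#' @export
read_genotypes <- function(path, map_path, dialect = c("dosage", "ped-map")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)

  if (dialect == "dosage") {
    map <- read.table(map_path, header = TRUE, sep = "\t",
                      colClasses = c("character", "character", "numeric"))
    names(map) <- c("snp_id", "chrom", "pos_bp")
    d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    row.names = 1)
    dos <- as.matrix(d)
  } else {
    map <- read.table(map_path, header = FALSE, sep = "\t",
                      colClasses = c("character", "character", "numeric",
                                     "numeric"))
    map <- data.frame(snp_id = map[[2]], chrom = map[[1]], pos_bp = map[[4]])
    ped <- read.table(path, header = FALSE, colClasses = "character")
    if ((ncol(ped) - 6) %% 2 != 0)
      stop("malformed .ped: odd number of allele columns")
    m <- (ncol(ped) - 6) / 2
    al <- as.matrix(ped[, -(1:6), drop = FALSE])
    if (!all(al %in% c("1", "2")))
      stop("malformed .ped: alleles must be coded 1/2")
    dos <- (al[, seq(1, 2 * m, 2), drop = FALSE] == "2") +
           (al[, seq(2, 2 * m, 2), drop = FALSE] == "2")
    rownames(dos) <- ped[[2]]
    colnames(dos) <- map$snp_id[seq_len(m)]
  }

  if (ncol(dos) != nrow(map))
    stop("dimension mismatch: matrix has ", ncol(dos),
         " SNP columns but map has ", nrow(map), " rows")
  bad <- which(!(dos %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(dos))
    stop("non-{0,1,2} dosage at row ", rc[1], ", column ", rc[2])
  }
  if (anyDuplicated(map$snp_id)) stop("duplicate SNP ids in map")
  if (anyDuplicated(rownames(dos))) stop("duplicate individual ids")
  if (any(map$pos_bp < 0)) stop("negative bp position in map")
  storage.mode(dos) <- "integer"
  if (is.null(colnames(dos))) colnames(dos) <- map$snp_id
  freq <- colMeans(dos) / 2
  structure(list(dosages = dos, map = map, allele_freq = freq,
                 monomorphic = freq == 0 | freq == 1, pedigree = NULL),
            class = "genotype_data")
}

#' Write a genotype object as dosage matrix + map
#'
#' Inverse of [read_genotypes()] for the `"dosage"` dialect.
#'
#' @param geno a `genotype_data`.
#' @param path,map_path output file paths (tab-delimited).
#' @export
write_genotypes <- function(geno, path, map_path) {
  d <- data.frame(id = rownames(geno$dosages), geno$dosages,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(geno$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, map_path))
}

#' Read a phenotype table
#'
#' CSV with header: `id`, `group`, then one numeric column per trait.
#' Missing trait values are permitted (empty or NA) and kept as NA; the
#' affected individual is excluded from that trait's GWAS only.
#'
#' @param path CSV file.
#' @return data.frame with `id`, `group` and named trait columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  ph <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                   colClasses = "character")
  if (!all(c("id", "group") %in% names(ph)))
    stop("phenotype file must have 'id' and 'group' columns")
  if (anyDuplicated(ph$id)) stop("duplicate individual ids in phenotype file")
  traits <- setdiff(names(ph), c("id", "group"))
  if (!length(traits)) stop("no trait columns found")
  for (tr in traits) {
    v <- suppressWarnings(as.numeric(ph[[tr]]))
    if (any(!is.na(ph[[tr]]) & ph[[tr]] != "" & is.na(v)))
      stop("non-numeric value in trait column '", tr, "'")
    ph[[tr]] <- v
  }
  ph
}

#' Write a phenotype table
#' @param pheno data.frame as returned by [read_phenotypes()].
#' @param path output CSV.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene interval map
#'
#' BED-like tab-delimited file with header `gene_id`, `chrom`, `start_bp`,
#' `end_bp`. Coordinates are interpreted as 1-based inclusive; a file in
#' 0-based half-open BED convention can be converted with `bed = TRUE`
#' (adds 1 to starts).
#'
#' @param path TSV file.
#' @param bed logical; if TRUE starts are 0-based half-open and converted.
#' @return data.frame `gene_id`, `chrom`, `start_bp`, `end_bp`.
#' @export
read_gene_map <- function(path, bed = FALSE) {
  if (!file.exists(path)) stop("gene map not found: ", path)
  gm <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "numeric",
                                  "numeric"))
  names(gm) <- c("gene_id", "chrom", "start_bp", "end_bp")
  if (bed) gm$start_bp <- gm$start_bp + 1
  if (anyDuplicated(gm$gene_id)) stop("duplicate gene ids in gene map")
  if (any(gm$start_bp > gm$end_bp)) stop("gene map has start > end")
  if (any(gm$start_bp < 1)) stop("gene map coordinates must be >= 1")
  gm
}

#' Write a gene interval map
#' @param gene_map data.frame as from [read_gene_map()].
#' @param path output TSV.
#' @export
write_gene_map <- function(gene_map, path) {
  write.table(gene_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' Tab-delimited with header; required columns `gene_id`, `term_id`,
#' optional `term_name` and `category`. Genes with no terms are simply
#' absent; empty term ids are rejected.
#'
#' @param path TSV file.
#' @return an `annotation_table` (see [simulate_annotations()]).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  an <- read.table(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("gene_id", "term_id") %in% names(an)))
    stop("annotation file must have 'gene_id' and 'term_id' columns")
  if (any(an$term_id == "" | an$gene_id == ""))
    stop("empty gene or term id in annotation file")
  g2t <- lapply(split(an$term_id, an$gene_id), function(x) sort(unique(x)))
  term_name <- if ("term_name" %in% names(an))
    setNames(an$term_name, an$term_id)[!duplicated(an$term_id)]
  else setNames(unique(an$term_id), unique(an$term_id))
  term_category <- if ("category" %in% names(an))
    setNames(an$category, an$term_id)[!duplicated(an$term_id)]
  else setNames(rep("annotation", length(unique(an$term_id))), unique(an$term_id))
  structure(list(gene2term = g2t, term_name = term_name,
                 term_category = term_category),
            class = "annotation_table")
}

#' Write an annotation table
#' @param annotations an `annotation_table`.
#' @param path output TSV.
#' @export
write_annotations <- function(annotations, path) {
  rows <- do.call(rbind, lapply(names(annotations$gene2term), function(g) {
    terms <- annotations$gene2term[[g]]
    data.frame(gene_id = g, term_id = terms,
               term_name = unname(annotations$term_name[terms]),
               category = unname(annotations$term_category[terms]))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
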