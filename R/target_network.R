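#' Build a gene x miRNA target incidence matrix
#'
#' `incidence[g, m]` is the number of sites of class `>= min_class` that
#' miRNA `m` has in gene `g`'s 3'UTR. Rows cover every gene in the UTR
#' collection (zero rows kept), columns every miRNA. Gene symbols are
#' upper-cased on ingest.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param utrs named character vector of UTRs (unique gene symbols).
#' @param min_class weakest site class counted (default `"7mer-A1"`).
#' @param sites optional precomputed site table from [scan_sites()]
#'   (columns `gene`, `mirna`, `site_class`); when supplied the UTRs are
#'   only used for the gene roster.
#' @return integer matrix, `rownames` = genes, `colnames` = miRNA ids.
#' @export
build_target_matrix <- function(mirnas, utrs, min_class = "7mer-A1",
                                sites = NULL) {
  if (length(mirnas) == 0) stop("empty miRNA set")
  genes <- toupper(names(utrs))
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (is.null(sites)) {
    sites <- scan_sites(mirnas, utrs, min_class = min_class)
  } else {
    keep <- site_class_rank(sites$site_class) >= site_class_rank(min_class)
    sites <- sites[keep, , drop = FALSE]
  }
  mat <- matrix(0L, nrow = length(genes), ncol = length(mirnas),
                dimnames = list(genes, names(mirnas)))
  if (nrow(sites)) {
    tab <- table(factor(toupper(sites$gene), levels = genes),
                 factor(sites$mirna, levels = names(mirnas)))
    mat[] <- as.integer(tab)
  }
  mat
}

#' Restrict a target matrix to brain-expressed genes
#'
#' Keeps only rows whose gene symbol is in the expressed-gene universe;
#' column set and row order are preserved. An empty intersection yields a
#' zero-row matrix with a warning, not an error. Idempotent.
#'
#' @param matrix target matrix from [build_target_matrix()].
#' @param universe character vector of expressed gene symbols.
#' @return the row-filtered matrix.
#' @export
filter_brain_expressed <- function(matrix, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  keep <- rownames(matrix) %in% toupper(universe)
  if (!any(keep)) {
    warning("no target genes are in the expressed-gene universe")
  }
  matrix[keep, , drop = FALSE]
}

#' Genes co-targeted by at least k distinct miRNAs
#'
#' Counts distinct targeting miRNAs per gene (not total sites): a gene is
#' co-targeted when `>= k` columns of the incidence matrix are positive.
#'
#' @param matrix target matrix.
#' @param k co-targeting threshold (default 3).
#' @return list with `k`, `genes` (sorted) and `per_gene_mirnas`
#'   (named list gene -> targeting miRNA ids).
#' @export
cotargeted_genes <- function(matrix, k = 3L) {
  stopifnot(k >= 1)
  if (k > ncol(matrix)) {
    warning("k = ", k, " exceeds the number of miRNAs (", ncol(matrix), ")")
    return(list(k = k, genes = character(0),
                per_gene_mirnas = stats::setNames(list(), character(0))))
  }
  n_mirnas <- rowSums(matrix > 0)
  genes <- sort(rownames(matrix)[n_mirnas >= k])
  per_gene <- lapply(genes, function(g) colnames(matrix)[matrix[g, ] > 0])
  names(per_gene) <- genes
  list(k = k, genes = genes, per_gene_mirnas = per_gene)
}

#' Rank panel miRNAs by their number of targets in a pathway
#'
#' For each miRNA, counts pathway genes with positive incidence; sorted by
#' count descending, ties broken lexicographically by miRNA id.
#'
#' @param matrix target matrix.
#' @param pathway character vector of pathway gene symbols.
#' @param pathway_name optional label carried in the result.
#' @return data.frame `mirna`, `n_pathway_targets` (sorted), with attribute
#'   `pathway`.
#' @export
rank_mirnas_by_pathway <- function(matrix, pathway, pathway_name = NA_character_) {
  if (length(pathway) == 0) stop("empty pathway")
  rows <- intersect(rownames(matrix), toupper(pathway))
  counts <- if (length(rows)) {
    colSums(matrix[rows, , drop = FALSE] > 0)
  } else {
    stats::setNames(rep(0L, ncol(matrix)), colnames(matrix))
  }
  ord <- order(-counts, names(counts))
  out <- data.frame(mirna = names(counts)[ord],
                    n_pathway_targets = as.integer(counts[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "pathway") <- pathway_name
  out
}
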