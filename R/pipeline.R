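#' Default pipeline run configuration
#'
#' Parameters for the full analysis chain over a study input directory
#' (as written by [write_study()]): induction classification, seed-site
#' scanning of the induced panel, brain-expression filtering,
#' co-targeting, permutation enrichment, miRNA ranking and replicate
#' concordance. All randomness derives from the single root `seed` via
#' labeled substreams.
#'
#' @param input_dir directory holding `mirnas.fasta`, `utrs.fasta`,
#'   `universe.txt`, `pathways.gmt`, `expression.tsv`.
#' @param out_dir output directory.
#' @param seed integer root seed.
#' @param theta induction fold threshold (default 1.5).
#' @param alpha class-assignment significance level (default 0.05).
#' @param k co-targeting threshold (default 3).
#' @param min_class weakest site class counted as a binding site
#'   (default `"7mer-A1"`).
#' @param n_perm enrichment permutations (default 9999).
#' @param cutoff enrichment significance cutoff (default 0.01).
#' @param reference reference feature name (default `"snoRNA-202"`).
#' @param concordance_R random panels for the concordance baseline
#'   (default 1000).
#' @param rank_pathway pathway used for miRNA ranking; `NULL` (default)
#'   takes the top-enriched pathway.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir, seed = 1L, theta = 1.5,
                       alpha = 0.05, k = 3L, min_class = "7mer-A1",
                       n_perm = 9999L, cutoff = 0.01,
                       reference = "snoRNA-202", concordance_R = 1000L,
                       rank_pathway = NULL) {
  cfg <- list(input_dir = input_dir, out_dir = out_dir,
              seed = as.integer(seed), theta = theta, alpha = alpha,
              k = as.integer(k), min_class = min_class,
              n_perm = as.integer(n_perm), cutoff = cutoff,
              reference = reference, concordance_R = as.integer(concordance_R),
              rank_pathway = rank_pathway)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#' @param path YAML file with the fields of [run_config()].
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: fold-change normalization, induction classification
#' and panel selection, seed-site scanning of the induced panel, target
#' matrix and brain-expression filter, co-targeting, permutation
#' enrichment, pathway miRNA ranking and replicate concordance; every
#' intermediate is written as a commented TSV and a JSON manifest records
#' version, parameters, seeds and content digests. The pipeline is a pure
#' function of (inputs, config): identical inputs and config give
#' byte-identical outputs.
#'
#' @param config a [run_config()] or path to a YAML file of one.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  ind <- config$input_dir
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  version <- as.character(utils::packageVersion("fearmiR"))
  cfg_for_digest <- config[setdiff(names(config), c("input_dir", "out_dir"))]
  digest_file <- tempfile()
  jsonlite::write_json(cfg_for_digest, digest_file, auto_unbox = TRUE,
                       digits = NA)
  cfg_digest <- unname(tools::md5sum(digest_file))
  unlink(digest_file)
  hdr <- c(paste("fearmiR", version),
           paste("config_digest", cfg_digest),
           paste("seed", config$seed))

  inputs <- run_stage("ingest", {
    list(mirnas = read_fasta(file.path(ind, "mirnas.fasta")),
         utrs = read_fasta(file.path(ind, "utrs.fasta")),
         universe = read_gene_list(file.path(ind, "universe.txt")),
         pathways = read_gmt(file.path(ind, "pathways.gmt")),
         expression = read_tsv(file.path(ind, "expression.tsv")))
  })

  fc <- run_stage("normalize", {
    normalize_and_fold(inputs$expression, reference = config$reference)
  })
  classes <- run_stage("classify", {
    classify_induction(fc, alpha = config$alpha, theta = config$theta)
  })
  panel <- run_stage("panel", {
    sort(intersect(classes$feature[classes$induced], names(inputs$mirnas)))
  })
  if (length(panel) == 0) stop("pipeline stage 'panel' failed: no induced miRNA ",
                               "with a sequence record", call. = FALSE)
  sites <- run_stage("scan", {
    scan_sites(inputs$mirnas[panel], inputs$utrs, min_class = config$min_class)
  })
  mat <- run_stage("cotarget", {
    build_target_matrix(inputs$mirnas[panel], inputs$utrs,
                        min_class = config$min_class, sites = sites)
  })
  mat_brain <- run_stage("cotarget", {
    filter_brain_expressed(mat, inputs$universe)
  })
  cot <- run_stage("cotarget", cotargeted_genes(mat_brain, k = config$k))
  enr <- run_stage("enrich", {
    enrich_all(cot$genes, inputs$pathways, inputs$universe,
               n_perm = config$n_perm, cutoff = config$cutoff,
               rng_seed = derive_seed(config$seed, "enrich"))
  })
  rank_pw <- config$rank_pathway %||% enr$pathway[1]
  ranking <- run_stage("rank", {
    rank_mirnas_by_pathway(mat_brain, inputs$pathways[[rank_pw]],
                           pathway_name = rank_pw)
  })
  conc <- run_stage("concordance", {
    pc <- pairwise_concordance(fc, panel)
    bl <- random_panel_baseline(fc, m = length(panel),
                                R = config$concordance_R,
                                rng_seed = derive_seed(config$seed, "concordance"),
                                exclude = panel)
    merge(pc, bl$per_pair, by = c("rep_a", "rep_b"), sort = TRUE)
  })

  paths <- c(folds = "folds.tsv", classification = "classification.tsv",
             panel = "panel.txt", sites = "sites.tsv",
             cotarget = "cotarget.tsv", enrichment = "enrichment.tsv",
             ranking = "ranking.tsv", concordance = "concordance.tsv")
  paths <- stats::setNames(file.path(out, paths), names(paths))
  write_tsv(fc, paths[["folds"]], hdr)
  write_tsv(classes, paths[["classification"]], hdr)
  writeLines(c(paste0("# ", hdr), panel), paths[["panel"]])
  write_tsv(sites, paths[["sites"]], hdr)
  write_tsv(data.frame(gene = cot$genes,
                       n_mirnas = lengths(cot$per_gene_mirnas),
                       mirnas = vapply(cot$per_gene_mirnas, paste,
                                       character(1), collapse = ","),
                       stringsAsFactors = FALSE),
            paths[["cotarget"]], hdr)
  write_tsv(enr, paths[["enrichment"]], hdr)
  write_tsv(ranking, paths[["ranking"]], hdr)
  write_tsv(conc, paths[["concordance"]], hdr)

  manifest <- list(
    tool = "fearmiR", version = version, config = cfg_for_digest,
    config_digest = cfg_digest,
    stage_seeds = list(enrich = derive_seed(config$seed, "enrich"),
                       concordance = derive_seed(config$seed, "concordance")),
    n_induced = sum(classes$induced), panel = panel,
    n_cotargeted = length(cot$genes), rank_pathway = rank_pw,
    outputs = as.list(vapply(paths, function(p) unname(tools::md5sum(p)),
                             character(1))))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
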