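#' Configuration for the synthetic study generator
#'
#' Holds every knob of the seeded generators that emulate the study design:
#' a panel of fear-induced miRNAs measured in three grouped replicates
#' (naive / immediate shock / delayed shock), a transcriptome of 3'UTRs with
#' planted seed sites so that a known subset of genes is co-targeted by
#' three or more panel miRNAs, a brain-expressed gene universe, and a
#' pathway collection with one set enriched among the co-targeted genes
#' (15 of its 40 members, with the first miRNA planted as the top
#' co-regulator holding 12 pathway targets).
#'
#' @param seed integer RNG root seed; every generator derives a labeled
#'   substream from it.
#' @param n_mirnas number of panel miRNAs (default 21).
#' @param mirna_length mature miRNA length in nt (default 22).
#' @param n_genes transcriptome size (default 2000).
#' @param utr_length UTR length in nt (default 500).
#' @param planted_cotarget_fraction fraction of genes planted with sites for
#'   `>= mirnas_per_gene` distinct miRNAs (default 0.09).
#' @param mirnas_per_gene distinct miRNAs planted per co-targeted gene
#'   (default 3).
#' @param n_nonbrain_cotargets co-targeted decoy genes excluded from the
#'   brain-expressed universe, exercising the expression filter (default 40).
#' @param brain_fraction fraction of non-target background genes kept in the
#'   brain-expressed universe (default 0.9).
#' @param n_pathways number of gene sets (default 20; one is the planted,
#'   enriched set).
#' @param pathway_size size of the planted pathway (default 40).
#' @param pathway_size_range size range of background pathways, drawn
#'   log-uniformly (default `c(10, 200)`, the spread of curated canonical
#'   pathway collections).
#' @param enriched_overlap planted-pathway members drawn from the
#'   co-targeted genes (default 15, the 15-of-40 geometry).
#' @param focal_pathway_targets pathway targets planted for the first
#'   ("focal") miRNA (default 12).
#' @param n_extra_focal_genes pathway members targeted by the focal miRNA
#'   alone or with one partner, hence not co-targeted (default 4).
#' @param n_replicates biological replicates per group (default 3).
#' @param groups group labels, must contain `naive` and `trained`.
#' @param class_assignments optional named character vector miRNA id ->
#'   class in `I/II/III/none`; default: 4 Class I, 3 Class II, rest III.
#' @param class_means named list of per-class mean fold-changes
#'   `c(immediate=, trained=)` relative to naive.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise on fold-changes (default 0.10).
#' @param n_background_features non-induced array features carried in the
#'   expression table besides the panel (default 100).
#' @param reference_feature name of the normalization reference feature.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mirnas = 21L,
                       mirna_length = 22L,
                       n_genes = 2000L,
                       utr_length = 500L,
                       planted_cotarget_fraction = 0.09,
                       mirnas_per_gene = 3L,
                       n_nonbrain_cotargets = 40L,
                       brain_fraction = 0.9,
                       n_pathways = 20L,
                       pathway_size = 40L,
                       pathway_size_range = c(10L, 200L),
                       enriched_overlap = 15L,
                       focal_pathway_targets = 12L,
                       n_extra_focal_genes = 4L,
                       n_replicates = 3L,
                       groups = c("naive", "immediate", "trained"),
                       class_assignments = NULL,
                       class_means = list(
                         I    = c(immediate = 1.0, trained = 3.0),
                         II   = c(immediate = 1.8, trained = 3.0),
                         III  = c(immediate = 2.0, trained = 2.0),
                         none = c(immediate = 1.0, trained = 1.0)),
                       noise_cv = 0.10,
                       n_background_features = 100L,
                       reference_feature = "snoRNA-202") {
  cfg <- list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
              mirna_length = as.integer(mirna_length),
              n_genes = as.integer(n_genes), utr_length = as.integer(utr_length),
              planted_cotarget_fraction = planted_cotarget_fraction,
              mirnas_per_gene = as.integer(mirnas_per_gene),
              n_nonbrain_cotargets = as.integer(n_nonbrain_cotargets),
              brain_fraction = brain_fraction,
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              pathway_size_range = as.integer(pathway_size_range),
              enriched_overlap = as.integer(enriched_overlap),
              focal_pathway_targets = as.integer(focal_pathway_targets),
              n_extra_focal_genes = as.integer(n_extra_focal_genes),
              n_replicates = as.integer(n_replicates), groups = groups,
              class_assignments = class_assignments, class_means = class_means,
              noise_cv = noise_cv,
              n_background_features = as.integer(n_background_features),
              reference_feature = reference_feature)
  stopifnot(cfg$n_mirnas >= 3, cfg$mirna_length >= 8,
            cfg$planted_cotarget_fraction >= 0,
            cfg$planted_cotarget_fraction <= 1,
            cfg$mirnas_per_gene >= 1, cfg$noise_cv >= 0,
            cfg$n_replicates >= 1,
            all(c("naive", "trained") %in% cfg$groups),
            cfg$enriched_overlap <= cfg$pathway_size)
  if (cfg$enriched_overlap > 0) {
    stopifnot(cfg$focal_pathway_targets - cfg$n_extra_focal_genes >= 0,
              cfg$focal_pathway_targets - cfg$n_extra_focal_genes <=
                cfg$enriched_overlap)
  }
  if (!all(c("I", "II", "III", "none") %in% names(cfg$class_means))) {
    stop("class_means must define classes I, II, III and none")
  }
  for (cl in c("I", "II", "III")) {
    if (cfg$class_means[[cl]][["trained"]] < 1) {
      stop("effect fold for induced class ", cl, " must be >= 1")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

default_class_assignments <- function(ids) {
  n <- length(ids)
  cls <- rep("III", n)
  cls[seq_len(min(4L, n))] <- "I"
  if (n > 4) cls[5:min(7L, n)] <- "II"
  stats::setNames(cls, ids)
}

#' Simulate a panel of mature miRNA sequences
#'
#' Random sequences over `A/C/G/U` with pairwise-distinct seeds
#' (positions 2-8). Seeds whose positions 4-6 read `AAU` are rejected: for
#' such seeds the target-side ATT substitution of [mutate_seed_region()] is
#' an identity, so every simulated seed is guaranteed mutable.
#'
#' @param config a [sim_config()].
#' @return named character vector of `n_mirnas` sequences
#'   (`mir-01`, `mir-02`, ...).
#' @export
simulate_mirnas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, "mirnas"), {
    n <- config$n_mirnas
    seqs <- character(0)
    seeds_seen <- character(0)
    tries <- 0L
    max_tries <- 1000L * n
    while (length(seqs) < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not generate ", n, " miRNAs with distinct, mutable seeds ",
             "within ", max_tries, " attempts (seed-uniqueness constraint)")
      }
      s <- random_seqs(1L, config$mirna_length, c("A", "C", "G", "U"))
      if (substr(s, 4, 6) == "AAU") next
      sd <- seed_of(s)
      if (sd %in% seeds_seen) next
      seeds_seen <- c(seeds_seen, sd)
      seqs <- c(seqs, s)
    }
    stats::setNames(seqs, sprintf("mir-%02d", seq_len(n)))
  })
}

# Background UTRs containing no 6mer-or-stronger core for any miRNA seed,
# by batch rejection sampling against the union of 6mer cores.
clean_background_utrs <- function(n, len, mirnas) {
  cores <- unique(vapply(mirnas, function(m) seed_patterns(m)$s6, character(1)))
  regex <- paste(cores, collapse = "|")
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 10000L) stop("background rejection sampling did not converge")
    cand <- random_seqs(max(200L, 2L * (n - length(out))), len)
    out <- c(out, cand[!grepl(regex, cand)])
  }
  out[seq_len(n)]
}

# Build the insert string for one planted site. Guard flanks ensure the
# planted class is also the reported class: a 7mer-m8 must not be followed
# by A (would scan as 8mer) and a 7mer-A1 must not be preceded by the
# m8-pairing base. Returns the string plus the site's offset within it.
site_insert <- function(pat, site_class) {
  switch(site_class,
    "8mer" = list(str = paste0(pat$s7, "A"), off = 0L, len = 8L),
    "7mer-m8" = list(
      str = paste0(pat$s7, sample(c("C", "G", "T"), 1L)),
      off = 0L, len = 7L),
    "7mer-A1" = list(
      str = paste0(sample(setdiff(c("A", "C", "G", "T"), pat$m8_char), 1L),
                   pat$s6, "A"),
      off = 1L, len = 7L),
    stop("unsupported planted site class: ", site_class))
}

# Plant non-overlapping sites (>=2 nt apart) for the given miRNAs into a
# clean background UTR; returns NULL if placement failed.
plant_sites_once <- function(bg, mirna_ids, mirnas, gene) {
  k <- length(mirna_ids)
  inserts <- lapply(mirna_ids, function(id) {
    pat <- seed_patterns(mirnas[[id]])
    cls <- sample(c("8mer", "7mer-m8", "7mer-A1"), 1L)
    c(site_insert(pat, cls), list(site_class = cls, mirna = id))
  })
  ins_len <- vapply(inserts, function(x) nchar(x$str), integer(1))
  len <- nchar(bg)
  if (len < sum(ins_len + 2L)) {
    stop("utr_length ", len, " too short to hold ", k, " planted sites")
  }
  starts <- NULL
  for (i in 1:200) {
    cand <- sort(sample.int(len - max(ins_len) + 1L, k) - 1L)  # 0-based
    if (k == 1L || all(diff(cand) >= ins_len[-k] + 2L)) {
      starts <- cand
      break
    }
  }
  if (is.null(starts)) return(NULL)
  utr <- bg
  sites <- vector("list", k)
  for (i in seq_len(k)) {
    ins <- inserts[[i]]
    s <- starts[i]
    substr(utr, s + 1L, s + nchar(ins$str)) <- ins$str
    site_start <- s + ins$off
    sites[[i]] <- data.frame(gene = gene, mirna = ins$mirna,
                             site_class = ins$site_class,
                             start = site_start,
                             end = site_start + ins$len,
                             stringsAsFactors = FALSE)
  }
  list(utr = utr, sites = do.call(rbind, sites))
}

#' Simulate a transcriptome of 3'UTRs with planted seed sites
#'
#' Background UTRs are rejection-sampled to contain no 6mer-or-stronger
#' site for any panel miRNA; planted genes receive non-overlapping sites
#' (class drawn from 8mer / 7mer-m8 / 7mer-A1, separated by >= 2 nt) at
#' recorded positions. Every planted gene is verified: re-scanning it must
#' report exactly the planted sites, and each planted site must be
#' abolishable by [mutate_seed_region()]; the gene is regenerated otherwise,
#' so ground truth and scanner output coincide by construction.
#'
#' UTRs are emitted in DNA alphabet (T), matching transcript-annotation
#' FASTA conventions; scanning is U/T-agnostic.
#'
#' @param config a [sim_config()].
#' @param mirnas named character vector from [simulate_mirnas()].
#' @param assignments optional named list `gene -> character vector of miRNA
#'   ids` fixing which miRNAs are planted where; by default
#'   `round(planted_cotarget_fraction * n_genes)` random genes each receive
#'   `mirnas_per_gene` random distinct miRNAs.
#' @return list with `utrs` (named character vector over all genes) and
#'   `truth` (list: `planted_sites` data.frame, `assignments`,
#'   `cotargeted_genes` = genes with >= 3 distinct planted miRNAs).
#' @export
simulate_transcriptome <- function(config, mirnas, assignments = NULL) {
  stopifnot(inherits(config, "sim_config"), length(mirnas) >= 1,
            !is.null(names(mirnas)))
  withr::with_seed(derive_seed(config$seed, "transcriptome"), {
    gene_names <- sprintf("GENE%04d", seq_len(config$n_genes))
    if (is.null(assignments)) {
      n_planted <- round(config$planted_cotarget_fraction * config$n_genes)
      planted_genes <- sort(sample(gene_names, n_planted))
      assignments <- lapply(planted_genes, function(g) {
        sample(names(mirnas), config$mirnas_per_gene)
      })
      names(assignments) <- planted_genes
    }
    stopifnot(all(names(assignments) %in% gene_names))
    utrs <- stats::setNames(
      clean_background_utrs(config$n_genes, config$utr_length, mirnas),
      gene_names)
    all_sites <- vector("list", length(assignments))
    for (j in seq_along(assignments)) {
      g <- names(assignments)[j]
      ok <- FALSE
      for (attempt in 1:60) {
        bg <- clean_background_utrs(1L, config$utr_length, mirnas)
        planted <- plant_sites_once(bg, assignments[[j]], mirnas, g)
        if (is.null(planted)) next
        if (planted_gene_valid(planted, mirnas)) {
          utrs[[g]] <- planted$utr
          all_sites[[j]] <- planted$sites
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("failed to plant verified sites in gene ", g)
    }
    planted_sites <- if (length(all_sites)) {
      do.call(rbind, all_sites)
    } else {
      data.frame(gene = character(0), mirna = character(0),
                 site_class = character(0), start = integer(0),
                 end = integer(0), stringsAsFactors = FALSE)
    }
    rownames(planted_sites) <- NULL
    n_distinct <- vapply(assignments, function(x) length(unique(x)), integer(1))
    truth <- list(
      planted_sites = planted_sites,
      assignments = assignments,
      cotargeted_genes = sort(names(assignments)[n_distinct >= 3L]))
    list(utrs = utrs, truth = truth)
  })
}

# A planted gene is valid when the scanner reports exactly the planted
# sites (for every panel miRNA) and every planted site is mutable.
planted_gene_valid <- function(planted, mirnas) {
  utr <- stats::setNames(planted$utr, planted$sites$gene[1])
  scanned <- scan_sites(mirnas, utr, min_class = "6mer")
  key <- function(df) {
    sort(paste(df$mirna, df$site_class, df$start, df$end, sep = ":"))
  }
  if (!identical(key(scanned), key(planted$sites))) return(FALSE)
  for (i in seq_len(nrow(planted$sites))) {
    site <- planted$sites[i, ]
    ok <- tryCatch({
      mutate_seed_region(mirnas[[site$mirna]], utr, site)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Simulate a pathway gene-set collection
#'
#' One designated pathway draws `enriched_overlap` members from the
#' co-targeted genes (plus any `extra_target_genes` recorded in `truth`),
#' filled up to `pathway_size` with non-target universe genes; the
#' remaining pathways are uniform draws from the universe with sizes
#' log-uniform in `pathway_size_range`. With `enriched_overlap = 0` or no
#' co-targeted genes, all pathways are uniform.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth list from [simulate_transcriptome()] (fields
#'   `cotargeted_genes`, optional `pathway_cotarget_genes`,
#'   `extra_target_genes`, `planted_sites`).
#' @param universe character vector: the brain-expressed gene universe.
#' @return list with `sets` (named list, GMT-serializable) and
#'   `enriched_pathway` (name or `NA`).
#' @export
simulate_pathways <- function(config, truth, universe) {
  stopifnot(inherits(config, "sim_config"), length(universe) > 0)
  if (config$pathway_size > length(universe)) {
    stop("pathway_size exceeds universe size")
  }
  withr::with_seed(derive_seed(config$seed, "pathways"), {
    cot <- intersect(truth$cotargeted_genes, universe)
    extra <- intersect(truth$extra_target_genes %||% character(0), universe)
    target_genes <- unique(c(truth$planted_sites$gene, extra))
    nontarget <- setdiff(universe, target_genes)
    sets <- list()
    enriched <- NA_character_
    plant <- config$enriched_overlap > 0 && length(cot) >= config$enriched_overlap
    if (plant) {
      enriched <- "vesicle_exocytosis"
      core <- truth$pathway_cotarget_genes %||% sample(cot, config$enriched_overlap)
      fill_n <- config$pathway_size - length(core) - length(extra)
      stopifnot(fill_n >= 0, fill_n <= length(nontarget))
      sets[[enriched]] <- sort(c(core, extra, sample(nontarget, fill_n)))
    }
    n_bg <- config$n_pathways - length(sets)
    rng <- log(config$pathway_size_range)
    for (i in seq_len(n_bg)) {
      sz <- min(length(universe), max(2L, round(exp(stats::runif(1, rng[1], rng[2])))))
      sets[[sprintf("random_pathway_%03d", i)]] <- sort(sample(universe, sz))
    }
    list(sets = sets, enriched_pathway = enriched)
  })
}

#' Simulate a grouped-replicate expression table
#'
#' Raw expression values for the miRNA panel, background array features and
#' the normalization reference, over `groups x n_replicates` samples. Each
#' value is `basal(feature) * class fold(group) * lognormal noise(CV) *
#' sample scale`; the shared per-sample scale factor emulates loading
#' differences and cancels under reference normalization. The reference
#' feature tracks the sample scale without extra noise (a high-abundance
#' reference whose replicate CV is negligible), so realized per-replicate
#' fold-changes follow `class mean x lognormal(noise_cv)`.
#'
#' @param config a [sim_config()].
#' @param mirna_ids feature names for the panel; defaults to
#'   `mir-01 ... mir-<n_mirnas>`.
#' @return list with `expression` (long data.frame: `feature`, `group`,
#'   `replicate`, `value`) and `true_classes` (named vector, panel and
#'   background features).
#' @export
simulate_expression <- function(config, mirna_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mirna_ids <- mirna_ids %||% sprintf("mir-%02d", seq_len(config$n_mirnas))
  cls <- config$class_assignments %||% default_class_assignments(mirna_ids)
  if (!identical(names(cls), mirna_ids)) {
    cls <- cls[mirna_ids]
    names(cls) <- mirna_ids
    if (anyNA(cls)) stop("class_assignments does not cover all miRNA ids")
  }
  if (!all(cls %in% c("I", "II", "III", "none"))) {
    stop("unknown induction class label: ",
         paste(setdiff(cls, c("I", "II", "III", "none")), collapse = ", "))
  }
  bg_ids <- if (config$n_background_features > 0) {
    sprintf("array-mir-%03d", seq_len(config$n_background_features))
  } else {
    character(0)
  }
  true_classes <- c(cls, stats::setNames(rep("none", length(bg_ids)), bg_ids))
  features <- c(names(true_classes), config$reference_feature)
  groups <- config$groups
  nrep <- config$n_replicates
  sigma <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0
  ln_noise <- function(n) {
    if (sigma == 0) rep(1, n) else stats::rlnorm(n, -sigma^2 / 2, sigma)
  }
  fold_of <- function(class, group) {
    if (group == "naive") return(1)
    config$class_means[[class]][[group]]
  }
  withr::with_seed(derive_seed(config$seed, "expression"), {
    basal <- stats::setNames(stats::rlnorm(length(true_classes), log(50), 0.5),
                             names(true_classes))
    rows <- list()
    for (g in groups) {
      for (r in seq_len(nrep)) {
        scale_j <- stats::rlnorm(1, 0, 0.25)
        vals <- vapply(names(true_classes), function(f) {
          basal[[f]] * fold_of(true_classes[[f]], g) * ln_noise(1) * scale_j
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          feature = c(names(true_classes), config$reference_feature),
          group = g, replicate = r,
          value = c(vals, 1000 * scale_j),
          stringsAsFactors = FALSE)
      }
    }
    list(expression = do.call(rbind, rows), true_classes = true_classes)
  })
}

#' Simulate a complete planted study
#'
#' Wires the four generators together with the study's headline geometry:
#' `n_mirnas` panel miRNAs; co-targeted genes planted at
#' `planted_cotarget_fraction`; `n_nonbrain_cotargets` co-targeted decoys
#' left out of the brain-expressed universe; one pathway holding
#' `enriched_overlap` co-targeted members out of `pathway_size`, in which
#' the focal miRNA (`mir-01`) is planted as top co-regulator with
#' `focal_pathway_targets` targets (partly via `n_extra_focal_genes`
#' pathway members it targets alone or with one partner) while every other
#' miRNA holds at most 8; and a grouped-replicate expression table with the
#' Class I/II/III structure.
#'
#' @param config a [sim_config()].
#' @return list: `config`, `mirnas`, `utrs`, `truth`, `pathways`,
#'   `universe`, `expression`, `true_classes`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mirnas <- simulate_mirnas(config)
  ids <- names(mirnas)
  focal <- ids[1]
  others <- ids[-1]
  design <- withr::with_seed(derive_seed(config$seed, "study-design"), {
    gene_names <- sprintf("GENE%04d", seq_len(config$n_genes))
    n_cot <- round(config$planted_cotarget_fraction * config$n_genes)
    geometry <- n_cot >= config$enriched_overlap && config$enriched_overlap > 0
    n_extra <- if (geometry) config$n_extra_focal_genes else 0L
    special <- sample(gene_names, n_cot + n_extra + config$n_nonbrain_cotargets)
    cot_genes <- sort(special[seq_len(n_cot)])
    extra_genes <- sort(special[n_cot + seq_len(n_extra)])
    decoy_genes <- sort(utils::tail(special, config$n_nonbrain_cotargets))
    asg <- list()
    pw_cot <- character(0)
    if (geometry) {
      pw_cot <- sample(cot_genes, config$enriched_overlap)
      n_focal_cot <- config$focal_pathway_targets - n_extra
      repeat {
        pw_asg <- lapply(seq_along(pw_cot), function(i) {
          if (i <= n_focal_cot) {
            c(focal, sample(others, config$mirnas_per_gene - 1L))
          } else {
            sample(others, config$mirnas_per_gene)
          }
        })
        names(pw_asg) <- pw_cot
        extra_asg <- lapply(seq_along(extra_genes), function(i) {
          if (i %% 2L == 1L) focal else c(focal, sample(others, 1L))
        })
        names(extra_asg) <- extra_genes
        counts <- table(c(unlist(pw_asg), unlist(extra_asg)))
        counts <- counts[setdiff(names(counts), focal)]
        if (length(counts) == 0L || max(counts) <= 8L) break
      }
      asg <- c(asg, pw_asg, extra_asg)
    }
    plain_cot <- setdiff(cot_genes, pw_cot)
    asg <- c(asg,
             stats::setNames(lapply(plain_cot, function(g) {
               sample(ids, config$mirnas_per_gene)
             }), plain_cot),
             stats::setNames(lapply(decoy_genes, function(g) {
               sample(ids, config$mirnas_per_gene)
             }), decoy_genes))
    background <- setdiff(gene_names, names(asg))
    brain_bg <- sort(sample(background,
                            round(config$brain_fraction * length(background))))
    list(assignments = asg, cot_genes = cot_genes, extra_genes = extra_genes,
         decoy_genes = decoy_genes, pw_cot = pw_cot,
         universe = sort(c(cot_genes, extra_genes, brain_bg)))
  })
  trans <- simulate_transcriptome(config, mirnas,
                                  assignments = design$assignments)
  truth <- trans$truth
  truth$cotargeted_brain <- design$cot_genes
  truth$nonbrain_cotargeted <- design$decoy_genes
  truth$pathway_cotarget_genes <- design$pw_cot
  truth$extra_target_genes <- design$extra_genes
  truth$focal_mirna <- focal
  pathways <- simulate_pathways(config, truth, design$universe)
  truth$enriched_pathway <- pathways$enriched_pathway
  expr <- simulate_expression(config, mirna_ids = ids)
  truth$true_classes <- expr$true_classes
  list(config = config, mirnas = mirnas, utrs = trans$utrs, truth = truth,
       pathways = pathways$sets, universe = design$universe,
       expression = expr$expression, true_classes = expr$true_classes)
}

#' Write all study inputs to a directory
#'
#' Emits the file set the pipeline consumes: miRNA FASTA, UTR FASTA
#' (record id = gene symbol), brain-expressed universe text file, GMT gene
#' sets, expression TSV and ground-truth tables.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    mirnas = file.path(dir, "mirnas.fasta"),
    utrs = file.path(dir, "utrs.fasta"),
    universe = file.path(dir, "universe.txt"),
    pathways = file.path(dir, "pathways.gmt"),
    expression = file.path(dir, "expression.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_classes = file.path(dir, "truth_classes.tsv"))
  write_fasta(study$mirnas, paths[["mirnas"]])
  write_fasta(study$utrs, paths[["utrs"]])
  write_gene_list(study$universe, paths[["universe"]])
  write_gmt(study$pathways, paths[["pathways"]])
  hdr <- sprintf("fearmiR %s simulated study; seed=%d",
                 as.character(utils::packageVersion("fearmiR")),
                 study$config$seed)
  write_tsv(study$expression, paths[["expression"]], header = hdr)
  write_tsv(study$truth$planted_sites, paths[["truth_sites"]], header = hdr)
  write_tsv(data.frame(feature = names(study$true_classes),
                       class = unname(study$true_classes)),
            paths[["truth_classes"]], header = hdr)
  invisible(paths)
}
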