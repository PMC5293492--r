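#' Inter-replicate concordance of fold-changes over a feature panel
#'
#' For every unordered pair of replicates in one group, correlates the two
#' fold-change vectors over the panel features. Pearson is computed on log
#' fold-changes (ratio data; configurable), Spearman on mid-ranks of the
#' raw folds. A zero-variance vector yields `NA` for the affected
#' coefficient rather than a number.
#'
#' @param fc fold-change table from [normalize_and_fold()].
#' @param panel character vector of panel feature ids (subset of the
#'   table's features).
#' @param group group whose replicates are compared (default `"trained"`).
#' @param log_pearson compute Pearson on log folds (default `TRUE`).
#' @return data.frame `rep_a`, `rep_b`, `pearson`, `spearman`.
#' @export
pairwise_concordance <- function(fc, panel, group = "trained",
                                 log_pearson = TRUE) {
  stopifnot(length(panel) >= 2)
  missing <- setdiff(panel, fc$feature)
  if (length(missing)) {
    stop("panel features not in the table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  sub <- fc[fc$group == group & fc$feature %in% panel, , drop = FALSE]
  reps <- sort(unique(sub$replicate))
  if (length(reps) < 2) stop("need at least 2 replicates in group ", group)
  m <- matrix(NA_real_, nrow = length(panel), ncol = length(reps),
              dimnames = list(panel, reps))
  m[cbind(match(sub$feature, panel), match(sub$replicate, reps))] <- sub$fold
  if (anyNA(m)) stop("incomplete fold-change table for the panel")
  safe_cor <- function(x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }
  pairs <- utils::combn(seq_along(reps), 2)
  out <- apply(pairs, 2, function(ij) {
    a <- m[, ij[1]]
    b <- m[, ij[2]]
    pa <- if (log_pearson) log(a) else a
    pb <- if (log_pearson) log(b) else b
    data.frame(rep_a = reps[ij[1]], rep_b = reps[ij[2]],
               pearson = safe_cor(pa, pb, "pearson"),
               spearman = safe_cor(a, b, "spearman"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Concordance baseline from random feature panels
#'
#' Draws `R` uniform random panels of size `m` from the feature universe
#' (excluding the selected panel by default), computes
#' [pairwise_concordance()] for each, and summarizes per replicate pair by
#' mean and standard deviation. Deterministic for a fixed seed.
#'
#' @param fc fold-change table.
#' @param m panel size (default 21).
#' @param R number of random panels (default 1000).
#' @param rng_seed integer seed.
#' @param exclude features excluded from the draw (default `NULL`: none);
#'   pass the selected panel for the cleaner null.
#' @param group replicate group (default `"trained"`).
#' @param log_pearson see [pairwise_concordance()].
#' @return list with `per_pair` (data.frame `rep_a`, `rep_b`,
#'   `mean_pearson`, `sd_pearson`, `mean_spearman`, `sd_spearman`), `m`,
#'   `R`.
#' @export
random_panel_baseline <- function(fc, m = 21L, R = 1000L, rng_seed = 1L,
                                  exclude = NULL, group = "trained",
                                  log_pearson = TRUE) {
  pool <- setdiff(unique(fc$feature), exclude)
  if (m > length(pool)) {
    stop("panel size m = ", m, " exceeds the ", length(pool),
         "-feature universe")
  }
  draws <- withr::with_seed(as.integer(rng_seed), {
    lapply(seq_len(R), function(i) sample(pool, m))
  })
  per <- lapply(draws, function(p) {
    pairwise_concordance(fc, p, group = group, log_pearson = log_pearson)
  })
  key <- paste(per[[1]]$rep_a, per[[1]]$rep_b, sep = ":")
  pearson <- sapply(per, `[[`, "pearson")
  spearman <- sapply(per, `[[`, "spearman")
  if (is.null(dim(pearson))) {
    pearson <- matrix(pearson, nrow = 1)
    spearman <- matrix(spearman, nrow = 1)
  }
  list(per_pair = data.frame(
         rep_a = per[[1]]$rep_a, rep_b = per[[1]]$rep_b,
         mean_pearson = rowMeans(pearson, na.rm = TRUE),
         sd_pearson = apply(pearson, 1, stats::sd, na.rm = TRUE),
         mean_spearman = rowMeans(spearman, na.rm = TRUE),
         sd_spearman = apply(spearman, 1, stats::sd, na.rm = TRUE),
         stringsAsFactors = FALSE),
       m = m, R = R)
}
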