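#' Overlap between a target list and a pathway
#' @param targets,pathway character vectors of gene symbols.
#' @return integer `|targets intersect pathway|`.
#' @export
observed_overlap <- function(targets, pathway) {
  length(intersect(toupper(targets), toupper(pathway)))
}

#' Upper-tail hypergeometric probability by log-choose tail summation
#'
#' `P(X >= observed)` for `X ~ Hypergeometric(U, pathway_size, n)`: the
#' overlap between a fixed pathway of `pathway_size` genes and a uniform
#' random draw of `n` genes from a universe of `U`. Computed by direct
#' summation of the tail with log-binomial coefficients; serves as the
#' closed-form oracle for the permutation null.
#'
#' @param U universe size.
#' @param pathway_size pathway size.
#' @param n drawn-set (target list) size.
#' @param observed observed overlap.
#' @return probability in `[0, 1]`.
#' @export
hypergeometric_pvalue <- function(U, pathway_size, n, observed) {
  stopifnot(length(U) == 1, length(observed) == 1)
  if (observed < 0 || pathway_size > U || n > U ||
      observed > min(pathway_size, n)) {
    stop("inconsistent hypergeometric counts: U=", U, ", K=", pathway_size,
         ", n=", n, ", observed=", observed)
  }
  if (observed == 0) return(1)
  k <- observed:min(pathway_size, n)
  terms <- lchoose(pathway_size, k) + lchoose(U - pathway_size, n - k) -
    lchoose(U, n)
  min(1, sum(exp(terms)))
}

#' Permutation p-value for pathway over-representation
#'
#' Draws `n_perm` uniform random gene sets of size `|targets|` from the
#' expressed-gene universe (without replacement within each set), counts
#' how many achieve an overlap with the pathway at least as large as
#' observed, and reports the add-one empirical p-value
#' `(n_ge + 1) / (n_perm + 1)` alongside the hypergeometric tail.
#'
#' @param targets target gene list (e.g. the co-targeted genes).
#' @param pathway pathway gene set; must lie within the universe.
#' @param universe expressed-gene universe the random sets are drawn from.
#' @param n_perm number of random sets (default 9999).
#' @param rng_seed integer seed; fixed seed gives identical results.
#' @param cutoff significance cutoff on the empirical p-value (default 0.01).
#' @return one-row data.frame: `pathway_size`, `target_list_size`,
#'   `observed_overlap`, `n_perm`, `n_ge`, `p_empirical`,
#'   `p_hypergeometric`, `significant`.
#' @export
permutation_pvalue <- function(targets, pathway, universe, n_perm = 9999L,
                               rng_seed = 1L, cutoff = 0.01) {
  stopifnot(n_perm >= 1)
  universe <- unique(toupper(universe))
  pathway <- unique(toupper(pathway))
  targets <- intersect(unique(toupper(targets)), universe)
  stray <- setdiff(pathway, universe)
  if (length(stray)) {
    stop("pathway members outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  U <- length(universe)
  n <- length(targets)
  obs <- observed_overlap(targets, pathway)
  member <- universe %in% pathway
  n_ge <- withr::with_seed(as.integer(rng_seed), {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (sum(member[sample.int(U, n)]) >= obs) hits <- hits + 1L
    }
    hits
  })
  p_emp <- (n_ge + 1) / (n_perm + 1)
  data.frame(pathway_size = length(pathway), target_list_size = n,
             observed_overlap = obs, n_perm = as.integer(n_perm),
             n_ge = n_ge, p_empirical = p_emp,
             p_hypergeometric = hypergeometric_pvalue(U, length(pathway), n, obs),
             significant = p_emp < cutoff,
             stringsAsFactors = FALSE)
}

#' Permutation enrichment over a whole gene-set collection
#'
#' One [permutation_pvalue()] per pathway, each on a deterministic
#' per-pathway substream derived from `rng_seed` (so results do not depend
#' on pathway order). Results sorted by empirical p-value, then name. A
#' Benjamini-Hochberg adjusted column can be added on request; the default
#' applies the raw per-pathway cutoff.
#'
#' @param targets target gene list.
#' @param sets named list of pathway gene sets.
#' @param universe expressed-gene universe.
#' @param n_perm permutations per pathway (default 9999).
#' @param cutoff significance cutoff (default 0.01).
#' @param rng_seed integer root seed.
#' @param bh add a `p_bh` Benjamini-Hochberg column (default `FALSE`).
#' @return data.frame, one row per pathway.
#' @export
enrich_all <- function(targets, sets, universe, n_perm = 9999L, cutoff = 0.01,
                       rng_seed = 1L, bh = FALSE) {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  rows <- lapply(names(sets), function(nm) {
    res <- permutation_pvalue(targets, sets[[nm]], universe, n_perm = n_perm,
                              rng_seed = derive_seed(rng_seed, nm),
                              cutoff = cutoff)
    cbind(pathway = nm, res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- stats::p.adjust(out$p_empirical, method = "BH")
  out <- out[order(out$p_empirical, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
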