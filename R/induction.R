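#' Reference-normalize expression and fold over the naive group
#'
#' Each raw value is divided by its sample's reference-feature value
#' (default `snoRNA-202`, with `RNU58` accepted as an alias), then by the
#' feature's naive-group mean of reference-normalized values, giving
#' fold-changes relative to the naive condition. By construction each
#' feature's naive-group mean fold-change is 1, and any per-sample scaling
#' of the raw values cancels.
#'
#' @param expression long data.frame: `feature`, `group`, `replicate`,
#'   `value` (nonnegative), containing the reference feature in every
#'   sample and a `naive` group.
#' @param reference reference feature name.
#' @return long data.frame `feature`, `group`, `replicate`, `fold`
#'   (reference feature removed).
#' @export
normalize_and_fold <- function(expression, reference = "snoRNA-202") {
  stopifnot(all(c("feature", "group", "replicate", "value") %in%
                  names(expression)))
  feats <- unique(expression$feature)
  if (!reference %in% feats) {
    alias <- c("snoRNA-202", "RNU58")
    hit <- intersect(alias, feats)
    if (length(hit) == 0) {
      stop("reference feature '", reference, "' not found in the table")
    }
    reference <- hit[1]
  }
  if (!"naive" %in% expression$group) stop("no 'naive' group in the table")
  sample_id <- paste(expression$group, expression$replicate, sep = ":")
  ref_rows <- expression$feature == reference
  ref <- expression$value[ref_rows]
  names(ref) <- sample_id[ref_rows]
  missing <- setdiff(unique(sample_id), names(ref))
  if (length(missing)) {
    stop("reference feature absent in sample(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    bad <- names(ref)[!is.finite(ref) | ref <= 0]
    stop("nonpositive reference value in sample(s): ",
         paste(bad, collapse = ", "))
  }
  df <- expression[!ref_rows, , drop = FALSE]
  refnorm <- df$value / ref[paste(df$group, df$replicate, sep = ":")]
  naive_mean <- tapply(refnorm[df$group == "naive"],
                       df$feature[df$group == "naive"], mean)
  if (!all(unique(df$feature) %in% names(naive_mean))) {
    stop("features missing from the naive group")
  }
  out <- data.frame(feature = df$feature, group = df$group,
                    replicate = df$replicate,
                    fold = unname(refnorm / naive_mean[df$feature]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Replicate-wise induction filter
#'
#' A feature is induced when its trained-group fold-change is at least
#' `theta` in every replicate (the all-replicates reading of "at least
#' 1.5-fold up-regulation in three biological replicates"); `n_required`
#' relaxes this to any `n_required` replicates.
#'
#' @param fc fold-change table from [normalize_and_fold()].
#' @param theta fold threshold, boundary inclusive (default 1.5).
#' @param n_required replicates required at or above `theta`; default all
#'   trained replicates.
#' @return named logical vector over features.
#' @export
detect_induced <- function(fc, theta = 1.5, n_required = NULL) {
  stopifnot(all(c("feature", "group", "fold") %in% names(fc)))
  tr <- fc[fc$group == "trained", , drop = FALSE]
  if (nrow(tr) == 0) stop("no 'trained' group in the fold-change table")
  pass <- tapply(tr$fold >= theta, tr$feature, sum)
  total <- tapply(tr$fold, tr$feature, length)
  need <- if (is.null(n_required)) total else pmin(n_required, total)
  res <- pass >= need
  stats::setNames(as.logical(res), names(res))[unique(tr$feature)]
}

# Welch two-sample two-tailed p-value on log fold-changes, guarded against
# zero-variance (noiseless) groups where t.test is undefined.
welch_log_p <- function(x, y, eps = 1e-12) {
  lx <- log(x)
  ly <- log(y)
  if (stats::var(lx) + stats::var(ly) < eps^2) {
    return(if (abs(mean(lx) - mean(ly)) < eps) 1 else 0)
  }
  stats::t.test(lx, ly, var.equal = FALSE)$p.value
}

#' Assign induction classes from grouped fold-changes
#'
#' Applies the induction filter, then per induced feature runs two-tailed
#' unequal-variance (Welch) tests on log fold-changes - trained vs naive,
#' immediate vs naive, trained vs immediate - and assigns:
#' Class I (induced only with learning): trained significant, immediate
#' not; Class II: both significant with a significant trained-over-
#' immediate increment; Class III: both significant, no trained-vs-
#' immediate difference; otherwise unclassified. Group summaries are
#' geometric means (fold-changes are ratios).
#'
#' @param fc fold-change table from [normalize_and_fold()]; all three
#'   groups with at least two replicates each.
#' @param alpha significance level (default 0.05).
#' @param theta induction fold threshold (default 1.5).
#' @param n_required see [detect_induced()].
#' @return data.frame, one row per feature: `feature`, `fold_immediate`,
#'   `fold_trained`, `p_trained_vs_naive`, `p_immediate_vs_naive`,
#'   `p_trained_vs_immediate`, `induced`, `class`.
#' @export
classify_induction <- function(fc, alpha = 0.05, theta = 1.5,
                               n_required = NULL) {
  stopifnot(all(c("feature", "group", "replicate", "fold") %in% names(fc)))
  need <- c("naive", "immediate", "trained")
  if (!all(need %in% fc$group)) {
    stop("missing group(s): ", paste(setdiff(need, fc$group), collapse = ", "))
  }
  counts <- table(fc$feature, fc$group)
  if (any(counts[, need] < 2)) {
    stop("fewer than 2 replicates in a group; cannot test")
  }
  induced <- detect_induced(fc, theta = theta, n_required = n_required)
  feats <- unique(fc$feature)
  gmean <- function(x) exp(mean(log(x)))
  rows <- lapply(feats, function(f) {
    g <- function(grp) fc$fold[fc$feature == f & fc$group == grp]
    p_tn <- welch_log_p(g("trained"), g("naive"))
    p_in <- welch_log_p(g("immediate"), g("naive"))
    p_ti <- welch_log_p(g("trained"), g("immediate"))
    fi <- gmean(g("immediate"))
    ft <- gmean(g("trained"))
    cls <- "unclassified"
    if (induced[[f]]) {
      t_sig <- p_tn < alpha
      i_sig <- p_in < alpha
      ti_sig <- p_ti < alpha
      if (t_sig && !i_sig) {
        cls <- "I"
      } else if (t_sig && i_sig && ti_sig && ft > fi) {
        cls <- "II"
      } else if (t_sig && i_sig && !ti_sig) {
        cls <- "III"
      }
    }
    data.frame(feature = f, fold_immediate = fi, fold_trained = ft,
               p_trained_vs_naive = p_tn, p_immediate_vs_naive = p_in,
               p_trained_vs_immediate = p_ti, induced = induced[[f]],
               class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
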