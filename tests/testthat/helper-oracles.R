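# Independent oracles used across the suite. All deliberately reimplement
# the checked computation from first principles (pure character loops,
# exhaustive enumeration, textbook formulas) and share no code with R/.

oracle_comp <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp <- function(x) {
  chars <- strsplit(chartr("Uu", "Tt", toupper(x)), "")[[1]]
  paste(rev(unname(oracle_comp[chars])), collapse = "")
}

# Exhaustive per-offset seed-site scan: every 0-based offset is tested for
# a 6mer core by direct substring equality, then the full 8mer / 7mer-m8 /
# 7mer-A1 patterns are tested at that locus and the strongest one reported.
oracle_scan <- function(mirna, utr, min_class = "6mer") {
  u <- chartr("Uu", "Tt", toupper(utr))
  m <- chartr("Uu", "Tt", toupper(mirna))
  s7 <- oracle_revcomp(substr(m, 2, 8))
  s6 <- oracle_revcomp(substr(m, 2, 7))
  p8 <- paste0(s7, "A")
  pa1 <- paste0(s6, "A")
  n <- nchar(u)
  rows <- list()
  if (n >= 6) {
    for (c0 in 0:(n - 6)) {
      if (substr(u, c0 + 1, c0 + 6) != s6) next
      if (c0 >= 1 && c0 + 8 <= n && substr(u, c0, c0 + 7) == p8) {
        rows[[length(rows) + 1]] <- list("8mer", c0 - 1, c0 + 7)
      } else if (c0 >= 1 && substr(u, c0, c0 + 6) == s7) {
        rows[[length(rows) + 1]] <- list("7mer-m8", c0 - 1, c0 + 6)
      } else if (c0 + 7 <= n && substr(u, c0 + 1, c0 + 7) == pa1) {
        rows[[length(rows) + 1]] <- list("7mer-A1", c0, c0 + 7)
      } else {
        rows[[length(rows) + 1]] <- list("6mer", c0, c0 + 6)
      }
    }
  }
  df <- data.frame(
    site_class = vapply(rows, function(r) r[[1]], character(1)),
    start = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
    end = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    stringsAsFactors = FALSE)
  keep_rank <- match(df$site_class, c("6mer", "7mer-A1", "7mer-m8", "8mer")) >=
    match(min_class, c("6mer", "7mer-A1", "7mer-m8", "8mer"))
  df <- df[keep_rank, , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Exhaustive hypergeometric upper tail: enumerate all size-n subsets of
# 1..U (pathway = 1..K) and count overlaps >= observed.
oracle_hyper_enum <- function(U, K, n, observed) {
  subsets <- utils::combn(U, n)
  mean(apply(subsets, 2, function(s) sum(s <= K)) >= observed)
}

# Textbook product-moment correlation from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Mid-ranks by hand, then the product-moment formula on ranks.
oracle_midrank <- function(x) {
  vapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2, numeric(1))
}
oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# Welch two-sample two-tailed p-value from the textbook statistic.
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(t), df)
}

# Long-format fold-change table from per-group replicate vectors.
make_fc <- function(feature, naive, immediate, trained) {
  data.frame(
    feature = feature,
    group = rep(c("naive", "immediate", "trained"),
                times = c(length(naive), length(immediate), length(trained))),
    replicate = c(seq_along(naive), seq_along(immediate), seq_along(trained)),
    fold = c(naive, immediate, trained),
    stringsAsFactors = FALSE)
}

# Random RNA / DNA sequences for fixtures.
rand_seq <- function(len, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
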