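#' Canonical seed-site classes, weakest to strongest
#'
#' Site efficacy order used throughout: `6mer < 7mer-A1 < 7mer-m8 < 8mer`.
#'
#' @format Character vector of length four.
#' @export
SITE_CLASSES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Rank of a site class (1 = weakest)
#' @param site_class character vector of class labels.
#' @return integer ranks.
#' @export
site_class_rank <- function(site_class) {
  r <- match(site_class, SITE_CLASSES)
  if (anyNA(r)) {
    stop("unknown site class: ", paste(unique(site_class[is.na(r)]), collapse = ", "))
  }
  r
}

# Normalize a nucleotide string to upper-case DNA (U -> T).
norm_dna <- function(x) chartr("Uu", "Tt", toupper(x))

# Reverse complement of a DNA string (scalar).
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

assert_alphabet <- function(seqs, alphabet, what = "sequence") {
  pat <- sprintf("^[%s]+$", paste(alphabet, collapse = ""))
  bad <- !grepl(pat, seqs)
  if (any(bad)) {
    nm <- names(seqs)[bad]
    if (is.null(nm)) nm <- which(bad)
    stop("illegal characters in ", what, ": ", paste(utils::head(nm, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Derive a labeled RNG substream seed
#'
#' Stable hash of a root seed and a stage label, so that adding or reordering
#' pipeline stages never silently reshuffles another stage's randomness.
#' Result is always a valid 32-bit integer seed.
#'
#' @param seed integer root seed.
#' @param label character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- sum(utf8ToInt(label) * (seq_len(nchar(label)) %% 97 + 1))
  as.integer((abs(seed) * 48271 + h * 16807 + 7) %% 2147483647L)
}

# Generate n random sequences of length len over the alphabet (uses the
# current RNG stream; callers are responsible for seeding).
random_seqs <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(alphabet, n * len, replace = TRUE), nrow = len)
  apply(m, 2, paste, collapse = "")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
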