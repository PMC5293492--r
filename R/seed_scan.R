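#' Seed of a mature miRNA
#'
#' The seed is the 7-nt stretch at miRNA positions 2-8 (1-based, 5'->3'),
#' the region whose Watson-Crick complementarity to a 3'UTR drives canonical
#' target recognition.
#'
#' @param mirna a mature miRNA sequence (character scalar, `A/C/G/U`,
#'   length >= 8).
#' @return 7-nt seed string.
#' @examples
#' seed_of("UAGCAGCAA")  # "AGCAGCA"
#' @export
seed_of <- function(mirna) {
  stopifnot(is.character(mirna), length(mirna) == 1)
  if (nchar(mirna) < 8) {
    stop("miRNA shorter than 8 nt: cannot extract seed (positions 2-8)")
  }
  substr(mirna, 2, 8)
}

# Seed-match patterns for one miRNA, in UTR (DNA, 5'->3') space.
#   s7 = revcomp(positions 2-8), s6 = revcomp(positions 2-7) = s7[2..7].
# Site definitions on the UTR:
#   8mer    = s7 followed by A
#   7mer-m8 = s7
#   7mer-A1 = s6 followed by A
#   6mer    = s6
seed_patterns <- function(mirna) {
  seed <- norm_dna(seed_of(mirna))
  s7 <- revcomp_dna(seed)
  list(s7 = s7, s6 = substr(s7, 2, 7), m8_char = substr(s7, 1, 1))
}

# Classify every 6mer-core occurrence (1-based core starts p) in one UTR
# string and return 0-based half-open site coordinates with the strongest
# class at each locus (an 8mer locus is never additionally reported as its
# nested weaker classes).
classify_cores <- function(utr, p, pat) {
  n <- nchar(utr)
  left_ok <- p > 1L & substring(utr, p - 1L, p - 1L) == pat$m8_char
  right_ok <- p + 6L <= n & substring(utr, p + 6L, p + 6L) == "A"
  cls <- ifelse(left_ok & right_ok, "8mer",
         ifelse(left_ok, "7mer-m8",
         ifelse(right_ok, "7mer-A1", "6mer")))
  start <- ifelse(left_ok, p - 2L, p - 1L)        # 0-based
  end <- ifelse(right_ok, p + 6L, p + 5L)         # half-open
  data.frame(site_class = cls, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Find canonical seed-match sites of one miRNA in one UTR
#'
#' Scans the UTR (read 5'->3') for the four canonical site classes and
#' reports, at each 6mer-core locus, the strongest class present
#' (`8mer > 7mer-m8 > 7mer-A1 > 6mer`). The target-position-1 `A` of
#' 8mer/7mer-A1 sites must literally be an `A` in the UTR. `U` and `T` are
#' treated as equivalent on both sides. Coordinates are 0-based half-open
#' on the UTR.
#'
#' @param mirna mature miRNA sequence (character scalar, length >= 8).
#' @param utr UTR sequence (character scalar, `A/C/G/T` or `A/C/G/U`);
#'   may be named by its gene symbol.
#' @param min_class weakest class to report (default `"6mer"`).
#' @param mirna_id,gene optional labels for the output table; default to the
#'   input names.
#' @return data.frame with columns `gene`, `mirna`, `site_class`, `start`,
#'   `end`, ordered by `start`.
#' @examples
#' find_seed_sites("UAGCAGCAA", c(g1 = "AAAATGCTGCTAAAAA"))
#' @export
find_seed_sites <- function(mirna, utr, min_class = "6mer",
                            mirna_id = NULL, gene = NULL) {
  stopifnot(length(utr) == 1)
  mirna_id <- mirna_id %||% names(mirna) %||% "mirna"
  gene <- gene %||% names(utr) %||% "utr"
  empty <- data.frame(gene = character(0), mirna = character(0),
                      site_class = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (!nzchar(utr)) return(empty)
  assert_alphabet(stats::setNames(utr, gene), c("A", "C", "G", "T", "U"),
                  "UTR record")
  assert_alphabet(stats::setNames(mirna, mirna_id), c("A", "C", "G", "U", "T"),
                  "miRNA record")
  pat <- seed_patterns(mirna)
  utr_dna <- norm_dna(utr)
  hits <- Biostrings::matchPattern(pat$s6, Biostrings::DNAString(utr_dna))
  p <- Biostrings::start(hits)
  if (length(p) == 0L) return(empty)
  sites <- classify_cores(utr_dna, p, pat)
  sites <- cbind(gene = gene, mirna = mirna_id, sites, stringsAsFactors = FALSE)
  sites <- sites[site_class_rank(sites$site_class) >= site_class_rank(min_class), ,
                 drop = FALSE]
  sites <- sites[order(sites$start, sites$end), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Scan a UTR collection with a panel of miRNAs
#'
#' Vectorized batch form of [find_seed_sites()]: all (miRNA, UTR) pairs,
#' one site table out.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param utrs named character vector of UTR sequences (names = gene
#'   symbols, unique).
#' @param min_class weakest class to report (default `"7mer-A1"`, i.e.
#'   7mer-or-stronger, the working definition of a binding site downstream).
#' @return data.frame `gene`, `mirna`, `site_class`, `start`, `end`.
#' @export
scan_sites <- function(mirnas, utrs, min_class = "7mer-A1") {
  stopifnot(length(mirnas) > 0, length(utrs) > 0,
            !is.null(names(mirnas)), !is.null(names(utrs)))
  if (anyDuplicated(names(utrs))) {
    stop("duplicate gene symbols in UTR collection: ",
         paste(unique(names(utrs)[duplicated(names(utrs))]), collapse = ", "))
  }
  assert_alphabet(utrs, c("A", "C", "G", "T", "U"), "UTR record")
  assert_alphabet(mirnas, c("A", "C", "G", "U", "T"), "miRNA record")
  utr_dna <- norm_dna(utrs)
  subject <- Biostrings::DNAStringSet(utr_dna)
  out <- vector("list", length(mirnas))
  for (i in seq_along(mirnas)) {
    pat <- seed_patterns(mirnas[[i]])
    m <- Biostrings::vmatchPattern(pat$s6, subject)
    starts <- Biostrings::startIndex(m)
    nhit <- lengths(starts)
    if (sum(nhit) == 0L) next
    gene_idx <- rep.int(seq_along(utrs), nhit)
    p <- unlist(starts, use.names = FALSE)
    sites <- classify_cores(utr_dna[gene_idx], p, pat)
    out[[i]] <- cbind(gene = names(utrs)[gene_idx],
                      mirna = names(mirnas)[i],
                      sites, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(gene = character(0), mirna = character(0),
                      site_class = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  sites <- do.call(rbind, out)
  sites <- sites[site_class_rank(sites$site_class) >= site_class_rank(min_class), ,
                 drop = FALSE]
  sites <- sites[order(match(sites$gene, names(utrs)),
                       match(sites$mirna, names(mirnas)),
                       sites$start, sites$end), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Does a miRNA target a UTR?
#'
#' Predicate form of [find_seed_sites()]: `TRUE` iff at least one site of
#' class `>= min_class` is present.
#'
#' @inheritParams find_seed_sites
#' @return logical scalar.
#' @export
is_target <- function(mirna, utr, min_class = "7mer-A1") {
  nrow(find_seed_sites(mirna, utr, min_class)) > 0
}

#' Mutate the target-side pairing of miRNA seed positions 4-6 to ATT
#'
#' In-silico analogue of site-directed mutagenesis of a reporter 3'UTR: the
#' three UTR nucleotides that pair (antiparallel) with seed positions 4-6
#' are replaced by `ATT`. For every site class these are the 2nd-4th
#' nucleotides of the 6mer core. The operator guarantees abolition: if the
#' site was not produced by scanning this UTR, or the replacement leaves or
#' coincidentally recreates any site of class >= 6mer overlapping the
#' original locus, it fails rather than return a still-functional UTR.
#'
#' @param mirna the targeting miRNA sequence (character scalar).
#' @param utr the UTR (character scalar, may be named).
#' @param site one row of a site table from [find_seed_sites()] /
#'   [scan_sites()] (needs `site_class`, `start`, `end`).
#' @return the mutated UTR, same name as the input.
#' @export
mutate_seed_region <- function(mirna, utr, site) {
  stopifnot(length(utr) == 1)
  site <- as.list(site)
  existing <- find_seed_sites(mirna, utr, min_class = "6mer")
  hit <- existing$site_class == site$site_class &
    existing$start == site$start & existing$end == site$end
  if (!any(hit)) {
    stop("site ", site$site_class, " [", site$start, ",", site$end,
         ") not found in UTR '", names(utr) %||% "utr", "'")
  }
  # 0-based start of the 6mer core within the site.
  core0 <- site$start + if (site$site_class %in% c("8mer", "7mer-m8")) 1L else 0L
  mutated <- utr
  substr(mutated, core0 + 2L, core0 + 4L) <- "ATT"
  residual <- find_seed_sites(mirna, mutated, min_class = "6mer")
  overlapping <- residual$start < site$end & residual$end > site$start
  if (any(overlapping)) {
    stop("ATT replacement failed to abolish the site at [", site$start, ",",
         site$end, "): a >=6mer site still overlaps the locus")
  }
  mutated
}
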