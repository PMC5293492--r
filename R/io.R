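#' Read a FASTA file of nucleotide sequences
#'
#' Record ids are the first whitespace-delimited token of each header; mixed
#' case is accepted and normalized to upper case. Duplicate ids, empty
#' sequences and characters outside `A/C/G/T/U` are errors naming the record.
#'
#' @param path file path.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  assert_alphabet(seqs, c("A", "C", "G", "T", "U"), "FASTA record")
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, member genes. Member symbols
#' are upper-cased on ingest; duplicate members within a line are collapsed
#' with a warning; duplicate set names or empty member lists are errors.
#'
#' @param path GMT file path.
#' @return named list of character vectors (gene symbol sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set names: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  sets <- lapply(seq_along(parts), function(i) {
    members <- parts[[i]][-(1:2)]
    members <- toupper(members[nzchar(members)])
    if (length(members) == 0L) {
      stop("gene set '", names_[i], "' has no members")
    }
    if (anyDuplicated(members)) {
      warning("gene set '", names_[i], "' has duplicated members; collapsing")
      members <- unique(members)
    }
    members
  })
  names(sets) <- names_
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-symbol-per-line gene list
#' @param path file path.
#' @return character vector of unique upper-case symbols.
#' @export
read_gene_list <- function(path) {
  x <- toupper(trimws(readLines(path)))
  unique(x[nzchar(x)])
}

#' Write a gene list, one symbol per line
#' @param genes character vector.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

# TSV with "#" comment header lines carrying provenance.
write_tsv <- function(df, path, header = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by this package (comment lines starting with '#')
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
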