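## 6-mer miRNA seed extraction and perfect-complement site search.

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U, then checks the alphabet, so DNA FASTA
#' inputs work transparently.
#'
#' @param x character vector of sequences.
#' @return sequences over `{A, C, G, U}`.
#' @export
rna_normalize <- function(x) {
  y <- chartr("tT", "uU", x)
  y <- toupper(y)
  bad <- grepl("[^ACGU]", y)
  stop_if(any(bad), "invalid nucleotide characters in sequence(s): %s",
          paste(utils::head(which(bad), 3), collapse = ", "))
  y
}

#' Reverse complement in RNA space
#'
#' Watson-Crick only (A<->U, C<->G); no G:U wobble.
#'
#' @param x RNA sequence(s), 5'->3'.
#' @return the reverse complement(s), 5'->3'.
#' @export
rna_reverse_complement <- function(x) {
  comp <- chartr("ACGU", "UGCA", rna_normalize(x))
  vapply(strsplit(comp, "", fixed = TRUE), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

#' Extract the 6-mer seed of a mature miRNA
#'
#' Positions 2-7 from the 5' end of the mature sequence: the minimal
#' pairing region considered predictive for target recognition.
#'
#' @param mirna_seq mature miRNA sequence(s), 5'->3', length >= 7.
#' @return the 6-nt seed(s).
#' @export
#' @examples
#' seed_of("AUGGCUAAGCG") # "UGGCUA"
seed_of <- function(mirna_seq) {
  s <- rna_normalize(mirna_seq)
  stop_if(any(nchar(s) < 7), "mature miRNA sequence must be at least 7 nt")
  substr(s, 2L, 7L)
}

#' Find perfect 6-mer seed-match sites in a target transcript
#'
#' Searches the target (sense strand, 5'->3') for every occurrence —
#' including overlapping ones — of the reverse complement of the miRNA's
#' seed. A perfect Watson-Crick match is required.
#'
#' @param mirna_seq mature miRNA sequence, 5'->3'.
#' @param target_seq target transcript sequence (RNA or DNA alphabet).
#' @return list with `site` (the 6-nt target substring searched for) and
#'   `positions` (strictly increasing 0-based start offsets; empty integer
#'   vector when there is no match).
#' @export
#' @examples
#' find_seed_matches("AUGGCUAAGCG", "GGGUAGCCAGG") # site UAGCCA at 3
find_seed_matches <- function(mirna_seq, target_seq) {
  target <- rna_normalize(target_seq)
  stop_if(!nzchar(target), "empty target sequence")
  site <- rna_reverse_complement(seed_of(mirna_seq))
  L <- nchar(target)
  if (L < 6L) return(list(site = site, positions = integer(0)))
  starts <- seq_len(L - 6L + 1L)
  hit <- substring(target, starts, starts + 5L) == site
  list(site = site, positions = as.integer(starts[hit] - 1L))
}

#' Does a target carry at least one seed match for a miRNA?
#'
#' @inheritParams find_seed_matches
#' @return `TRUE` iff [find_seed_matches()] finds at least one site.
#' @export
has_seed_match <- function(mirna_seq, target_seq) {
  length(find_seed_matches(mirna_seq, target_seq)$positions) > 0
}

#' Read / write sequences as FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as named character
#' vectors in the RNA alphabet.
#'
#' @param path FASTA file path.
#' @return `read_fasta` returns a named character vector of normalized RNA
#'   sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  rna_normalize(stats::setNames(as.character(ss), names(ss)))
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(NULL)
}
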