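# FASTA I/O thin wrappers (Biostrings-backed).

#' Read sequences or an alignment from FASTA
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
  else Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::AAStringSet(seqs)
  else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
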