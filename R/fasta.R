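#' Read a FASTA file into a sequence tibble
#'
#' Sequences travel through plasmidr as tibbles with one row per record and
#' columns `id` (the first whitespace-delimited token of the FASTA header)
#' and `seq` (uppercase DNA string). Plain and gzip-compressed FASTA are
#' accepted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    id = sub("\\s.*$", "", names(ss)),
    seq = unname(toupper(as.character(ss)))
  )
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id`, `seq`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  ss <- Biostrings::DNAStringSet(seqs$seq)
  names(ss) <- seqs$id
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  vapply(x, cpp_revcomp, "", USE.NAMES = FALSE)
}
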