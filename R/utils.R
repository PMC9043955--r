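DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character sequences
#'
#' @param x character vector of DNA sequences over {A,C,G,T,N}.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

#' Random DNA sequence with a target GC fraction
#'
#' Draws bases i.i.d. with P(G) = P(C) = gc/2. Uses the current RNG state;
#' callers are expected to seed.
#'
#' @param n sequence length (bp).
#' @param gc target GC fraction in [0, 1].
#' @return a single character string.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# scalar reverse complement without Biostrings overhead (hot loops)
rc1 <- function(s) rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", s))))

# deterministic sub-seed derivation; keeps values < 2^31
derive_seed <- function(seed, salt) {
  (as.numeric(seed) * 7919 + salt * 104729) %% 2147483647
}

# validate a sequence over a restricted alphabet; returns offending position or 0
first_invalid_pos <- function(seq, alphabet = c("A", "C", "G", "T")) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) bad[1] else 0L
}

# split a string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# all substrings of length w (character vector), 1-based sliding windows
seq_windows <- function(x, w) {
  n <- nchar(x)
  if (n < w) return(character(0))
  substring(x, seq_len(n - w + 1), seq_len(n - w + 1) + w - 1)
}

# rotate a string left by r positions
rotate_seq <- function(x, r) {
  n <- nchar(x)
  r <- r %% n
  if (r == 0) return(x)
  paste0(substr(x, r + 1, n), substr(x, 1, r))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path input file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), names(x))
}
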