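#' Scoring and masking options for pairwise IGS similarity
#'
#' Long deletions (> `long_indel_threshold` bp) can be excluded from the
#' identity calculation: when `mask_long_indels` is on, gap runs longer
#' than the threshold are removed from both numerator and denominator, so
#' a single long indel does not swamp the point-mutation signal.
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores (penalties
#'   as negative numbers).
#' @param long_indel_threshold gap-run length (bp) above which a run is
#'   maskable.
#' @param mask_long_indels mask long gap runs before computing identity.
#' @param identity_denominator "alignment_length" (default; matches the
#'   common "similarity" usage) or "ungapped_columns".
#' @export
similarity_options <- function(match = 1, mismatch = -1, gap_open = -2,
                               gap_extend = -0.5, long_indel_threshold = 5L,
                               mask_long_indels = FALSE,
                               identity_denominator = c("alignment_length",
                                                        "ungapped_columns")) {
  if (long_indel_threshold < 1) stop("long_indel_threshold must be >= 1")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 long_indel_threshold = as.integer(long_indel_threshold),
                 mask_long_indels = isTRUE(mask_long_indels),
                 identity_denominator = match.arg(identity_denominator)),
            class = "similarity_options")
}

#' GC content of a sequence
#'
#' (G + C) / (A + C + G + T); N bases are excluded from numerator and
#' denominator.
#'
#' @param seq a DNA sequence over {A,C,G,T,N}.
#' @param percent return percent (default) instead of a fraction.
#' @return GC content, as percent rounded to 1 decimal when
#'   `percent = TRUE`.
#' @export
gc_content <- function(seq, percent = TRUE) {
  if (!nchar(seq)) stop("empty sequence")
  bad <- first_invalid_pos(seq, c("A", "C", "G", "T", "N"))
  if (bad > 0) stop("invalid base at position ", bad)
  chars <- seq_chars(seq)
  acgt <- sum(chars != "N")
  if (acgt == 0) stop("sequence contains only N")
  frac <- sum(chars %in% c("G", "C")) / acgt
  if (percent) round(100 * frac, 1) else frac
}

# align two sequences under similarity_options, return gapped rows
align_pair <- function(a, b, opts = similarity_options()) {
  align_global(a, b, match = opts$match, mismatch = opts$mismatch,
               gap_open = -opts$gap_open, gap_ext = -opts$gap_extend)
}

# identity from two gapped rows under the options' masking/denominator
identity_from_alignment <- function(qa, qb, opts = similarity_options()) {
  ca <- seq_chars(qa)
  cb <- seq_chars(qb)
  if (opts$mask_long_indels) {
    gaps <- ca == "-" | cb == "-"
    r <- rle(gaps)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    drop <- unlist(mapply(function(s, e, v, l) {
      if (v && l > opts$long_indel_threshold) s:e else integer(0)
    }, starts, ends, r$values, r$lengths, SIMPLIFY = FALSE))
    if (length(drop)) {
      ca <- ca[-drop]
      cb <- cb[-drop]
    }
  }
  matched <- sum(ca == cb & ca != "-")
  denom <- switch(opts$identity_denominator,
                  alignment_length = length(ca),
                  ungapped_columns = sum(ca != "-" & cb != "-"))
  if (denom == 0) return(NA_real_)
  100 * matched / denom
}

#' Percent identity of two sequences under global alignment
#'
#' @param a,b sequences.
#' @param opts a [similarity_options()].
#' @return percent identity (0-100).
#' @export
pairwise_identity <- function(a, b, opts = similarity_options()) {
  if (!nchar(a) || !nchar(b)) stop("sequences must be nonempty")
  if (a == b) return(100)
  al <- align_pair(a, b, opts)
  identity_from_alignment(al$a, al$b, opts)
}

#' Intragenomic similarity range over a catalog of sequences
#'
#' @param seqs character vector (>= 2) of IGS sequences, or a
#'   `ribotype_catalog`.
#' @param opts a [similarity_options()].
#' @return a list: `min`, `max` (percent), and the full symmetric `matrix`.
#'   With fewer than two sequences, min and max are NA.
#' @export
similarity_range <- function(seqs, opts = similarity_options()) {
  if (inherits(seqs, "ribotype_catalog")) seqs <- seqs$catalog$igs_seq
  n <- length(seqs)
  if (n < 2) {
    warning("similarity range undefined for fewer than 2 sequences")
    return(list(min = NA_real_, max = NA_real_, matrix = NULL))
  }
  m <- diag(100, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- pairwise_identity(seqs[i], seqs[j], opts)
    }
  }
  off <- m[upper.tri(m)]
  list(min = min(off), max = max(off), matrix = m)
}

#' Substitution divergence of a CDS copy from the consensus
#'
#' Counts substitution columns of the global alignment; indels are listed
#' separately, not counted as substitutions.
#'
#' @param cds_seq CDS copy.
#' @param consensus consensus CDS.
#' @return a list: `n_substitutions`, `indels` (data.frame).
#' @export
cds_divergence <- function(cds_seq, consensus) {
  al <- align_global(cds_seq, consensus)
  mut <- alignment_mutations(al$a, al$b)
  list(n_substitutions = length(mut$substitution_columns),
       indels = mut$indels)
}
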