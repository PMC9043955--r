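#' Detect an internal tandem duplication within a repeat unit
#'
#' Self-comparison by seed-and-extend: shared >= `seed_k`-mers at distinct
#' positions vote for a duplication period; the leftmost seed of the
#' best-supported period anchors the first copy, whose extent is the
#' period itself; the second (and any further) copy is located by gapped
#' global-local alignment of the first copy against the immediately
#' following sequence. The search runs on the full unit (CDS + IGS)
#' because long spacer duplications can span the CDS 3' end. The trivial
#' self-match (offset 0) is excluded and copies must be adjacent
#' (gap <= 5 bp).
#'
#' @param unit_seq repeat-unit sequence (CDS-sense).
#' @param min_unit smallest duplication unit considered (bp, >= 10).
#' @param max_divergence maximum fraction of diverged columns between
#'   copies.
#' @param cds_length optional CDS length within the unit; when given, the
#'   call reports how much of the duplicated unit derives from the CDS
#'   versus the IGS.
#' @param seed_k seed k-mer length for the self-comparison.
#' @return a list of class `duplication_call` (unit_length, n_copies,
#'   copy_spans, snps_between_copies, indels_between_copies,
#'   cds_derived_length, igs_derived_length), or `NULL` when no adequate
#'   duplication exists.
#' @export
find_tandem_duplication <- function(unit_seq, min_unit = 30L,
                                    max_divergence = 0.2,
                                    cds_length = NULL, seed_k = 15L) {
  if (min_unit < 10L) stop("min_unit must be >= 10")
  n <- nchar(unit_seq)
  if (n < 2L * min_unit) return(NULL)
  wins <- seq_windows(unit_seq, seed_k)
  pos_by_kmer <- split(seq_along(wins), wins)
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) > 1L]
  if (!length(pos_by_kmer)) return(NULL)
  pairs <- do.call(rbind, lapply(pos_by_kmer, function(p) {
    if (length(p) > 8L) p <- p[seq_len(8L)]   # guard vs low-complexity seeds
    t(utils::combn(p, 2L))
  }))
  offs <- pairs[, 2L] - pairs[, 1L]
  keep <- offs >= min_unit
  if (!any(keep)) return(NULL)
  pairs <- pairs[keep, , drop = FALSE]
  offs <- offs[keep]

  # cluster offsets (indels between copies shift downstream seeds)
  ord <- order(offs)
  offs_s <- offs[ord]
  cluster <- cumsum(c(1L, diff(offs_s) > 20L))
  support <- tabulate(cluster)
  best_cl <- which.max(support)
  members <- ord[cluster == best_cl]
  # the period is the offset of the earliest seed pair in the cluster
  first <- members[which.min(pairs[members, 1L])]
  s1 <- pairs[first, 1L]
  period <- offs[first]

  # maximal left extension of the repeat phase, tolerating isolated
  # substitutions between the copies: stopping at the first mismatch would
  # rotate the phase whenever a copy carries a SNP near its start
  while (s1 > 1L) {
    if (substr(unit_seq, s1 - 1L, s1 - 1L) ==
        substr(unit_seq, s1 - 1L + period, s1 - 1L + period)) {
      s1 <- s1 - 1L
      next
    }
    peek_lo <- max(1L, s1 - 15L)
    if (s1 - peek_lo < 6L) break
    w1 <- seq_chars(substr(unit_seq, peek_lo, s1 - 1L))
    w2 <- seq_chars(substr(unit_seq, peek_lo + period, s1 - 1L + period))
    if (mean(w1 == w2) >= 0.75) s1 <- s1 - 1L else break
  }
  copy1 <- substr(unit_seq, s1, s1 + period - 1L)
  if (nchar(copy1) < min_unit) return(NULL)

  spans <- list(c(s1 - 1L, s1 + period - 1L))  # 0-based half-open
  snps <- 0L
  indel_lengths <- integer(0)
  cursor <- s1 + period
  n_copies <- 1L
  repeat {
    win_end <- min(n, cursor + period + max(20L, period %/% 4L))
    if (win_end - cursor + 1L < min_unit) break
    window <- substr(unit_seq, cursor, win_end)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(copy1), Biostrings::DNAString(window),
      type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 2, gapExtension = 0.5)
    sstart <- Biostrings::start(Biostrings::subject(pa))
    send <- Biostrings::end(Biostrings::subject(pa))
    if (sstart - 1L > 5L) break          # not adjacent
    qa <- as.character(Biostrings::alignedPattern(pa))
    qb <- as.character(Biostrings::alignedSubject(pa))
    mut <- alignment_mutations(qa, qb)
    div <- (length(mut$substitution_columns) + sum(mut$indels$length)) /
      nchar(copy1)
    if (div > max_divergence) break
    n_copies <- n_copies + 1L
    snps <- snps + length(mut$substitution_columns)
    indel_lengths <- c(indel_lengths, mut$indels$length)
    spans[[length(spans) + 1L]] <- c(cursor + sstart - 2L, cursor + send - 1L)
    cursor <- cursor + send
  }
  if (n_copies < 2L) return(NULL)

  cds_derived <- NA_integer_
  igs_derived <- NA_integer_
  if (!is.null(cds_length)) {
    cds_derived <- max(0L, min(spans[[1]][2], cds_length) - spans[[1]][1])
    igs_derived <- period - cds_derived
  }
  structure(list(
    unit_length = period,
    n_copies = n_copies,
    copy_spans = spans,
    snps_between_copies = snps,
    indels_between_copies = indel_lengths,
    cds_derived_length = cds_derived,
    igs_derived_length = igs_derived
  ), class = "duplication_call")
}

#' @export
print.duplication_call <- function(x, ...) {
  cat(sprintf(
    "tandem duplication: %d-bp unit x %d copies; %d SNP(s), indel(s) [%s] between copies\n",
    x$unit_length, x$n_copies, x$snps_between_copies,
    paste(x$indels_between_copies, collapse = ",")))
  if (!is.na(x$cds_derived_length)) {
    cat(sprintf("  CDS-derived %d bp, IGS-derived %d bp\n",
                x$cds_derived_length, x$igs_derived_length))
  }
  invisible(x)
}
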