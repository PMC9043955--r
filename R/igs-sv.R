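#' Load structural-variant signature definitions
#'
#' Structural variants of the IGS in potato-relative genomes are defined by
#' presence/absence of two group-specific indel segments (I and II) and a
#' GC dinucleotide duplication (GC-DUP) on a reference alignment. The
#' packaged signature set uses a synthetic reference alignment (the
#' original coordinates are not machine-readable); users can supply their
#' own alignment FASTA and YAML with real coordinates.
#'
#' @param yaml_path signature YAML; default: the packaged synthetic set.
#' @return a list of class `sv_signature_set`: `alignment` (named gapped
#'   rows), `segments` (name -> c(start, end) alignment columns, 1-based
#'   inclusive).
#' @export
load_sv_signatures <- function(yaml_path = NULL) {
  if (is.null(yaml_path)) {
    yaml_path <- system.file("extdata", "sv_signatures.yaml",
                             package = "ribomine5s")
  }
  spec <- yaml::read_yaml(yaml_path)
  aln_path <- spec$reference_alignment
  if (!file.exists(aln_path)) {
    aln_path <- file.path(dirname(yaml_path), aln_path)
  }
  aln <- read_fasta(aln_path)
  if (length(unique(nchar(aln))) != 1L) {
    stop("reference alignment rows have unequal lengths")
  }
  segments <- lapply(spec$segments, function(s) c(s$start, s$end))
  # segments must not overlap
  cols <- unlist(lapply(segments, function(s) s[1]:s[2]))
  if (anyDuplicated(cols)) stop("signature segments overlap")
  structure(list(alignment = aln, segments = segments),
            class = "sv_signature_set")
}

#' Structural-variant label from segment presence
#'
#' Decision table: SV-A carries both group-specific indels; SV-B carries
#' indel I but lost indel II; SV-C and SV-D lost indel I and are separated
#' by the GC duplication (absent in C, present in D). Any other
#' combination is unclassified.
#'
#' @param presence named logical vector with elements `indel_I`,
#'   `indel_II`, `GC_DUP`.
#' @return "A", "B", "C", "D" or "unclassified".
#' @export
sv_label <- function(presence) {
  i1 <- isTRUE(presence[["indel_I"]])
  i2 <- isTRUE(presence[["indel_II"]])
  dup <- isTRUE(presence[["GC_DUP"]])
  if (i1 && i2) "A"
  else if (i1 && !i2) "B"
  else if (!i1 && i2 && !dup) "C"
  else if (!i1 && i2 && dup) "D"
  else "unclassified"
}

# For each alignment column covered by `row_gapped`'s bases, does the query
# contribute a base there? Returns logical over all columns (NA where the
# row itself is gapped).
map_query_to_columns <- function(query, row_gapped,
                                 opts = similarity_options()) {
  row_seq <- gsub("-", "", row_gapped, fixed = TRUE)
  al <- align_pair(query, row_seq, opts)
  qa <- seq_chars(al$a)   # query row, gapped
  qb <- seq_chars(al$b)   # reference row, gapped
  row_cols <- which(seq_chars(row_gapped) != "-")  # alignment column of each row base
  ncols <- nchar(row_gapped)
  covered <- rep(NA, ncols)
  ri <- 0L
  for (t in seq_along(qb)) {
    if (qb[t] != "-") {
      ri <- ri + 1L
      covered[row_cols[ri]] <- qa[t] != "-"
    }
  }
  covered
}

#' Classify an IGS sequence into structural variants A-D
#'
#' The query is profile-aligned to the packaged reference alignment (via
#' its closest row); a signature segment is present iff at least 50% of
#' its aligned columns are covered by query bases. Segments whose closest
#' overall row does not itself carry them are assessed against the best
#' row that does, so an inserted segment (e.g. the GC duplication) is not
#' lost as an unmappable insertion.
#'
#' @param igs_seq IGS sequence.
#' @param signatures an `sv_signature_set` from [load_sv_signatures()].
#' @param min_profile_identity reject queries below this percent identity
#'   to every reference row.
#' @return a list of class `sv_call`: `presence` (named logical), `label`,
#'   `best_reference`, `identity`.
#' @export
classify_sv <- function(igs_seq, signatures = load_sv_signatures(),
                        min_profile_identity = 40) {
  aln <- signatures$alignment
  opts <- similarity_options()
  idents <- vapply(aln, function(row) {
    pairwise_identity(igs_seq, gsub("-", "", row, fixed = TRUE), opts)
  }, numeric(1))
  best <- which.max(idents)
  if (idents[best] < min_profile_identity) {
    stop("not a Petota-like IGS: best profile identity ",
         sprintf("%.1f", idents[best]), "% < ", min_profile_identity, "%")
  }
  seg_presence <- vapply(names(signatures$segments), function(nm) {
    cols <- signatures$segments[[nm]]
    cols <- cols[1]:cols[2]
    # rows that themselves carry the segment (>= 50% non-gap there)
    carrier <- vapply(aln, function(row) {
      mean(seq_chars(row)[cols] != "-") >= 0.5
    }, logical(1))
    use <- if (carrier[best]) best else {
      cand <- which(carrier)
      if (!length(cand)) return(FALSE)
      cand[which.max(idents[cand])]
    }
    covered <- map_query_to_columns(igs_seq, aln[[use]], opts)
    vals <- covered[cols]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(FALSE)
    mean(vals) >= 0.5
  }, logical(1))
  structure(list(presence = seg_presence,
                 label = sv_label(seg_presence),
                 best_reference = names(aln)[best],
                 identity = unname(idents[best])),
            class = "sv_call")
}

#' @export
print.sv_call <- function(x, ...) {
  cat(sprintf("SV call: %s (indel I %s, indel II %s, GC-DUP %s; closest %s, %.1f%%)\n",
              x$label,
              ifelse(x$presence[["indel_I"]], "+", "-"),
              ifelse(x$presence[["indel_II"]], "+", "-"),
              ifelse(x$presence[["GC_DUP"]], "+", "-"),
              x$best_reference, x$identity))
  invisible(x)
}
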