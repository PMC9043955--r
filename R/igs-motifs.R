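IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   Y = c("C", "T"), R = c("A", "G"),
                   N = c("A", "C", "G", "T"))

motif_mismatches <- function(window, pattern) {
  wc <- seq_chars(window)
  pc <- seq_chars(pattern)
  if (length(wc) != length(pc)) return(NA_integer_)
  sum(vapply(seq_along(pc), function(i) {
    !(wc[i] %in% IUPAC_SETS[[pc[i]]])
  }, logical(1)))
}

#' Catalog of Pol III promoter and terminator motifs
#'
#' Defaults encode the external promoter elements conserved in 5S spacers
#' of *Solanum*-like genomes: a 7-bp TATA-like box (TTTAATA) beginning at
#' offset -30, the GC dinucleotide at its typical -12 position and at the
#' additional -14 position, the conserved GA dinucleotide at -3, a
#' pyrimidine (C or T) at -1, and the oligo-T transcription terminator
#' (TTTTT) within the first 15 bp of the IGS 5' end. Offsets are negative
#' and counted so that -1 is the IGS base immediately 5' of the next CDS
#' first base.
#'
#' @param window search half-width around the expected offset (bp).
#' @return a data.frame of class `motif_catalog`.
#' @export
motif_catalog <- function(window = 5L) {
  out <- data.frame(
    name = c("tata_box", "gc_m14", "gc_m12", "ga_m3", "pyrimidine_m1",
             "terminator"),
    pattern = c("TTTAATA", "GC", "GC", "GA", "Y", "TTTTT"),
    expected_offset = c(-30L, -14L, -12L, -3L, -1L, NA_integer_),
    window = c(window, window, window, window, 0L, NA_integer_),
    max_mismatches = c(1L, 0L, 0L, 0L, 0L, 0L),
    region = c("upstream", "upstream", "upstream", "upstream", "upstream",
               "igs_5prime"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("motif_catalog", "data.frame")
  out
}

#' Scan an IGS for promoter and terminator motifs
#'
#' Upstream entries are searched within `expected_offset` +/- `window`
#' allowing at most `max_mismatches`; the terminator is searched from the
#' IGS 5' start (first 15 bp). The reported offset is the best hit's
#' (fewest mismatches, then closest to the expected offset).
#'
#' @param igs the IGS sequence (the sequence between two CDS copies,
#'   CDS-sense; its last base sits at offset -1), or a one-row
#'   `repeat_units` data.frame.
#' @param catalog a [motif_catalog()].
#' @return a data.frame (`motif_report`): name, found, offset, mismatches,
#'   reason for absences.
#' @export
scan_promoter_motifs <- function(igs, catalog = motif_catalog()) {
  if (is.data.frame(igs)) igs <- igs$igs_seq[1]
  L <- nchar(igs)
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    entry <- catalog[i, ]
    m <- nchar(entry$pattern)
    if (entry$region == "igs_5prime") {
      lim <- min(15L, L)
      if (lim < m) {
        return(data.frame(name = entry$name, found = FALSE,
                          offset = NA_integer_, mismatches = NA_integer_,
                          reason = "IGS shorter than terminator search window",
                          stringsAsFactors = FALSE))
      }
      starts <- seq_len(lim - m + 1L)
      mms <- vapply(starts, function(s) {
        motif_mismatches(substr(igs, s, s + m - 1L), entry$pattern)
      }, integer(1))
      best <- which(mms == min(mms))[1]
      found <- mms[best] <= entry$max_mismatches
      return(data.frame(name = entry$name, found = found,
                        offset = if (found) starts[best] else NA_integer_,
                        mismatches = if (found) mms[best] else NA_integer_,
                        reason = if (found) "" else "no match in IGS 5' window",
                        stringsAsFactors = FALSE))
    }
    exp_off <- entry$expected_offset
    if (L < abs(exp_off)) {
      return(data.frame(name = entry$name, found = FALSE,
                        offset = NA_integer_, mismatches = NA_integer_,
                        reason = "IGS shorter than expected offset",
                        stringsAsFactors = FALSE))
    }
    cand <- (exp_off - entry$window):(exp_off + entry$window)
    # offset o places the motif at IGS positions [L + o + 1, L + o + m]
    cand <- cand[L + cand + 1L >= 1L & L + cand + m <= L]
    if (!length(cand)) {
      return(data.frame(name = entry$name, found = FALSE,
                        offset = NA_integer_, mismatches = NA_integer_,
                        reason = "search window outside IGS",
                        stringsAsFactors = FALSE))
    }
    mms <- vapply(cand, function(o) {
      motif_mismatches(substr(igs, L + o + 1L, L + o + m), entry$pattern)
    }, integer(1))
    ok <- mms <= entry$max_mismatches
    if (!any(ok)) {
      return(data.frame(name = entry$name, found = FALSE,
                        offset = NA_integer_, mismatches = NA_integer_,
                        reason = "no match within offset window",
                        stringsAsFactors = FALSE))
    }
    pick <- which(ok)[order(mms[ok], abs(cand[ok] - exp_off))][1]
    data.frame(name = entry$name, found = TRUE, offset = cand[pick],
               mismatches = mms[pick], reason = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("motif_report", "data.frame")
  out
}
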