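#' Build a CDS probe set for read filtering
#'
#' Tiles every overlapping window of the coding sequence into probes of
#' `probe_length` and closes the set under reverse complement, emulating
#' exact-match pre-filtering of reads that contain 5S rDNA fragments.
#'
#' @param cds coding sequence over {A,C,G,T}.
#' @param probe_length probe length in bp (default 20).
#' @return an object of class `probe_set`.
#' @export
make_probes <- function(cds, probe_length = 20L) {
  probe_length <- as.integer(probe_length)
  if (nchar(cds) < probe_length) {
    stop("probe_length (", probe_length, ") exceeds CDS length (", nchar(cds), ")")
  }
  bad <- first_invalid_pos(cds)
  if (bad > 0) {
    stop("ambiguous base '", substr(cds, bad, bad), "' in CDS at position ", bad)
  }
  fw <- seq_windows(cds, probe_length)
  probes <- unique(c(fw, revcomp(fw)))
  structure(list(probe_length = probe_length, probes = probes,
                 source_cds = cds, n_forward = length(fw)),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("probe_set: %d unique %d-bp probes (%d forward windows)\n",
              length(x$probes), x$probe_length, x$n_forward))
  invisible(x)
}

#' Filter a read library with a CDS probe set
#'
#' A read is kept iff any of its windows exactly equals a probe (the probe
#' set already contains both strands). For paired libraries a pair is kept
#' if either mate matches, preserving junction-spanning information. Reads
#' shorter than the probe length are discarded and counted.
#'
#' @param library a `read_library`.
#' @param probes a `probe_set` from [make_probes()].
#' @return the filtered `read_library`, in input order, with an attribute
#'   `filter_stats` (kept, discarded, too_short).
#' @export
filter_reads <- function(library, probes) {
  stopifnot(inherits(probes, "probe_set"))
  if (!length(probes$probes)) stop("empty probe set")
  plen <- probes$probe_length

  hits_for <- function(reads) {
    n <- length(reads)
    keep <- logical(n)
    widths <- nchar(reads)
    long_enough <- widths >= plen
    max_off <- max(widths) - plen + 1
    for (o in seq_len(max(max_off, 0))) {
      todo <- which(!keep & long_enough & widths >= o + plen - 1)
      if (!length(todo)) break
      win <- substring(reads[todo], o, o + plen - 1)
      keep[todo[data.table::`%chin%`(win, probes$probes)]] <- TRUE
    }
    list(keep = keep, too_short = sum(!long_enough))
  }

  h1 <- hits_for(library$reads)
  if (library$layout == "paired") {
    h2 <- hits_for(library$reads2)
    keep <- h1$keep | h2$keep
    too_short <- h1$too_short + h2$too_short
  } else {
    keep <- h1$keep
    too_short <- h1$too_short
  }
  if (too_short > 0) {
    warning(too_short, " read(s) shorter than the probe length were discarded")
  }
  out <- new_read_library(
    library$reads[keep], library$ids[keep], library$layout,
    library$read_length, library$error_rate,
    reads2 = if (!is.null(library$reads2)) library$reads2[keep] else NULL,
    meta = if (!is.null(library$meta)) library$meta[keep, , drop = FALSE] else NULL
  )
  attr(out, "filter_stats") <- c(kept = sum(keep),
                                 discarded = sum(!keep),
                                 too_short = too_short)
  message(sprintf("probe filter: kept %d / %d reads", sum(keep), length(keep)))
  out
}
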