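# apply i.i.d. substitution errors to a character vector of reads
apply_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  n_err <- rbinom(length(reads), nchar(reads), error_rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    chars <- seq_chars(reads[i])
    pos <- sample(length(chars), n_err[i])
    for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

new_read_library <- function(reads, ids, layout, read_length, error_rate,
                             reads2 = NULL, meta = NULL) {
  structure(list(reads = unname(reads), ids = ids, reads2 = reads2,
                 layout = layout, read_length = read_length,
                 error_rate = error_rate, meta = meta),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("read_library: %d %s-end reads of %d bp (error rate %g)\n",
              length(x$reads), x$layout, x$read_length, x$error_rate))
  invisible(x)
}

#' @export
length.read_library <- function(x) length(x$reads)

#' Simulate an error-bearing short-read library from a genome sequence
#'
#' Single-end reads are drawn uniformly from both strands; the read count is
#' `round(coverage * length(array) / read_length)`. Paired-end mode draws
#' fragments of `insert_size` and reports both mates (R2 on the opposite
#' strand). Per-base substitution errors are applied at `error_rate`.
#' Optionally a fraction of reads is replaced by reads from a random
#' non-rDNA background, to exercise filter specificity.
#'
#' @param array genome string (from [build_tandem_array()]).
#' @param config a [sim_config()].
#' @return a `read_library` object; `$meta` records the true source
#'   position, strand and background status of every read.
#' @export
simulate_reads <- function(array, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 3))
  L <- nchar(array)
  rl <- config$read_length
  if (rl > L) stop("read_length exceeds array length")
  if (config$layout == "paired" && config$insert_size < rl) {
    stop("paired insert size must be >= read_length")
  }

  if (config$layout == "single") {
    n_reads <- round(config$coverage * L / rl)
    n_bg <- round(config$background_read_fraction * n_reads)
    n_fg <- n_reads - n_bg
    pos <- sample.int(L - rl + 1, n_fg, replace = TRUE)
    strand <- sample(c("+", "-"), n_fg, replace = TRUE)
    reads <- if (n_fg > 0) substring(array, pos, pos + rl - 1) else character(0)
    rc <- strand == "-"
    reads[rc] <- revcomp(reads[rc])
    meta <- data.frame(pos = pos, strand = strand,
                       background = rep(FALSE, n_fg),
                       stringsAsFactors = FALSE)
    if (n_bg > 0) {
      bg_genome <- random_dna(max(20 * rl, 2000), 0.5)
      bpos <- sample.int(nchar(bg_genome) - rl + 1, n_bg, replace = TRUE)
      bstrand <- sample(c("+", "-"), n_bg, replace = TRUE)
      breads <- substring(bg_genome, bpos, bpos + rl - 1)
      brc <- bstrand == "-"
      breads[brc] <- revcomp(breads[brc])
      reads <- c(reads, breads)
      meta <- rbind(meta, data.frame(pos = NA_integer_, strand = bstrand,
                                     background = TRUE,
                                     stringsAsFactors = FALSE))
    }
    reads <- apply_read_errors(reads, config$error_rate)
    ids <- sprintf("read_%06d", seq_along(reads))
    return(new_read_library(reads, ids, "single", rl, config$error_rate,
                            meta = meta))
  }

  # paired layout
  is <- config$insert_size
  n_pairs <- round(config$coverage * L / (2 * rl))
  fpos <- sample.int(max(L - is + 1, 1), n_pairs, replace = TRUE)
  fstrand <- sample(c("+", "-"), n_pairs, replace = TRUE)
  frag <- substring(array, fpos, pmin(fpos + is - 1, L))
  flip <- fstrand == "-"
  frag[flip] <- revcomp(frag[flip])
  r1 <- substr(frag, 1, rl)
  r2 <- revcomp(substring(frag, pmax(nchar(frag) - rl + 1, 1), nchar(frag)))
  r1 <- apply_read_errors(r1, config$error_rate)
  r2 <- apply_read_errors(r2, config$error_rate)
  ids <- sprintf("pair_%06d", seq_len(n_pairs))
  meta <- data.frame(pos = fpos, strand = fstrand,
                     background = rep(FALSE, n_pairs),
                     stringsAsFactors = FALSE)
  new_read_library(r1, ids, "paired", rl, config$error_rate, reads2 = r2,
                   meta = meta)
}
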