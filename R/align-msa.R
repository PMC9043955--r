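#' Center-star progressive alignment of a small sequence set
#'
#' The center is the sequence maximizing the summed pairwise alignment
#' score (ties broken by name); every other sequence is pairwise-aligned
#' to the center and the alignments are merged column-wise
#' ("once a gap, always a gap"). Deterministic; intended for the tens to
#' low hundreds of IGS-scale sequences a ribotype catalog holds.
#'
#' @param seqs named character vector (1-200 sequences).
#' @param opts a [similarity_options()].
#' @return an object of class `igs_alignment`: list with `rows` (named
#'   gapped sequences, equal length) and `length`.
#' @export
align_small <- function(seqs, opts = similarity_options()) {
  n <- length(seqs)
  if (n < 1 || n > 200) stop("align_small handles 1-200 sequences")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_len(n))
  if (n == 1) {
    return(structure(list(rows = seqs, length = nchar(seqs[[1]])),
                     class = "igs_alignment"))
  }
  if (length(unique(seqs)) == 1L) {
    return(structure(list(rows = seqs, length = nchar(seqs[[1]])),
                     class = "igs_alignment"))
  }
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- align_pair(seqs[[i]], seqs[[j]], opts)$score
      scores[i, j] <- scores[j, i] <- s
    }
  }
  total <- rowSums(scores)
  center <- order(-total, names(seqs))[1]
  others <- setdiff(seq_len(n), center)
  Lc <- nchar(seqs[[center]])

  # pairwise alignments to the center; ins[[i]][j+1] = columns inserted
  # after center position j (j = 0..Lc)
  pair_aln <- vector("list", n)
  ins <- matrix(0L, nrow = n, ncol = Lc + 1L)
  for (i in others) {
    al <- align_pair(seqs[[center]], seqs[[i]], opts)
    pair_aln[[i]] <- al
    cc <- seq_chars(al$a)
    cpos <- 0L
    for (t in seq_along(cc)) {
      if (cc[t] == "-") ins[i, cpos + 1L] <- ins[i, cpos + 1L] + 1L
      else cpos <- cpos + 1L
    }
  }
  master_ins <- apply(ins, 2, max)

  build_row <- function(i) {
    if (i == center) {
      chars <- seq_chars(seqs[[center]])
      out <- character(0)
      for (j in 0:Lc) {
        out <- c(out, rep("-", master_ins[j + 1L]),
                 if (j < Lc) chars[j + 1L])
      }
      return(paste(out, collapse = ""))
    }
    al <- pair_aln[[i]]
    cc <- seq_chars(al$a)
    sc <- seq_chars(al$b)
    blocks <- vector("list", Lc + 1L)   # inserted chars after center pos j
    aligned <- character(Lc)            # char aligned to center pos j
    cpos <- 0L
    for (t in seq_along(cc)) {
      if (cc[t] == "-") {
        blocks[[cpos + 1L]] <- c(blocks[[cpos + 1L]], sc[t])
      } else {
        cpos <- cpos + 1L
        aligned[cpos] <- sc[t]
      }
    }
    out <- character(0)
    for (j in 0:Lc) {
      blk <- blocks[[j + 1L]]
      pad <- master_ins[j + 1L] - length(blk)
      out <- c(out, blk, rep("-", pad), if (j < Lc) aligned[j + 1L])
    }
    paste(out, collapse = "")
  }

  rows <- vapply(seq_len(n), build_row, character(1))
  names(rows) <- names(seqs)
  structure(list(rows = rows, length = nchar(rows[[1]])),
            class = "igs_alignment")
}

#' @export
print.igs_alignment <- function(x, ...) {
  cat(sprintf("igs_alignment: %d rows x %d columns\n",
              length(x$rows), x$length))
  invisible(x)
}

as_alignment_rows <- function(aln) {
  rows <- if (inherits(aln, "igs_alignment")) aln$rows else aln
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows must have equal length")
  }
  rows
}

#' Descriptive statistics of a multiple alignment
#'
#' @param aln an `igs_alignment` or named character vector of equal-length
#'   gapped rows.
#' @param opts a [similarity_options()] (controls the identity
#'   denominator).
#' @return a list: `length` (columns), `identical_sites` (columns where
#'   every row carries the same non-gap base), `mean_pairwise_identity`
#'   (percent, averaged over all unordered pairs; per pair, columns gapped
#'   in both rows are dropped first).
#' @export
alignment_stats <- function(aln, opts = similarity_options()) {
  rows <- as_alignment_rows(aln)
  if (length(rows) < 2) stop("alignment_stats needs >= 2 rows")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  identical_sites <- sum(apply(mat, 2, function(col) {
    col[1] != "-" && all(col == col[1])
  }))
  n <- nrow(mat)
  idents <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- mat[i, ]
      b <- mat[j, ]
      keep <- !(a == "-" & b == "-")
      a <- a[keep]
      b <- b[keep]
      matched <- sum(a == b & a != "-")
      denom <- switch(opts$identity_denominator,
                      alignment_length = length(a),
                      ungapped_columns = sum(a != "-" & b != "-"))
      idents <- c(idents, 100 * matched / denom)
    }
  }
  list(length = ncol(mat), identical_sites = identical_sites,
       mean_pairwise_identity = mean(idents))
}
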