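# non-negative least squares with a tiny ridge augmentation so the active
# set stays numerically full-rank even for near-collinear candidates
nnls_fit <- function(A, b) {
  lam <- sqrt(1e-8 * mean(colSums(A^2)))
  Aa <- rbind(A, diag(lam, ncol(A)))
  ba <- c(b, rep(0, ncol(A)))
  pracma::lsqnonneg(Aa, ba)$x
}

#' Resolve repeat-unit paths by coverage-balanced decomposition
#'
#' Tandem 5S arrays produce cyclic k-mer graph components in which allelic
#' bubbles (one per intra-genomic variant) fragment the unitigs, so no
#' single unbranched contig spans a complete repeat unit once several
#' ribotypes coexist. This step enumerates candidate unit cycles anchored
#' at a CDS seed k-mer, discards branch choices that no read supports
#' locally, and then selects the candidate subset whose k-mer multiset
#' weights, fitted by non-negative least squares against the observed
#' k-mer coverages, carry at least `min_flow` of the total repeat flow.
#' Mosaic (chimeric) paths combining variants of different ribotypes
#' receive no flow in this fit and are dropped.
#'
#' @param graph a `kmer_graph`.
#' @param reads the read library the graph was built from (for branch
#'   support and the support window).
#' @param cds_reference the CDS sequence used to seed and orient units.
#' @param config an [assembly_config()].
#' @param support_reads reads used for the branch-support window index;
#'   defaults to `reads`. Passing the unfiltered library here is
#'   recommended: probe-filtered sets lack the spacer-interior-only reads
#'   that support branches deep inside a long IGS.
#' @return a `data.frame` of class `contig_set` with one wrapped contig per
#'   resolved unit (columns contig, length, mean_coverage, circular,
#'   flow_weight, contig_id).
#' @export
resolve_repeat_paths <- function(graph, reads, cds_reference,
                                 config = assembly_config(),
                                 support_reads = reads) {
  k <- graph$k
  e <- graph_env(graph, config$min_kmer_coverage)
  read_seqs <- if (inherits(support_reads, "read_library")) {
    c(support_reads$reads, support_reads$reads2)
  } else as.character(support_reads)

  empty <- data.frame(contig = character(0), length = integer(0),
                      mean_coverage = numeric(0), circular = logical(0),
                      flow_weight = numeric(0), contig_id = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("contig_set", "data.frame")

  # seed: prefer the k-mer at the CDS 5' end so candidate units start at
  # the canonical CDS first base
  seed <- NULL
  seed_offset <- 0L
  for (p in seq_len(max(nchar(cds_reference) - k + 1L, 0L))) {
    w <- substr(cds_reference, p, p + k - 1L)
    if (node_present(e, w)) { seed <- w; seed_offset <- p - 1L; break }
  }
  if (is.null(seed)) {
    warning("no CDS k-mer present in the pruned graph; no units resolved")
    return(empty)
  }

  rl <- min(nchar(read_seqs))
  w_sup <- config$support_window
  if (is.null(w_sup)) w_sup <- max(2L * k, rl - 30L)
  w_sup <- min(w_sup, rl)
  support_windows <- cpp_all_windows(c(read_seqs, revcomp(read_seqs)), w_sup,
                                     config$min_window_support)

  # flow is fitted against complete-library k-mer counts: probe-filtered
  # sets under-cover the IGS interior (such reads carry no CDS probe), and
  # that systematic dip distorts the least-squares decomposition
  bcnt <- cpp_kmer_count(read_seqs, k)
  b_env <- new.env(hash = TRUE, parent = emptyenv(),
                   size = max(2L * length(bcnt$kmer), 16L))
  if (length(bcnt$kmer)) {
    vals <- as.list(bcnt$count)
    names(vals) <- bcnt$kmer
    list2env(vals, envir = b_env)
  }

  # the seed set holds the CDS-start k-mer plus its variants present in
  # the graph (diverged or pseudogenized CDS copies), so every traversal
  # spans exactly one repeat unit whichever CDS variant flanks it
  seed_set <- unique(c(seed, cpp_hamming_neighbors(ls(e), seed,
                                                   config$max_cds_mismatches)))
  # A traversal that spans more than one repeat arises when an interior
  # CDS copy carries lesions (typically an indel) that hide its start
  # k-mer from the terminal set. Such copies are discovered adaptively:
  # extract the constituent units of one representative long cycle, add
  # the hidden CDS start k-mers as seeds, and re-enumerate - the long
  # cycles (and the combinatorial chimeras they would multiply) vanish.
  units <- character(0)
  for (round in 1:5) {
    units <- cpp_enumerate_units(ls(e), seed_set, k, support_windows, w_sup,
                                 config$max_unit_length,
                                 config$max_candidates)
    if (!length(units)) break
    long <- units[nchar(units) >= min(nchar(units)) + 200L]
    if (!length(long) || round == 5L) break
    rep1 <- long[which.min(nchar(long))]
    mdf <- data.frame(contig = paste0(rep1, substr(rep1, 1L,
                                                   nchar(cds_reference) + k)),
                      length = nchar(rep1), mean_coverage = NA_real_,
                      circular = TRUE, contig_id = "unit_path_01",
                      stringsAsFactors = FALSE)
    class(mdf) <- c("contig_set", "data.frame")
    ex <- extract_repeat_units(mdf, cds_reference, config$max_cds_mismatches)
    new_seeds <- setdiff(substr(ex$cds_seq, 1L, k), seed_set)
    new_seeds <- new_seeds[nchar(new_seeds) == k &
                             vapply(new_seeds, node_present, logical(1), e = e)]
    if (!length(new_seeds)) break
    seed_set <- c(seed_set, new_seeds)
  }
  if (!length(units)) {
    warning("no complete unit cycle through the CDS seed; no units resolved")
    return(empty)
  }
  # undo the seed offset so every unit starts at the CDS first base
  if (seed_offset > 0L) {
    units <- vapply(units, function(u) rotate_seq(u, nchar(u) - seed_offset),
                    character(1), USE.NAMES = FALSE)
  }
  # residual long cycles (round cap reached) are split into constituents
  long <- which(nchar(units) >= min(nchar(units)) + 200L)
  if (length(long)) {
    mseqs <- units[long]
    mdf <- data.frame(contig = paste0(mseqs, substr(mseqs, 1L,
                                                    nchar(cds_reference) + k)),
                      length = nchar(mseqs), mean_coverage = NA_real_,
                      circular = TRUE,
                      contig_id = sprintf("unit_path_%02d", seq_along(mseqs)),
                      stringsAsFactors = FALSE)
    class(mdf) <- c("contig_set", "data.frame")
    ex <- extract_repeat_units(mdf, cds_reference, config$max_cds_mismatches)
    units <- unique(c(units[-long], paste0(ex$cds_seq, ex$igs_seq)))
  }

  units <- sort(units)
  tri <- cpp_units_kmer_triplets(units, k)
  all_kms <- tri$kmers
  A <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                            dims = c(length(all_kms), length(units)))
  b <- vapply(all_kms, function(km) {
    if (node_present(b_env, km)) node_count(b_env, km) else 0
  }, numeric(1))

  if (length(units) == 1L) {
    wts <- 1
  } else {
    # With many candidates (variants farther apart than the support window
    # multiply combinatorially), select by non-negative orthogonal matching
    # pursuit, then refine forward-backward: greedy order alone can bury a
    # low-abundance true unit under several of its one-column mosaics, each
    # of which explains part of its coverage signal.
    colnorm <- sqrt(Matrix::colSums(A^2))
    nnls_res <- function(S) {
      w <- nnls_fit(as.matrix(A[, S, drop = FALSE]), b)
      r <- b - as.vector(A[, S, drop = FALSE] %*% w)
      list(w = w, r = r, norm = sqrt(sum(r^2)))
    }
    S <- seq_along(units)
    if (length(units) > 60L) {
      S <- integer(0)
      r <- b
      for (step in seq_len(60L)) {
        corr <- as.vector(Matrix::crossprod(A, r)) / colnorm
        corr[S] <- -Inf
        j <- which.max(corr)
        if (!is.finite(corr[j]) || corr[j] <= 1e-8) break
        S <- c(S, j)
        fit <- nnls_res(S)
        r <- fit$r
        if (fit$norm < 1e-6 * sqrt(sum(b^2))) break
      }
      # forward-backward refinement: keep admitting the candidate most
      # correlated with the residual while it improves the fit, shedding
      # members whose weight has collapsed
      fit <- nnls_res(S)
      for (iter in seq_len(30L)) {
        corr <- as.vector(Matrix::crossprod(A, fit$r)) / colnorm
        corr[S] <- -Inf
        j <- which.max(corr)
        if (!is.finite(corr[j]) || corr[j] <= 1e-8) break
        fit2 <- nnls_res(c(S, j))
        if (fit2$norm >= fit$norm * (1 - 1e-4)) break
        S <- c(S, j)
        fit <- fit2
        drop <- S[fit$w <= 1e-8 * sum(fit$w)]
        if (length(drop)) {
          S <- setdiff(S, drop)
          fit <- nnls_res(S)
        }
      }
      S <- sort(S)
      units <- units[S]
      A <- A[, S, drop = FALSE]
    }
    wts <- nnls_fit(as.matrix(A), b)
    if (sum(wts) <= 0) {
      warning("flow fit degenerate; no units resolved")
      return(empty)
    }
    wts <- wts / sum(wts)
    keep <- wts >= config$min_flow
    if (!any(keep)) keep <- wts == max(wts)
    units <- units[keep]
    A <- A[, keep, drop = FALSE]
    if (length(units) > 1L) {
      wts <- nnls_fit(as.matrix(A), b)
      wts <- wts / sum(wts)
    } else {
      wts <- 1
    }
  }

  cov <- vapply(seq_along(units), function(j) {
    kms <- all_kms[A[, j] != 0]
    present <- kms[vapply(kms, node_present, logical(1), e = e)]
    if (!length(present)) return(0)
    mean(vapply(present, node_count, numeric(1), e = e))
  }, numeric(1))

  # wrap each unit with its own CDS head so downstream anchor extraction
  # sees one full IGS flanked by two CDS fragments
  cds_len <- nchar(cds_reference)
  wrapped <- vapply(units, function(u) {
    paste0(u, substr(u, 1L, min(nchar(u), cds_len + k)))
  }, character(1), USE.NAMES = FALSE)

  ord <- order(-wts, units)
  out <- data.frame(contig = wrapped[ord],
                    length = nchar(units)[ord],
                    mean_coverage = cov[ord],
                    circular = TRUE,
                    flow_weight = wts[ord],
                    stringsAsFactors = FALSE)
  out$contig_id <- sprintf("unit_path_%02d", seq_len(nrow(out)))
  class(out) <- c("contig_set", "data.frame")
  out
}

# indel-tolerant supplementary anchors: CDS located by its 20-bp prefix,
# extent refined by its 20-bp suffix
fuzzy_anchors <- function(contig, cds, existing_pos) {
  L <- nchar(cds)
  pre <- substr(cds, 1, 20)
  suf <- substr(cds, L - 19, L)
  hits <- cpp_anchor_scan(contig, pre, 2L)
  hits <- hits[hits$strand == "+", , drop = FALSE]
  out <- NULL
  for (p in hits$pos) {
    if (length(existing_pos) && any(abs(existing_pos - p) <= 10)) next
    lo <- p + floor(0.6 * L)
    hi <- min(p + ceiling(1.4 * L), nchar(contig) - 19)
    if (hi < lo) next
    window <- substr(contig, lo, hi + 19)
    sh <- cpp_anchor_scan(window, suf, 2L)
    sh <- sh[sh$strand == "+", , drop = FALSE]
    if (!nrow(sh)) next
    cds_end <- lo + sh$pos[1] - 1 + 19
    out <- rbind(out, data.frame(pos = p, cds_end = cds_end,
                                 mismatches = NA_integer_, strand = "+",
                                 stringsAsFactors = FALSE))
  }
  out
}

# Local-alignment anchor discovery over a whole contig: iteratively takes
# the best local CDS hit, masks it, and repeats. Catches CDS copies whose
# lesions defeat every ungapped scan (e.g. an indel inside the probe
# prefix).
local_cds_anchors <- function(seq, cds, existing_pos, max_hits = 8L) {
  L <- nchar(cds)
  out <- NULL
  masked <- seq
  for (h in seq_len(max_hits)) {
    pa <- tryCatch(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(cds), Biostrings::DNAString(masked),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 2, gapExtension = 0.5), error = function(e) NULL)
    if (is.null(pa)) break
    sstart <- Biostrings::start(Biostrings::subject(pa))
    send <- Biostrings::end(Biostrings::subject(pa))
    span <- send - sstart + 1L
    if (Biostrings::score(pa) < 0.5 * L || span < 0.8 * L || span > 1.2 * L) {
      break
    }
    if (!length(existing_pos) || !any(abs(existing_pos - sstart) <= 10)) {
      out <- rbind(out, data.frame(pos = sstart, cds_end = send,
                                   mismatches = NA_integer_, strand = "+",
                                   stringsAsFactors = FALSE))
      existing_pos <- c(existing_pos, sstart)
    }
    substr(masked, sstart, send) <- strrep("N", span)
  }
  out
}

# Third anchor pass: a CDS copy whose lesions defeat both the full-length
# and the prefix/suffix scans (e.g. an indel within the first probe-length
# bases) leaves an inter-anchor gap wide enough to hold two spacers and a
# CDS. Local gapped alignment of the reference CDS inside such gaps
# recovers the hidden anchor so the flanking repeats are not fused.
add_gap_anchors <- function(seq, cds, anch, max_rounds = 10L) {
  L <- nchar(cds)
  for (round in seq_len(max_rounds)) {
    gaps <- data.frame(lo = anch$cds_end[-nrow(anch)] + 1L,
                       hi = anch$pos[-1] - 1L)
    gaps <- gaps[gaps$hi - gaps$lo + 1L >= L + 60L, , drop = FALSE]
    added <- FALSE
    for (g in seq_len(nrow(gaps))) {
      region <- substr(seq, gaps$lo[g], gaps$hi[g])
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(cds), Biostrings::DNAString(region),
        type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = TRUE),
        gapOpening = 2, gapExtension = 0.5)
      span <- Biostrings::end(Biostrings::subject(pa)) -
        Biostrings::start(Biostrings::subject(pa)) + 1L
      if (Biostrings::score(pa) >= 0.5 * L &&
          span >= 0.8 * L && span <= 1.2 * L) {
        pos <- gaps$lo[g] + Biostrings::start(Biostrings::subject(pa)) - 1L
        cds_end <- gaps$lo[g] + Biostrings::end(Biostrings::subject(pa)) - 1L
        anch <- rbind(anch, data.frame(pos = pos, cds_end = cds_end,
                                       mismatches = NA_integer_,
                                       strand = "+",
                                       stringsAsFactors = FALSE))
        anch <- anch[order(anch$pos), , drop = FALSE]
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  anch
}

#' Extract complete repeat units from contigs
#'
#' Locates CDS anchor occurrences (ungapped, at most `max_cds_mismatches`
#' mismatches, both strands; an indel-tolerant prefix/suffix scan
#' supplements the full-length scan so pseudogenized CDS copies still
#' anchor) and, for each pair of consecutive co-oriented anchors, emits the
#' inter-anchor sequence as an IGS with canonical start at the downstream
#' CDS first base. Units are reported on the CDS-sense strand. Circular
#' contigs are doubled before scanning and duplicate rotations collapsed.
#'
#' @param contigs a `contig_set` (from [prune_and_assemble()] or
#'   [resolve_repeat_paths()]) or a character vector of contig sequences.
#' @param cds_reference CDS sequence to anchor on.
#' @param max_cds_mismatches mismatch tolerance for full-length anchors.
#' @return a `data.frame` of class `repeat_units`: unit_seq, cds_seq,
#'   igs_seq, igs_start/igs_end (0-based half-open within unit),
#'   source_contig, mean_coverage, flow_weight. Contigs with fewer than two
#'   anchors are counted in attribute `skipped`; contigs with anchors on
#'   both strands are flagged in attribute `anomalous`.
#' @export
extract_repeat_units <- function(contigs, cds_reference,
                                 max_cds_mismatches = 5L) {
  if (is.character(contigs)) {
    contigs <- data.frame(contig = contigs, length = nchar(contigs),
                          mean_coverage = NA_real_, circular = FALSE,
                          contig_id = sprintf("contig_%02d", seq_along(contigs)),
                          stringsAsFactors = FALSE)
  }
  if (is.null(contigs$flow_weight)) contigs$flow_weight <- NA_real_
  if (nchar(cds_reference) == 0) stop("cds_reference must be nonempty")

  units <- list()
  skipped <- 0L
  anomalous <- character(0)
  for (i in seq_len(nrow(contigs))) {
    seq <- contigs$contig[i]
    if (isTRUE(contigs$circular[i]) &&
        !grepl("unit_path", contigs$contig_id[i], fixed = TRUE)) {
      # triple, not double: a rotation that splits the CDS across the wrap
      # needs a third copy for the second full anchor to fit; duplicate
      # rotations are collapsed below
      seq <- paste0(seq, seq, seq)
    }
    anch <- cpp_anchor_scan(seq, cds_reference, max_cds_mismatches)
    if (nrow(anch) && length(unique(anch$strand)) > 1L) {
      anomalous <- c(anomalous, contigs$contig_id[i])
      next
    }
    if (nrow(anch) && all(anch$strand == "-")) {
      seq <- revcomp(seq)
      anch <- cpp_anchor_scan(seq, cds_reference, max_cds_mismatches)
    }
    anch <- data.frame(pos = anch$pos,
                       cds_end = anch$pos + nchar(cds_reference) - 1L,
                       mismatches = anch$mismatches,
                       strand = anch$strand, stringsAsFactors = FALSE)
    fz <- fuzzy_anchors(seq, cds_reference, anch$pos)
    anch <- rbind(anch, fz)
    if (is.null(anch) || nrow(anch) < 2L) {
      la <- local_cds_anchors(seq, cds_reference,
                              if (is.null(anch)) integer(0) else anch$pos)
      anch <- rbind(anch, la)
    }
    if (is.null(anch) || nrow(anch) < 2L) {
      skipped <- skipped + 1L
      next
    }
    anch <- anch[order(anch$pos), , drop = FALSE]
    anch <- add_gap_anchors(seq, cds_reference, anch)
    for (j in seq_len(nrow(anch) - 1L)) {
      a1 <- anch[j, ]
      a2 <- anch[j + 1L, ]
      if (a2$pos <= a1$cds_end) next      # overlapping anchors
      # refine the CDS extent by gapped alignment so indel-bearing
      # (pseudogenized) copies do not shift the CDS/IGS boundary
      prefix_end <- min(a1$pos + nchar(cds_reference) + 10L, a2$pos - 1L)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(cds_reference),
        Biostrings::DNAString(substr(seq, a1$pos, prefix_end)),
        type = "global-local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = TRUE),
        gapOpening = 2, gapExtension = 0.5)
      cds_end <- a1$pos + Biostrings::end(Biostrings::subject(pa)) - 1L
      cds_seq <- substr(seq, a1$pos, cds_end)
      igs_seq <- substr(seq, cds_end + 1L, a2$pos - 1L)
      if (nchar(igs_seq) == 0L) next
      units[[length(units) + 1L]] <- data.frame(
        unit_seq = paste0(cds_seq, igs_seq),
        cds_seq = cds_seq, igs_seq = igs_seq,
        igs_start = nchar(cds_seq), igs_end = nchar(cds_seq) + nchar(igs_seq),
        source_contig = contigs$contig_id[i],
        mean_coverage = contigs$mean_coverage[i],
        flow_weight = contigs$flow_weight[i],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(units)) do.call(rbind, units) else {
    data.frame(unit_seq = character(0), cds_seq = character(0),
               igs_seq = character(0), igs_start = integer(0),
               igs_end = integer(0), source_contig = character(0),
               mean_coverage = numeric(0), flow_weight = numeric(0),
               stringsAsFactors = FALSE)
  }
  # circular contigs scanned doubled can emit the same rotation twice
  out <- out[!duplicated(out[c("unit_seq", "source_contig")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repeat_units", "data.frame")
  attr(out, "skipped") <- skipped
  attr(out, "anomalous") <- anomalous
  out
}
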