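#' Assembly configuration
#'
#' @param k k-mer size (odd, >= 15).
#' @param min_kmer_coverage minimum k-mer coverage retained by pruning.
#'   Deep real libraries warrant ~100; synthetic desk-scale libraries use 5.
#' @param max_contigs_reported contigs retained after coverage ranking.
#' @param min_overlap_identity exact-overlap requirement of the k-mer graph
#'   (fixed at 1: edges are exact (k-1)-overlaps).
#' @param max_cds_mismatches mismatch tolerance when anchoring the CDS in a
#'   contig; tolerates diverged CDS copies while pseudogene judgement is
#'   deferred to the ribotype-calling step.
#' @param support_window length of the read-support window consulted at
#'   graph branch points during path resolution; default `2 * k`, capped at
#'   the read length.
#' @param min_flow smallest per-candidate flow (fraction of total repeat
#'   flow) retained by the coverage-balanced path decomposition.
#' @param max_unit_length longest candidate repeat-unit path explored.
#' @param max_candidates cap on enumerated candidate paths.
#' @param min_window_support times a support window must occur among the
#'   reads before a branch choice trusts it (2 rejects windows forged by a
#'   single sequencing error).
#' @return an object of class `assembly_config`.
#' @export
assembly_config <- function(k = 31L,
                            min_kmer_coverage = 5L,
                            max_contigs_reported = 12L,
                            min_overlap_identity = 1.0,
                            max_cds_mismatches = 5L,
                            support_window = NULL,
                            min_flow = 0.02,
                            max_unit_length = 2000L,
                            max_candidates = 30000L,
                            min_window_support = 2L) {
  k <- as.integer(k)
  if (k < 15L || k %% 2L == 0L) stop("k must be odd and >= 15")
  if (min_kmer_coverage < 1L) stop("min_kmer_coverage must be >= 1")
  if (min_overlap_identity != 1.0) {
    stop("the k-mer graph only supports exact overlaps (min_overlap_identity = 1)")
  }
  structure(list(
    k = k, min_kmer_coverage = as.integer(min_kmer_coverage),
    max_contigs_reported = as.integer(max_contigs_reported),
    min_overlap_identity = min_overlap_identity,
    max_cds_mismatches = as.integer(max_cds_mismatches),
    support_window = support_window,
    min_flow = min_flow,
    max_unit_length = as.integer(max_unit_length),
    max_candidates = as.integer(max_candidates),
    min_window_support = as.integer(min_window_support)
  ), class = "assembly_config")
}

#' Build a strand-canonical k-mer graph from reads
#'
#' Nodes are k-mers collapsed with their reverse complements
#' (lexicographic minimum); node coverage counts the read windows
#' contributing the k-mer. Windows containing N are skipped. Edges are the
#' implicit exact (k-1)-overlaps between present k-mers.
#'
#' @param reads a `read_library` or character vector of reads.
#' @param config an [assembly_config()].
#' @return an object of class `kmer_graph` with fields `kmers`, `counts`,
#'   `k`.
#' @export
build_graph <- function(reads, config = assembly_config()) {
  seqs <- if (inherits(reads, "read_library")) {
    c(reads$reads, reads$reads2)
  } else {
    as.character(reads)
  }
  res <- cpp_kmer_count(seqs, config$k)
  if (!length(res$kmer)) warning("empty read set: the k-mer graph has no nodes")
  structure(list(kmers = res$kmer, counts = res$count, k = config$k),
            class = "kmer_graph")
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf("kmer_graph: %d canonical %d-mers (coverage %s)\n",
              length(x$kmers), x$k,
              if (length(x$counts)) {
                sprintf("%d-%d", min(x$counts), max(x$counts))
              } else "-"))
  invisible(x)
}

# hash environment of oriented k-mers -> coverage (both orientations keyed)
graph_env <- function(graph, min_cov = 1L) {
  keep <- graph$counts >= min_cov
  km <- graph$kmers[keep]
  cnt <- graph$counts[keep]
  e <- new.env(hash = TRUE, parent = emptyenv(), size = max(2L * length(km), 16L))
  if (length(km)) {
    rc <- revcomp(km)
    vals <- as.list(c(cnt, cnt))
    names(vals) <- c(km, rc)
    list2env(vals, envir = e)
  }
  e
}

node_present <- function(e, km) exists(km, envir = e, inherits = FALSE)
node_count <- function(e, km) get(km, envir = e, inherits = FALSE)

successors <- function(e, km, k) {
  core <- substr(km, 2, k)
  cand <- paste0(core, DNA_BASES)
  cand[vapply(cand, node_present, logical(1), e = e)]
}

predecessors <- function(e, km, k) {
  core <- substr(km, 1, k - 1)
  cand <- paste0(DNA_BASES, core)
  cand[vapply(cand, node_present, logical(1), e = e)]
}

#' Number of (k-1)-overlap edges in the graph
#'
#' Each bidirected edge is counted once.
#'
#' @param graph a `kmer_graph`.
#' @param min_cov count only nodes at or above this coverage.
#' @export
kmer_graph_edges <- function(graph, min_cov = 1L) {
  e <- graph_env(graph, min_cov)
  nodes <- ls(e)
  total <- 0L
  for (nd in nodes) total <- total + length(successors(e, nd, graph$k))
  total %/% 2L
}

#' Prune the graph and assemble unitig contigs
#'
#' Nodes below `min_kmer_coverage` are removed; contigs are the maximal
#' unbranched paths of the remaining bidirected graph (allelic bubble
#' branches therefore come out as separate contigs, which downstream
#' ribotype separation relies on). Pure cycles - the expected signature of
#' a homogeneous tandem array - are linearized starting at their
#' lexicographically smallest k-mer and flagged `circular`. Contigs are
#' ranked by mean k-mer coverage and the top `max_contigs_reported` kept.
#'
#' @param graph a `kmer_graph`.
#' @param config an [assembly_config()].
#' @return a `data.frame` of class `contig_set`: contig sequence, length,
#'   mean coverage, circularity.
#' @export
prune_and_assemble <- function(graph, config = assembly_config()) {
  k <- graph$k
  e <- graph_env(graph, config$min_kmer_coverage)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  seen <- function(km) exists(km, envir = visited, inherits = FALSE)
  mark <- function(km) {
    assign(km, TRUE, envir = visited)
    assign(rc1(km), TRUE, envir = visited)
  }
  nodes <- sort(ls(e))
  contigs <- character(0)
  covs <- numeric(0)
  circ <- logical(0)

  walk_from <- function(s) {
    path_nodes <- s
    cur <- s
    repeat {
      succ <- successors(e, cur, k)
      if (length(succ) != 1L) break
      nxt <- succ[1]
      if (length(predecessors(e, nxt, k)) != 1L) break
      if (nxt == s || seen(nxt)) break
      path_nodes <- c(path_nodes, nxt)
      cur <- nxt
    }
    path_nodes
  }

  emit <- function(path_nodes, circular) {
    seq <- paste0(path_nodes[1],
                  paste(substr(path_nodes[-1], k, k), collapse = ""))
    cov <- mean(vapply(path_nodes, node_count, numeric(1), e = e))
    contigs <<- c(contigs, seq)
    covs <<- c(covs, cov)
    circ <<- c(circ, circular)
    for (nd in path_nodes) mark(nd)
  }

  # linear unitigs: start at nodes that begin a maximal unbranched path
  for (s in nodes) {
    if (seen(s)) next
    preds <- predecessors(e, s, k)
    is_start <- length(preds) != 1L ||
      length(successors(e, preds[1], k)) != 1L
    if (!is_start) next
    emit(walk_from(s), circular = FALSE)
  }
  # leftovers are pure cycles; declared rotation: lexicographically
  # smallest oriented k-mer of the cycle
  for (s in nodes) {
    if (seen(s)) next
    cyc <- s
    cur <- s
    repeat {
      nxt <- successors(e, cur, k)[1]
      if (is.na(nxt) || nxt == s) break
      if (nxt %in% cyc) break
      cyc <- c(cyc, nxt)
      cur <- nxt
    }
    rot <- which(cyc == min(cyc))[1]
    cyc <- c(cyc[rot:length(cyc)], cyc[seq_len(rot - 1L)])
    emit(cyc, circular = TRUE)
  }

  ord <- order(-covs, contigs)
  keep <- head(ord, config$max_contigs_reported)
  out <- data.frame(contig = contigs[keep],
                    length = nchar(contigs[keep]),
                    mean_coverage = covs[keep],
                    circular = circ[keep],
                    stringsAsFactors = FALSE)
  out$contig_id <- sprintf("contig_%02d", seq_len(nrow(out)))
  class(out) <- c("contig_set", "data.frame")
  attr(out, "n_unitigs_total") <- length(contigs)
  out
}
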