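# shared fixtures and independent oracles for the test suite

quick_sim <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, ...)
  rs <- generate_ribotype_set(cfg)
  arr <- build_tandem_array(rs$ribotypes, rs$truth, cfg, rs$ancestral_cds)
  lib <- simulate_reads(arr$array, cfg)
  list(cfg = cfg, rs = rs, arr = arr, lib = lib)
}

run_assembly <- function(sim, assembly = assembly_config()) {
  flib <- suppressMessages(filter_reads(sim$lib, make_probes(sim$rs$ancestral_cds)))
  graph <- build_graph(flib, assembly)
  resolved <- resolve_repeat_paths(graph, flib, sim$rs$ancestral_cds, assembly,
                                   support_reads = sim$lib)
  units <- extract_repeat_units(resolved, sim$rs$ancestral_cds,
                                assembly$max_cds_mismatches)
  list(filtered = flib, graph = graph, resolved = resolved, units = units)
}

# exhaustive global alignment oracle for tiny sequences: enumerates every
# gapped pairing recursively, returns the optimal score and the range of
# identities (percent, alignment-length denominator) among co-optimal
# alignments
oracle_global_alignments <- function(a, b, match = 1, mismatch = -1,
                                     gap_open = -2, gap_ext = -0.5) {
  best <- new.env()
  best$score <- -Inf
  best$idents <- numeric(0)
  rec <- function(i, j, score, cols, matched, in_gap) {
    if (i > nchar(a) && j > nchar(b)) {
      if (score > best$score + 1e-9) {
        best$score <- score
        best$idents <- 100 * matched / cols
      } else if (abs(score - best$score) <= 1e-9) {
        best$idents <- c(best$idents, 100 * matched / cols)
      }
      return(invisible())
    }
    if (i <= nchar(a) && j <= nchar(b)) {
      hit <- substr(a, i, i) == substr(b, j, j)
      rec(i + 1, j + 1, score + if (hit) match else mismatch,
          cols + 1, matched + hit, "none")
    }
    if (i <= nchar(a)) {
      pen <- if (in_gap == "a") gap_ext else gap_open + gap_ext
      rec(i + 1, j, score + pen, cols + 1, matched, "a")
    }
    if (j <= nchar(b)) {
      pen <- if (in_gap == "b") gap_ext else gap_open + gap_ext
      rec(i, j + 1, score + pen, cols + 1, matched, "b")
    }
  }
  rec(1, 1, 0, 0, 0, "none")
  list(score = best$score, identities = range(best$idents))
}

# independent minimax path distances by repeated relaxation (distinct
# algorithm from the package's MST-based computation)
oracle_minimax <- function(D) {
  n <- nrow(D)
  S <- D
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        S[i, j] <- min(S[i, j], max(S[i, k], S[k, j]))
      }
    }
  }
  S
}

# gap-as-fifth-state hamming distance matrix, written independently
oracle_hap_dist <- function(seqs) {
  n <- length(seqs)
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sum(utf8ToInt(seqs[i]) != utf8ToInt(seqs[j]))
    }
  }
  D
}

random_haplotype_set <- function(n, len) {
  base <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  seqs <- vapply(seq_len(n), function(i) {
    chars <- strsplit(base, "")[[1]]
    nmut <- sample(1:max(1, len %/% 2), 1)
    pos <- sample(len, nmut)
    for (p in pos) chars[p] <- sample(c("A", "C", "G", "T", "-"), 1)
    paste(chars, collapse = "")
  }, character(1))
  unique(seqs)
}
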