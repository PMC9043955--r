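# Positions of the canonical Pol III motifs within an IGS of length L,
# counting offset -1 as the IGS base immediately 5' of the next CDS.
# Returns a list of (name, start, end, seq) in 1-based IGS coordinates.
igs_motif_layout <- function(L) {
  list(
    list(name = "terminator", start = 1L, end = 5L, seq = "TTTTT"),
    list(name = "tata", start = L - 29L, end = L - 23L, seq = "TTTAATA"),
    list(name = "gc_m14", start = L - 13L, end = L - 12L, seq = "GC"),
    list(name = "gc_m12", start = L - 11L, end = L - 10L, seq = "GC"),
    list(name = "ga_m3", start = L - 2L, end = L - 1L, seq = "GA"),
    list(name = "py_m1", start = L, end = L, seq = "T")
  )
}

plant_motifs <- function(igs) {
  L <- nchar(igs)
  chars <- seq_chars(igs)
  for (m in igs_motif_layout(L)) {
    if (m$start < 1 || m$end > L) next
    chars[m$start:m$end] <- seq_chars(m$seq)
  }
  paste(chars, collapse = "")
}

protected_positions <- function(L, plant) {
  if (!plant) return(integer(0))
  unlist(lapply(igs_motif_layout(L), function(m) {
    if (m$start < 1 || m$end > L) return(integer(0))
    m$start:m$end
  }))
}

# substitute `n` bases at distinct positions drawn from `allowed`
mutate_snps <- function(seq, n, allowed = seq_len(nchar(seq))) {
  if (n == 0) return(seq)
  if (length(allowed) < n) stop("not enough mutable positions for requested SNPs")
  chars <- seq_chars(seq)
  pos <- if (length(allowed) == 1) allowed else sample(allowed, n)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

apply_indel <- function(seq, len, type, protected = integer(0)) {
  L <- nchar(seq)
  if (type == "deletion") {
    starts <- setdiff(seq_len(L - len + 1), protected)
    starts <- starts[vapply(starts, function(s) {
      !any((s:(s + len - 1)) %in% protected)
    }, logical(1))]
    if (!length(starts)) stop("no unprotected span available for deletion")
    s <- if (length(starts) == 1) starts else sample(starts, 1)
    paste0(substr(seq, 1, s - 1), substr(seq, s + len, L))
  } else if (type == "insertion") {
    starts <- setdiff(seq_len(L + 1), protected)
    s <- if (length(starts) == 1) starts else sample(starts, 1)
    paste0(substr(seq, 1, s - 1), random_dna(len, 0.5), substr(seq, s, L))
  } else {
    stop("indel type must be 'insertion' or 'deletion'")
  }
}

# Plant an internal tandem duplication into a repeat unit. The duplicated
# segment spans the CDS 3' end (cds_part bp) plus the adjacent IGS 5'
# region; extra copies are inserted immediately after the first copy, with
# the planted divergence confined to the IGS-derived portion (matching the
# anatomy of the long eggplant-type spacer variant).
plant_duplication <- function(cds, igs, spec) {
  unit <- spec$unit
  copies <- if (is.null(spec$copies)) 2L else spec$copies
  cds_part <- if (is.null(spec$cds_part)) min(32L, nchar(cds)) else spec$cds_part
  snps <- if (is.null(spec$snps)) 0L else spec$snps
  indel <- if (is.null(spec$indel)) 0L else spec$indel
  igs_part <- unit - cds_part
  stopifnot(copies >= 2, cds_part >= 0, igs_part > 0, igs_part <= nchar(igs))
  x <- paste0(substr(cds, nchar(cds) - cds_part + 1, nchar(cds)),
              substr(igs, 1, igs_part))
  extra <- character(copies - 1)
  for (j in seq_len(copies - 1)) {
    xj <- x
    # choose the deletion span first and keep planted substitutions clear
    # of it: a substitution flanking an indel makes the SNP/indel
    # decomposition of the copy divergence alignment-ambiguous
    del_start <- 0L
    if (indel > 0) {
      lo <- cds_part + 5
      hi <- nchar(xj) - indel - 4
      del_start <- if (hi > lo) sample(lo:hi, 1) else lo
    }
    if (snps > 0) {
      igs_positions <- (cds_part + 1):nchar(xj)
      if (del_start > 0) {
        guard <- (del_start - 3L):(del_start + indel + 2L)
        igs_positions <- setdiff(igs_positions, guard)
      }
      xj <- mutate_snps(xj, snps, allowed = igs_positions)
    }
    if (del_start > 0) {
      xj <- paste0(substr(xj, 1, del_start - 1),
                   substr(xj, del_start + indel, nchar(xj)))
    }
    extra[j] <- xj
  }
  paste0(substr(igs, 1, igs_part),
         paste(extra, collapse = ""),
         substr(igs, igs_part + 1, nchar(igs)))
}

#' Generate a seeded set of IGS ribotypes
#'
#' Draws a latent ancestral CDS and IGS, then derives every ribotype from
#' that ancestor by its configured substitutions, indels and (optionally)
#' an internal tandem duplication, so the set forms a star around an
#' unsampled ancestral spacer (the shape intragenomic ribotype sets take in
#' haplotype networks). With no configured mutations a ribotype is the
#' ancestor itself. Any mutation collision producing two identical
#' ribotypes triggers a regeneration of the colliding ribotype, up to
#' `max_regen_attempts`.
#'
#' @param config a [sim_config()].
#' @return a list with elements `ancestral_cds`, `ancestral_igs`,
#'   `ribotypes` (named character vector R1..Rn of IGS sequences) and
#'   `truth` (a partial truth set: sequences, proportions, seed).
#' @export
generate_ribotype_set <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1))
  cds <- random_dna(config$cds_length, 0.55)
  igs0 <- random_dna(config$igs_length, config$igs_gc)
  if (config$plant_promoter_motifs && config$igs_length >= 40) {
    igs0 <- plant_motifs(igs0)
  }
  L <- nchar(igs0)
  prot <- protected_positions(L, config$plant_promoter_motifs && L >= 40)
  n <- config$n_ribotypes

  # distribute indel plans over ribotypes (round-robin when unassigned)
  indel_by_ribo <- vector("list", n)
  if (!is.null(config$indel_spec)) {
    rr <- 0L
    for (entry in config$indel_spec) {
      target <- entry$ribotype
      if (is.null(target)) {
        target <- (rr %% n) + 1L
        rr <- rr + 1L
      }
      indel_by_ribo[[target]] <- c(indel_by_ribo[[target]], list(entry))
    }
  }
  dup <- config$duplication_spec
  dup_target <- if (!is.null(dup)) {
    if (is.null(dup$ribotype)) n else dup$ribotype
  } else 0L

  ribos <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(config$max_regen_attempts)) {
      ri <- mutate_snps(igs0, config$snps_per_ribotype,
                        allowed = setdiff(seq_len(L), prot))
      for (entry in indel_by_ribo[[i]]) {
        ri <- apply_indel(ri, entry$length, entry$type, protected = prot)
      }
      if (i == dup_target) ri <- plant_duplication(cds, ri, dup)
      if (!ri %in% ribos[seq_len(i - 1L)]) {
        ribos[i] <- ri
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not generate ", n, " distinct ribotypes after ",
           config$max_regen_attempts, " attempts; increase IGS length or ",
           "reduce mutation collisions")
    }
  }
  names(ribos) <- paste0("R", seq_len(n))
  truth <- structure(list(
    ribotype_sequences = ribos,
    true_proportions = setNames(config$proportions, names(ribos)),
    array_layout = NULL,
    seed = config$seed
  ), class = "truth_set")
  list(ancestral_cds = cds, ancestral_igs = igs0, ribotypes = ribos,
       truth = truth)
}
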