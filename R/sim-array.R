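# largest-remainder apportionment of `total` copies over `p`
apportion_copies <- function(p, total) {
  base <- floor(p * total)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- p * total - base
    ord <- order(-frac, seq_along(p))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Disable a CDS copy: one 1-2 bp indel or three substitutions (the same
# lesions the pseudogene-detection rule triggers on). Indels are kept away
# from the CDS termini: a lesion at the very junction is formally
# ambiguous between a CDS indel and a length variant of the neighboring
# spacer, so no observer could attribute it.
pseudogenize_cds <- function(cds) {
  L <- nchar(cds)
  if (runif(1) < 0.5) {
    len <- sample(1:2, 1)
    interior <- 10:(L - len - 10)
    s <- if (length(interior) == 1) interior else sample(interior, 1)
    if (runif(1) < 0.5) {
      paste0(substr(cds, 1, s - 1), substr(cds, s + len, L))
    } else {
      paste0(substr(cds, 1, s - 1), random_dna(len, 0.5), substr(cds, s, L))
    }
  } else {
    mutate_snps(cds, 3)
  }
}

#' Build a tandem array genome from a ribotype set
#'
#' Concatenates `array_copies` repeat units (CDS + IGS) between two random
#' flanks. Realized per-ribotype copy numbers follow the configured
#' proportions by largest-remainder rounding; copy order is a seeded
#' shuffle (tandem arrays in vivo may be interleaved, and order must not
#' affect downstream results). A configured fraction of copies is
#' pseudogenized by mutating their CDS.
#'
#' @param ribotypes named character vector of IGS sequences (from
#'   [generate_ribotype_set()]).
#' @param truth the partial truth set from [generate_ribotype_set()]; its
#'   `array_layout` is filled in.
#' @param config a [sim_config()].
#' @param ancestral_cds the CDS sequence shared by all copies.
#' @return a list with `array` (the genome string), `truth` (completed
#'   truth set, including per-copy CDS variants and 1-based unit start
#'   coordinates) and `unit_starts`.
#' @export
build_tandem_array <- function(ribotypes, truth, config, ancestral_cds) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 2))
  n <- length(ribotypes)
  counts <- apportion_copies(truth$true_proportions, config$array_copies)
  if (any(counts == 0)) {
    stop("proportions x array_copies round to zero copies for ribotype(s): ",
         paste(names(ribotypes)[counts == 0], collapse = ", "))
  }
  ids <- rep(names(ribotypes), counts)
  ids <- sample(ids)                       # seeded shuffle of copy order
  n_ps <- round(config$pseudogene_fraction * config$array_copies)
  ps_flag <- rep(FALSE, config$array_copies)
  if (n_ps > 0) ps_flag[sample(config$array_copies, n_ps)] <- TRUE

  cds_variants <- character(config$array_copies)
  units <- character(config$array_copies)
  for (i in seq_len(config$array_copies)) {
    cds_i <- if (ps_flag[i]) pseudogenize_cds(ancestral_cds) else ancestral_cds
    cds_variants[i] <- cds_i
    units[i] <- paste0(cds_i, ribotypes[[ids[i]]])
  }
  flank5 <- random_dna(config$flank_length, 0.5)
  flank3 <- random_dna(config$flank_length, 0.5)
  array <- paste0(flank5, paste(units, collapse = ""), flank3)
  unit_starts <- config$flank_length + 1 +
    c(0, cumsum(nchar(units)))[seq_len(config$array_copies)]

  truth$array_layout <- data.frame(
    copy_index = seq_len(config$array_copies),
    ribotype_id = ids,
    pseudogene = ps_flag,
    start = unit_starts,
    width = nchar(units),
    stringsAsFactors = FALSE
  )
  truth$cds_variants <- cds_variants
  list(array = array, truth = truth, unit_starts = unit_starts)
}
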