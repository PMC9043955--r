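#' Simulation configuration for synthetic 5S rDNA tandem arrays
#'
#' Bundles every knob of the synthetic-data generator: the repeat-unit
#' anatomy (conserved CDS + variable IGS), the ribotype mixture, the
#' mutation plan per derived ribotype, pseudogenization, array geometry and
#' the read-sampling model. Defaults emulate a typical diploid *Solanum*-like
#' 5S locus: a 120-bp CDS, a ~210-bp IGS (the common 190-220 bp range),
#' ribotypes at geometrically decreasing proportions, and ~97% intragenomic
#' IGS identity (6 SNPs per derived ribotype over 210 bp).
#'
#' @param seed integer seed driving every random choice.
#' @param cds_length CDS length in bp.
#' @param igs_length ancestral IGS length in bp.
#' @param igs_gc target GC fraction of the ancestral IGS.
#' @param n_ribotypes number of ribotypes in the mixture (ribotype 1 is the
#'   ancestral sequence).
#' @param proportions numeric vector of genomic proportions summing to 1;
#'   default is a geometric series (each ribotype half the previous one).
#' @param snps_per_ribotype number of substitutions separating each derived
#'   ribotype from the ancestor.
#' @param indel_spec optional list of indel plans, each a list with elements
#'   `length` (bp), `type` ("insertion" or "deletion") and optionally
#'   `ribotype` (index 2..n; unassigned entries are distributed round-robin
#'   over the derived ribotypes).
#' @param duplication_spec optional internal tandem-duplication plan: a list
#'   with `unit` (duplicated segment length, bp), `copies` (total copy
#'   number), `cds_part` (bp of the segment overlapping the CDS 3' end),
#'   `snps` and `indel` (divergence planted between the copies, in the
#'   IGS-derived portion only) and optionally `ribotype` (default: the last
#'   ribotype).
#' @param pseudogene_fraction fraction of array copies carrying a disabled
#'   CDS (a 1-2 bp indel or 3 substitutions).
#' @param array_copies number of repeat units in the tandem array.
#' @param flank_length length of random non-rDNA sequence on each side.
#' @param background_read_fraction fraction of simulated reads drawn from a
#'   random non-rDNA background instead of the array.
#' @param coverage mean read depth over the array.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate.
#' @param layout "single" or "paired".
#' @param insert_size fragment length for paired layout.
#' @param plant_promoter_motifs place canonical Pol III promoter/terminator
#'   motifs in the ancestral IGS (TTTAATA at -30, GC at -14 and -12, GA at
#'   -3, T at -1, TTTTT at the IGS 5' end) and protect them from planted
#'   mutations, as these motifs are conserved in real spacers.
#' @param max_regen_attempts retries when a mutation collision makes two
#'   ribotypes identical.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       cds_length = 120,
                       igs_length = 210,
                       igs_gc = 0.5,
                       n_ribotypes = 3,
                       proportions = NULL,
                       snps_per_ribotype = 6,
                       indel_spec = NULL,
                       duplication_spec = NULL,
                       pseudogene_fraction = 0.1,
                       array_copies = 20,
                       flank_length = 300,
                       background_read_fraction = 0,
                       coverage = 100,
                       read_length = 150,
                       error_rate = 0,
                       layout = c("single", "paired"),
                       insert_size = 400,
                       plant_promoter_motifs = TRUE,
                       max_regen_attempts = 20) {
  layout <- match.arg(layout)
  if (is.null(proportions)) {
    w <- 0.5^(seq_len(n_ribotypes) - 1)
    proportions <- w / sum(w)
  }
  cfg <- structure(list(
    seed = as.integer(seed),
    cds_length = as.integer(cds_length),
    igs_length = as.integer(igs_length),
    igs_gc = igs_gc,
    n_ribotypes = as.integer(n_ribotypes),
    proportions = proportions,
    snps_per_ribotype = as.integer(snps_per_ribotype),
    indel_spec = indel_spec,
    duplication_spec = duplication_spec,
    pseudogene_fraction = pseudogene_fraction,
    array_copies = as.integer(array_copies),
    flank_length = as.integer(flank_length),
    background_read_fraction = background_read_fraction,
    coverage = coverage,
    read_length = as.integer(read_length),
    error_rate = error_rate,
    layout = layout,
    insert_size = as.integer(insert_size),
    plant_promoter_motifs = isTRUE(plant_promoter_motifs),
    max_regen_attempts = as.integer(max_regen_attempts)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$cds_length > 0, cfg$igs_length > 0, cfg$array_copies >= 1,
    cfg$flank_length >= 0, cfg$read_length > 0, cfg$coverage > 0,
    cfg$n_ribotypes >= 1, cfg$snps_per_ribotype >= 0
  )
  fr <- c(cfg$igs_gc, cfg$pseudogene_fraction, cfg$background_read_fraction,
          cfg$error_rate)
  if (any(fr < 0 | fr > 1)) {
    stop("fractions (igs_gc, pseudogene_fraction, background_read_fraction, ",
         "error_rate) must lie in [0, 1]")
  }
  if (length(cfg$proportions) != cfg$n_ribotypes) {
    stop("proportions must have one entry per ribotype")
  }
  if (abs(sum(cfg$proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (tolerance 1e-9)")
  }
  if (any(cfg$proportions < 0 | cfg$proportions > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("5S rDNA array simulation config\n")
  cat(sprintf("  seed %d | unit %d+%d bp | %d ribotypes | %d copies\n",
              x$seed, x$cds_length, x$igs_length, x$n_ribotypes,
              x$array_copies))
  cat(sprintf("  proportions: %s\n",
              paste(sprintf("%.3f", x$proportions), collapse = " ")))
  cat(sprintf("  reads: %s %d bp, %gx, error %g\n", x$layout, x$read_length,
              x$coverage, x$error_rate))
  invisible(x)
}
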