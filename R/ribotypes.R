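#' CDS integrity (pseudogene detection) configuration
#'
#' A repeat whose CDS carries indels or several substitutions is treated as
#' a pseudogene and excluded from the intact catalog. "Several" is
#' operationalized as >= 3 substitutions by default, since a normal 5S CDS
#' copy carries no more than about two mutations relative to its consensus.
#'
#' @param pseudo_snp_threshold substitution count at which a CDS is called
#'   pseudogenized.
#' @param any_indel_is_pseudogene whether a single CDS indel suffices.
#' @export
integrity_config <- function(pseudo_snp_threshold = 3L,
                             any_indel_is_pseudogene = TRUE) {
  if (pseudo_snp_threshold < 1L) stop("pseudo_snp_threshold must be >= 1")
  structure(list(pseudo_snp_threshold = as.integer(pseudo_snp_threshold),
                 any_indel_is_pseudogene = isTRUE(any_indel_is_pseudogene)),
            class = "integrity_config")
}

#' Classification thresholds for ribotype abundance classes
#'
#' Major: relative genomic content >= `major_min` (default 10% of all IGS
#' copies); minor: below major but >= `minor_min` (default 5%); rare:
#' below `minor_min`.
#'
#' @param major_min major-class threshold (fraction).
#' @param minor_min minor-class threshold (fraction).
#' @export
classification_config <- function(major_min = 0.10, minor_min = 0.05) {
  if (!(0 < minor_min && minor_min < major_min && major_min < 1)) {
    stop("need 0 < minor_min < major_min < 1")
  }
  structure(list(major_min = major_min, minor_min = minor_min),
            class = "classification_config")
}

# global alignment of two sequences; returns the two gapped rows
align_global <- function(a, b, match = 1, mismatch = -1,
                         gap_open = 2, gap_ext = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE),
    gapOpening = gap_open, gapExtension = gap_ext
  )
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

# mutation report from a gapped pair: substitutions and indel runs
alignment_mutations <- function(qa, qb) {
  ca <- seq_chars(qa)
  cb <- seq_chars(qb)
  gap_a <- ca == "-"
  gap_b <- cb == "-"
  subs <- which(!gap_a & !gap_b & ca != cb)
  gaps <- gap_a | gap_b
  r <- rle(gaps)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  indels <- data.frame(
    column = starts[r$values],
    length = r$lengths[r$values],
    type = ifelse(gap_a[starts[r$values]], "insertion", "deletion"),
    stringsAsFactors = FALSE
  )
  list(substitution_columns = subs, indels = indels)
}

#' Check the CDS of a repeat unit against the consensus
#'
#' Globally aligns the unit's CDS to the consensus and flags the unit as a
#' pseudogene if the alignment contains any indel (when enabled) or at
#' least `pseudo_snp_threshold` substitutions.
#'
#' @param cds_seq the unit's CDS sequence (or a one-row `repeat_units`).
#' @param cds_consensus consensus CDS.
#' @param config an [integrity_config()].
#' @return a list: `pseudogene` flag, `n_substitutions`, `indels`
#'   (data.frame of alignment column, length, type), `identity` (percent
#'   over alignment columns).
#' @export
check_cds_integrity <- function(cds_seq, cds_consensus,
                                config = integrity_config()) {
  if (is.data.frame(cds_seq)) cds_seq <- cds_seq$cds_seq[1]
  if (!nchar(cds_consensus)) stop("empty CDS consensus")
  al <- align_global(cds_seq, cds_consensus)
  mut <- alignment_mutations(al$a, al$b)
  ncol_aln <- nchar(al$a)
  n_match <- sum(seq_chars(al$a) == seq_chars(al$b))
  identity <- 100 * n_match / ncol_aln
  if (identity < 50) {
    stop("sequence is not a recognizable CDS copy (alignment identity ",
         sprintf("%.1f", identity), "% < 50%)")
  }
  n_sub <- length(mut$substitution_columns)
  pseudo <- (config$any_indel_is_pseudogene && nrow(mut$indels) > 0) ||
    n_sub >= config$pseudo_snp_threshold
  list(pseudogene = pseudo, n_substitutions = n_sub, indels = mut$indels,
       substitution_columns = mut$substitution_columns, identity = identity)
}

# column-majority consensus over equal-length sequences (modal length
# subset), ties broken alphabetically
majority_consensus <- function(seqs) {
  lens <- nchar(seqs)
  modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  seqs <- seqs[lens == modal]
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  paste(apply(mat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    cand <- names(tab)[tab == max(tab)]
    sort(cand)[1]
  }), collapse = "")
}

#' Deduplicate repeat units into a ribotype catalog
#'
#' The CDS consensus is the column-majority over units (computed before
#' exclusion, from the modal-length CDS set); units failing
#' [check_cds_integrity()] are set aside as pseudogene records. Every
#' distinct IGS sequence among the intact units - any difference, whether
#' substitution or indel, separates - becomes one ribotype. Ordering is by
#' descending source coverage, then sequence.
#'
#' @param units a `repeat_units` data.frame.
#' @param config an [integrity_config()].
#' @return a list of class `ribotype_catalog`: `catalog` (data.frame: id,
#'   igs_seq, representative unit columns, pseudogene = FALSE),
#'   `pseudogenes` (analogous records), `cds_consensus`.
#' @export
dedup_ribotypes <- function(units, config = integrity_config()) {
  if (!nrow(units)) {
    warning("no repeat units supplied; empty catalog")
    return(structure(list(catalog = units, pseudogenes = units,
                          cds_consensus = NA_character_),
                     class = "ribotype_catalog"))
  }
  consensus <- majority_consensus(units$cds_seq)
  integ <- lapply(units$cds_seq, function(s) {
    tryCatch(check_cds_integrity(s, consensus, config),
             error = function(e) NULL)
  })
  rejected <- vapply(integ, is.null, logical(1))
  if (any(rejected)) {
    warning(sum(rejected), " unit(s) rejected as non-CDS (identity < 50%)")
    units <- units[!rejected, , drop = FALSE]
    integ <- integ[!rejected]
  }
  pseudo <- vapply(integ, `[[`, logical(1), "pseudogene")

  weight_of <- function(df) {
    w <- df$flow_weight
    ifelse(is.na(w), ifelse(is.na(df$mean_coverage), 0, df$mean_coverage), w)
  }
  make_catalog <- function(df) {
    if (!nrow(df)) {
      df$id <- character(0)
      return(df)
    }
    ord <- order(-weight_of(df), df$igs_seq)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df$igs_seq), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  intact <- make_catalog(units[!pseudo, , drop = FALSE])
  pseudos <- make_catalog(units[pseudo, , drop = FALSE])
  if (nrow(intact)) intact$id <- sprintf("RT%02d", seq_len(nrow(intact)))
  if (nrow(pseudos)) pseudos$id <- sprintf("PS%02d", seq_len(nrow(pseudos)))
  if (!nrow(intact)) warning("zero intact units: empty ribotype catalog")
  structure(list(catalog = intact, pseudogenes = pseudos,
                 cds_consensus = consensus),
            class = "ribotype_catalog")
}

#' @export
print.ribotype_catalog <- function(x, ...) {
  cat(sprintf("ribotype_catalog: %d intact ribotypes, %d pseudogene records\n",
              nrow(x$catalog), nrow(x$pseudogenes)))
  invisible(x)
}

#' Drop catalog entries without uniquely-supporting reads
#'
#' A mosaic (chimeric) assembly artifact combines variants of two real
#' ribotypes, so every read placement it attracts is matched equally well
#' by one of its sources; a real ribotype, by contrast, has reads covering
#' its private variant columns that map to it strictly better than to any
#' other reference. Entries with fewer than `min_unique` strictly-best
#' read placements are removed from the intact catalog. Unlike the
#' abundance map-back, validation maps against the *undoubled* units: a
#' doubled reference presents a wrap junction, and in an interleaved
#' array the junction of a mosaic can coincide with a real boundary
#' between two adjacent units of its source ribotypes.
#'
#' @param catalog a `ribotype_catalog`.
#' @param reads a `read_library` (the complete or filtered library).
#' @param max_mismatches mapping tolerance, as in [estimate_abundance()].
#' @param min_unique required number of strictly-best placements.
#' @return the catalog with unsupported intact entries removed (recorded
#'   in attribute `dropped`).
#' @export
drop_unsupported_ribotypes <- function(catalog, reads, max_mismatches = 2L,
                                       min_unique = 2L) {
  cat_df <- catalog$catalog
  if (nrow(cat_df) < 2L) return(catalog)
  refs <- cat_df$unit_seq
  rd <- c(reads$reads, reads$reads2)
  mp <- cpp_map_reads(rd, refs, as.integer(max_mismatches))
  mm <- mp$mismatch
  unique_hits <- integer(nrow(cat_df))
  best <- do.call(pmin, as.data.frame(mm))
  for (i in which(best <= max_mismatches)) {
    js <- which(mm[i, ] == best[i])
    if (length(js) == 1L) unique_hits[js] <- unique_hits[js] + 1L
  }
  keep <- unique_hits >= min_unique
  if (all(keep)) return(catalog)
  dropped <- cat_df[!keep, , drop = FALSE]
  catalog$catalog <- cat_df[keep, , drop = FALSE]
  if (nrow(catalog$catalog)) {
    catalog$catalog$id <- sprintf("RT%02d", seq_len(nrow(catalog$catalog)))
  }
  rownames(catalog$catalog) <- NULL
  attr(catalog, "dropped") <- dropped
  message(nrow(dropped), " catalog entr(y/ies) without unique read support removed")
  catalog
}

#' Estimate relative genomic content of each ribotype by read map-back
#'
#' Each reference is the representative unit doubled head-to-tail so
#' junction-spanning reads place; reads are aligned to every reference on
#' both strands without gaps, tolerating at most `max_mismatches`
#' mismatches. Each read's unit weight is split equally among the
#' references achieving its minimum mismatch count, and only reads whose
#' best placement overlaps the IGS by at least `min_igs_overlap` bp
#' contribute (CDS-only reads are shared by all ribotypes and carry no
#' information). Relative content is the ribotype's weight over the total
#' contributing weight.
#'
#' Reads that tie across the entire catalog are likewise excluded: like
#' CDS-only reads, they carry no information about relative content and
#' would only pull every estimate toward uniformity.
#'
#' @param catalog a `ribotype_catalog` (intact ribotypes are used).
#' @param filtered_reads a `read_library`.
#' @param max_mismatches mapping mismatch tolerance (default 2).
#' @param min_igs_overlap minimum IGS overlap in bp (default 20).
#' Pseudogenized repeats are excluded from the catalog, but the IGS copies
#' they carry still count among "all IGS copies in the genome": pseudogene
#' records therefore serve as additional mapping references, and each
#' one's weight is folded into the catalog ribotype with the identical
#' IGS (weight on a pseudogene reference whose IGS matches no catalog
#' entry is reported as unassigned).
#'
#' @return an `abundance_table` data.frame: id, assigned_weight,
#'   relative_content, abundance_class ("unset"), plus attributes
#'   `unassigned_weight` and `total_weight`.
#' @export
estimate_abundance <- function(catalog, filtered_reads, max_mismatches = 2L,
                               min_igs_overlap = 20L) {
  if (inherits(catalog, "ribotype_catalog")) {
    cat_df <- catalog$catalog
    ps_df <- catalog$pseudogenes
  } else {
    cat_df <- catalog
    ps_df <- catalog[0, , drop = FALSE]
  }
  if (!nrow(cat_df)) stop("empty ribotype catalog")
  ref_df <- rbind(cat_df[c("unit_seq", "cds_seq", "igs_seq")],
                  ps_df[c("unit_seq", "cds_seq", "igs_seq")])
  # fold group: catalog row index sharing the IGS; 0 when none does
  group <- c(seq_len(nrow(cat_df)),
             match(ps_df$igs_seq, cat_df$igs_seq, nomatch = 0L))
  refs <- paste0(ref_df$unit_seq, ref_df$unit_seq)
  unit_len <- nchar(ref_df$unit_seq)
  cds_len <- nchar(ref_df$cds_seq)
  reads <- c(filtered_reads$reads, filtered_reads$reads2)
  n <- length(reads)
  mp <- cpp_map_reads(reads, refs, as.integer(max_mismatches))

  best <- do.call(pmin, as.data.frame(mp$mismatch))
  placed <- best <= max_mismatches
  ref_weights <- numeric(length(refs))
  contributing <- 0
  unassigned <- 0
  rl <- nchar(reads)
  all_groups <- seq_len(nrow(cat_df))
  for (i in which(placed)) {
    js <- which(mp$mismatch[i, ] == best[i])
    # IGS overlap of the best placement on each tied reference
    ok <- vapply(js, function(j) {
      s <- mp$pos[i, j]
      e2 <- s + rl[i] - 1L
      igs1 <- c(cds_len[j] + 1L, unit_len[j])
      igs2 <- c(unit_len[j] + cds_len[j] + 1L, 2L * unit_len[j])
      ov <- max(0L, min(e2, igs1[2]) - max(s, igs1[1]) + 1L) +
        max(0L, min(e2, igs2[2]) - max(s, igs2[1]) + 1L)
      ov >= min_igs_overlap
    }, logical(1))
    js <- js[ok]
    tie_groups <- unique(group[js])
    if (!length(js) ||
        (nrow(cat_df) > 1L && setequal(tie_groups, all_groups))) {
      # no informative placement, or a tie across the whole catalog
      unassigned <- unassigned + 1
      next
    }
    ref_weights[js] <- ref_weights[js] + 1 / length(js)
    contributing <- contributing + 1
  }
  unassigned <- unassigned + sum(!placed)
  weights <- vapply(all_groups, function(g) sum(ref_weights[group == g]),
                    numeric(1))
  unassigned <- unassigned + sum(ref_weights[group == 0L])
  rel <- if (contributing > 0) weights / sum(weights) else {
    warning("no read contributes to abundance estimation; contents set to 0")
    rep(0, length(weights))
  }
  out <- data.frame(id = cat_df$id,
                    igs_seq = cat_df$igs_seq,
                    assigned_weight = weights,
                    relative_content = rel,
                    abundance_class = "unset",
                    stringsAsFactors = FALSE)
  class(out) <- c("abundance_table", "data.frame")
  attr(out, "total_weight") <- sum(weights)
  attr(out, "unassigned_weight") <- unassigned
  attr(out, "n_reads") <- n
  out
}

#' Classify ribotypes as major, minor or rare
#'
#' Major: content >= `major_min`; minor: `minor_min` <= content <
#' `major_min`; rare otherwise. The summary reports class counts and the
#' cumulative fraction of repeats carried by major + minor ribotypes.
#'
#' @param table an `abundance_table`.
#' @param config a [classification_config()].
#' @return the table with `abundance_class` filled, plus attribute
#'   `summary` (list: counts per class, cumulative_major_minor).
#' @export
classify_abundance <- function(table, config = classification_config()) {
  cls <- ifelse(table$relative_content >= config$major_min, "major",
                ifelse(table$relative_content >= config$minor_min, "minor",
                       "rare"))
  table$abundance_class <- cls
  attr(table, "summary") <- list(
    n_major = sum(cls == "major"),
    n_minor = sum(cls == "minor"),
    n_rare = sum(cls == "rare"),
    cumulative_major_minor = sum(table$relative_content[cls != "rare"])
  )
  table
}
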