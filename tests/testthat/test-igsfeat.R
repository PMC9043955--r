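test_that("GC content follows its definition and ignores N", {
  expect_equal(gc_content("GGCC"), 100.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GGCCNN"), 100.0)
  expect_equal(gc_content("GCAT"), 50.0)
  expect_error(gc_content("NNN"), "only N")
  expect_error(gc_content(""), "empty")
  expect_error(gc_content("ACGX"), "invalid base")
  # invariant under reverse complement
  set.seed(12)
  for (i in 1:10) {
    s <- random_dna(sample(50:300, 1), runif(1, 0.3, 0.7))
    expect_equal(gc_content(s), gc_content(revcomp(s)))
  }
})

test_that("pairwise identity is symmetric, 100 on self, and optimal on tiny cases", {
  set.seed(13)
  a <- random_dna(80, 0.5)
  expect_equal(pairwise_identity(a, a), 100)
  b <- mutate_snps(a, 8)
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  # tiny-case oracle: exhaustive enumeration of all gapped alignments
  for (pair in list(c("ACGT", "TGCA"), c("ACGT", "ACG"), c("AAAA", "ATA"))) {
    ours <- pairwise_identity(pair[1], pair[2])
    oracle <- oracle_global_alignments(pair[1], pair[2])
    expect_gte(ours, oracle$identities[1] - 1e-9)
    expect_lte(ours, oracle$identities[2] + 1e-9)
  }
})

test_that("long-indel masking removes a long deletion from the identity", {
  set.seed(14)
  a <- random_dna(200, 0.5)
  b <- paste0(substr(a, 1, 95), substr(a, 106, 200))  # 10-bp deletion
  unmasked <- pairwise_identity(a, b)
  expect_lt(unmasked, 100)
  masked <- pairwise_identity(a, b, similarity_options(mask_long_indels = TRUE))
  expect_equal(masked, 100)
  # a short (<= threshold) indel is not masked
  c2 <- paste0(substr(a, 1, 97), substr(a, 101, 200))  # 3-bp deletion
  masked_short <- pairwise_identity(a, c2,
                                    similarity_options(mask_long_indels = TRUE))
  expect_lt(masked_short, 100)
})

test_that("similarity range reports the extremes of the pairwise matrix", {
  set.seed(15)
  a <- random_dna(150, 0.5)
  expect_equal(similarity_range(c(a, a))$min, 100)
  seqs <- c(a, mutate_snps(a, 3), mutate_snps(a, 25))
  sr <- similarity_range(seqs)
  direct <- c(pairwise_identity(seqs[1], seqs[2]),
              pairwise_identity(seqs[1], seqs[3]),
              pairwise_identity(seqs[2], seqs[3]))
  expect_equal(sr$min, min(direct))
  expect_equal(sr$max, max(direct))
  expect_true(isSymmetric(sr$matrix))
  expect_warning(similarity_range(a), "fewer than 2")
})

test_that("exact and diverged tandem duplications are called correctly", {
  set.seed(16)
  x <- random_dna(50, 0.5)
  call <- find_tandem_duplication(paste0(random_dna(40, 0.5), x, x,
                                         random_dna(40, 0.5)))
  expect_false(is.null(call))
  expect_equal(call$unit_length, 50)
  expect_equal(call$n_copies, 2)
  expect_equal(call$snps_between_copies, 0)

  x2 <- mutate_snps(x, 2)
  call2 <- find_tandem_duplication(paste0(random_dna(40, 0.5), x, x2,
                                          random_dna(40, 0.5)))
  expect_equal(call2$snps_between_copies, 2)
  expect_equal(call2$unit_length, 50)
})

test_that("sequences without long repeats yield no duplication call", {
  set.seed(17)
  for (i in 1:5) {
    s <- random_dna(250, 0.5)
    # brute-force oracle: no repeated substring of length >= 30
    wins <- seq_windows(s, 30)
    if (anyDuplicated(wins)) next
    expect_null(find_tandem_duplication(s, min_unit = 30))
  }
})

test_that("the eggplant-type long spacer anatomy is recovered exactly", {
  cfg <- sim_config(seed = 77, n_ribotypes = 2, proportions = c(0.5, 0.5),
                    snps_per_ribotype = 0,
                    duplication_spec = list(unit = 146, copies = 2,
                                            cds_part = 32, snps = 6,
                                            indel = 8))
  rs <- generate_ribotype_set(cfg)
  unit <- paste0(rs$ancestral_cds, rs$ribotypes[["R2"]])
  call <- find_tandem_duplication(unit, cds_length = 120)
  expect_false(is.null(call))
  expect_equal(call$unit_length, 146)
  expect_equal(call$n_copies, 2)
  expect_equal(call$snps_between_copies, 6)
  expect_equal(call$indels_between_copies, 8)
  expect_equal(call$cds_derived_length, 32, tolerance = 0.1)
  expect_equal(call$igs_derived_length, 114, tolerance = 0.1)
})

test_that("promoter and terminator motifs are reported at planted offsets", {
  cfg <- sim_config(seed = 88)
  rs <- generate_ribotype_set(cfg)
  rep_ <- scan_promoter_motifs(rs$ancestral_igs)
  expect_true(all(rep_$found))
  expect_equal(rep_$mismatches, rep(0L, 6))
  expect_equal(rep_$offset[rep_$name == "tata_box"], -30L)
  expect_equal(rep_$offset[rep_$name == "gc_m14"], -14L)
  expect_equal(rep_$offset[rep_$name == "gc_m12"], -12L)
  expect_equal(rep_$offset[rep_$name == "ga_m3"], -3L)
  expect_equal(rep_$offset[rep_$name == "pyrimidine_m1"], -1L)
  expect_equal(rep_$offset[rep_$name == "terminator"], 1L)
})

test_that("motif reports on random spacers agree with an exhaustive scan", {
  set.seed(18)
  cat_ <- motif_catalog()
  for (i in 1:5) {
    igs <- random_dna(210, 0.5)
    rep_ <- scan_promoter_motifs(igs, cat_)
    L <- nchar(igs)
    for (r in seq_len(nrow(cat_))) {
      entry <- cat_[r, ]
      m <- nchar(entry$pattern)
      if (entry$region == "igs_5prime") {
        offs <- seq_len(min(15, L) - m + 1)
        hits <- vapply(offs, function(s) {
          motif_mismatches(substr(igs, s, s + m - 1), entry$pattern) <=
            entry$max_mismatches
        }, logical(1))
      } else {
        offs <- (entry$expected_offset - entry$window):
          (entry$expected_offset + entry$window)
        offs <- offs[L + offs + 1 >= 1 & L + offs + m <= L]
        hits <- vapply(offs, function(o) {
          motif_mismatches(substr(igs, L + o + 1, L + o + m),
                           entry$pattern) <= entry$max_mismatches
        }, logical(1))
      }
      expect_equal(rep_$found[r], any(hits))
    }
  }
})

test_that("a short IGS reports upstream entries absent with a reason", {
  rep_ <- scan_promoter_motifs("TTTTTACGT")
  expect_false(rep_$found[rep_$name == "tata_box"])
  expect_match(rep_$reason[rep_$name == "tata_box"], "shorter")
})

test_that("CDS divergence counts substitutions, listing indels apart", {
  set.seed(19)
  cds <- random_dna(120, 0.55)
  expect_equal(cds_divergence(cds, cds)$n_substitutions, 0)
  expect_equal(cds_divergence(mutate_snps(cds, 2), cds)$n_substitutions, 2)
  del <- paste0(substr(cds, 1, 59), substr(cds, 63, 120))
  res <- cds_divergence(del, cds)
  expect_equal(sum(res$indels$length), 3)
})

test_that("structural-variant decision table covers all presence combinations", {
  combos <- expand.grid(indel_I = c(TRUE, FALSE), indel_II = c(TRUE, FALSE),
                        GC_DUP = c(TRUE, FALSE))
  labels <- apply(combos, 1, function(p) {
    sv_label(setNames(as.logical(p), names(combos)))
  })
  expected <- apply(combos, 1, function(p) {
    if (p[1] && p[2]) "A"
    else if (p[1] && !p[2]) "B"
    else if (!p[1] && p[2] && !p[3]) "C"
    else if (!p[1] && p[2] && p[3]) "D"
    else "unclassified"
  })
  expect_identical(labels, expected)
  expect_setequal(unique(labels), c("A", "B", "C", "D", "unclassified"))
})

test_that("reference-derived spacers classify to their own structural variant", {
  sig <- load_sv_signatures()
  ungap <- function(x) gsub("-", "", x, fixed = TRUE)
  expect_identical(classify_sv(ungap(sig$alignment[["ref_SVA"]]), sig)$label, "A")
  expect_identical(classify_sv(ungap(sig$alignment[["ref_SVB"]]), sig)$label, "B")
  expect_identical(classify_sv(ungap(sig$alignment[["ref_SVC"]]), sig)$label, "C")
  expect_identical(classify_sv(ungap(sig$alignment[["ref_SVD"]]), sig)$label, "D")
  # deleting indel II from the B exemplar leaves neither indel: unclassified
  b <- ungap(sig$alignment[["ref_SVB"]])
  a_cols <- sig$segments[["indel_I"]]
  b_noI <- paste0(substr(b, 1, a_cols[1] - 1), substr(b, a_cols[2] + 1, nchar(b)))
  expect_identical(classify_sv(b_noI, sig)$label, "unclassified")
  set.seed(20)
  expect_error(classify_sv(random_dna(60, 0.5), sig), "not a Petota-like")
})
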