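make_unit_df <- function(cds, igs, coverage = 10, weight = NA_real_) {
  data.frame(unit_seq = paste0(cds, igs), cds_seq = cds, igs_seq = igs,
             igs_start = nchar(cds), igs_end = nchar(cds) + nchar(igs),
             source_contig = "test", mean_coverage = coverage,
             flow_weight = weight, stringsAsFactors = FALSE)
}

test_that("CDS integrity flags indels and several substitutions", {
  set.seed(9)
  cds <- random_dna(120, 0.55)
  expect_false(check_cds_integrity(cds, cds)$pseudogene)

  del1 <- paste0(substr(cds, 1, 59), substr(cds, 61, 120))
  res <- check_cds_integrity(del1, cds)
  expect_true(res$pseudogene)
  expect_equal(sum(res$indels$length), 1)

  two_snp <- mutate_snps(cds, 2)
  res2 <- check_cds_integrity(two_snp, cds)
  expect_false(res2$pseudogene)
  expect_equal(res2$n_substitutions, 2)

  three_snp <- mutate_snps(cds, 3)
  expect_true(check_cds_integrity(three_snp, cds)$pseudogene)
  # configurable threshold
  expect_false(check_cds_integrity(
    three_snp, cds, integrity_config(pseudo_snp_threshold = 5))$pseudogene)

  expect_error(check_cds_integrity(random_dna(120, 0.5), cds),
               "not a recognizable CDS")
})

test_that("deduplication separates on any IGS difference and sidelines pseudogenes", {
  set.seed(10)
  cds <- random_dna(120, 0.55)
  igs <- random_dna(210, 0.5)
  igs_snp <- mutate_snps(igs, 1)
  same <- rbind(make_unit_df(cds, igs, 10), make_unit_df(cds, igs, 5))
  cat1 <- dedup_ribotypes(same)
  expect_equal(nrow(cat1$catalog), 1L)

  two <- rbind(make_unit_df(cds, igs), make_unit_df(cds, igs_snp))
  cat2 <- dedup_ribotypes(two)
  expect_equal(nrow(cat2$catalog), 2L)

  # an IGS indel also separates
  igs_del <- paste0(substr(igs, 1, 99), substr(igs, 103, 210))
  cat3 <- dedup_ribotypes(rbind(make_unit_df(cds, igs),
                                make_unit_df(cds, igs_del)))
  expect_equal(nrow(cat3$catalog), 2L)

  cds_del <- paste0(substr(cds, 1, 49), substr(cds, 51, 120))
  three <- rbind(make_unit_df(cds, igs, 10), make_unit_df(cds, igs_snp, 8),
                 make_unit_df(cds_del, igs, 6))
  cat4 <- dedup_ribotypes(three)
  expect_equal(nrow(cat4$catalog), 2L)
  expect_equal(nrow(cat4$pseudogenes), 1L)
  # ordering: descending coverage
  expect_identical(cat4$catalog$igs_seq, c(igs, igs_snp))
})

test_that("abundance of a single ribotype is 1 and ties split the unit weight", {
  sim <- quick_sim(seed = 43, n_ribotypes = 1, proportions = 1,
                   snps_per_ribotype = 0, pseudogene_fraction = 0,
                   error_rate = 0)
  unit <- paste0(sim$rs$ancestral_cds, sim$rs$ribotypes[[1]])
  cat1 <- structure(list(
    catalog = make_unit_df(sim$rs$ancestral_cds, sim$rs$ribotypes[[1]]),
    pseudogenes = make_unit_df(sim$rs$ancestral_cds, "X")[0, ],
    cds_consensus = sim$rs$ancestral_cds), class = "ribotype_catalog")
  cat1$catalog$id <- "RT01"
  ab <- estimate_abundance(cat1, sim$lib)
  expect_equal(ab$relative_content, 1.0)

  # three references; a read matching two of them equally takes 0.5 each
  set.seed(11)
  cds <- random_dna(120, 0.55)
  igs_a <- random_dna(210, 0.5)
  igs_b <- igs_a
  substr(igs_b, 200, 200) <- if (substr(igs_a, 200, 200) == "A") "G" else "A"
  igs_c <- mutate_snps(igs_a, 30)
  cat3 <- structure(list(
    catalog = rbind(make_unit_df(cds, igs_a), make_unit_df(cds, igs_b),
                    make_unit_df(cds, igs_c)),
    pseudogenes = make_unit_df(cds, "X")[0, ],
    cds_consensus = cds), class = "ribotype_catalog")
  cat3$catalog$id <- c("A", "B", "C")
  # a read inside the IGS region shared by A and B but diverged in C
  rd <- substr(igs_a, 20, 120)
  lib <- new_read_library(rd, "tie", "single", nchar(rd), 0)
  ab3 <- estimate_abundance(cat3, lib)
  expect_equal(ab3$assigned_weight, c(0.5, 0.5, 0))
})

test_that("classification thresholds and boundaries follow the class rules", {
  tab <- data.frame(id = paste0("R", 1:5),
                    igs_seq = letters[1:5],
                    assigned_weight = c(12, 7, 4, 10, 5),
                    relative_content = c(0.12, 0.07, 0.04, 0.10, 0.05),
                    abundance_class = "unset", stringsAsFactors = FALSE)
  out <- classify_abundance(tab)
  expect_identical(out$abundance_class,
                   c("major", "minor", "rare", "major", "minor"))
  s <- attr(out, "summary")
  expect_equal(s$n_major + s$n_minor + s$n_rare, nrow(tab))
  expect_equal(s$cumulative_major_minor,
               sum(tab$relative_content[c(1, 2, 4, 5)]))

  tab2 <- data.frame(id = paste0("R", 1:3), igs_seq = letters[1:3],
                     assigned_weight = c(6, 3, 1),
                     relative_content = c(0.6, 0.3, 0.1),
                     abundance_class = "unset", stringsAsFactors = FALSE)
  out2 <- classify_abundance(tab2)
  expect_identical(out2$abundance_class, rep("major", 3))
  expect_equal(attr(out2, "summary")$cumulative_major_minor, 1.0)
})

test_that("relative contents sum to one and survive read duplication", {
  sim <- quick_sim(seed = 47, error_rate = 0)
  asm <- run_assembly(sim)
  cat_ <- dedup_ribotypes(asm$units)
  ab <- estimate_abundance(cat_, sim$lib)
  expect_equal(sum(ab$relative_content), 1, tolerance = 1e-9)

  doubled <- sim$lib
  doubled$reads <- c(doubled$reads, doubled$reads)
  doubled$ids <- c(sim$lib$ids, paste0(sim$lib$ids, "_dup"))
  ab2 <- estimate_abundance(cat_, doubled)
  expect_equal(ab2$relative_content, ab$relative_content, tolerance = 1e-12)
})

test_that("mosaic catalog entries without unique read support are dropped", {
  sim <- quick_sim(seed = 53, error_rate = 0)
  asm <- run_assembly(sim)
  cat_ <- dedup_ribotypes(asm$units)
  # forge a mosaic of the two most abundant ribotypes: first half of one,
  # second half of the other
  a <- cat_$catalog$igs_seq[1]
  b <- cat_$catalog$igs_seq[2]
  mosaic <- paste0(substr(a, 1, 105), substr(b, 106, nchar(b)))
  if (mosaic %in% cat_$catalog$igs_seq) skip("mosaic collided with a real ribotype")
  forged <- cat_$catalog[1, ]
  forged$igs_seq <- mosaic
  forged$unit_seq <- paste0(forged$cds_seq, mosaic)
  forged$id <- "FORGED"
  cat_$catalog <- rbind(cat_$catalog, forged)
  cleaned <- suppressMessages(drop_unsupported_ribotypes(cat_, sim$lib))
  expect_false(mosaic %in% cleaned$catalog$igs_seq)
  expect_setequal(cleaned$catalog$igs_seq, unname(sim$rs$ribotypes))
})

test_that("classification_config and integrity_config validate their bounds", {
  expect_error(classification_config(major_min = 0.05, minor_min = 0.10))
  expect_error(integrity_config(pseudo_snp_threshold = 0))
})
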