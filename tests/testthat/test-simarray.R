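test_that("a single ribotype with no mutations reproduces the ancestor", {
  cfg <- sim_config(seed = 3, n_ribotypes = 1, snps_per_ribotype = 0,
                    proportions = 1)
  rs <- generate_ribotype_set(cfg)
  expect_identical(unname(rs$ribotypes[["R1"]]), rs$ancestral_igs)
})

test_that("generation is byte-identical under a fixed seed", {
  a <- quick_sim(seed = 7)
  b <- quick_sim(seed = 7)
  expect_identical(a$rs$ribotypes, b$rs$ribotypes)
  expect_identical(a$arr$array, b$arr$array)
  expect_identical(a$lib$reads, b$lib$reads)
  c <- quick_sim(seed = 8)
  expect_false(identical(a$arr$array, c$arr$array))
})

test_that("ribotypes are pairwise distinct and carry the configured SNPs", {
  cfg <- sim_config(seed = 11, n_ribotypes = 4,
                    proportions = rep(0.25, 4), snps_per_ribotype = 5)
  rs <- generate_ribotype_set(cfg)
  expect_equal(length(unique(rs$ribotypes)), 4)
  for (r in rs$ribotypes) {
    expect_equal(nchar(r), nchar(rs$ancestral_igs))
    d <- sum(seq_chars(r) != seq_chars(rs$ancestral_igs))
    expect_equal(d, 5)
  }
})

test_that("a planted duplication lengthens the ribotype by the unit size", {
  cfg <- sim_config(seed = 5, n_ribotypes = 2, proportions = c(0.5, 0.5),
                    snps_per_ribotype = 0,
                    duplication_spec = list(unit = 146, copies = 2))
  rs <- generate_ribotype_set(cfg)
  expect_equal(nchar(rs$ribotypes[["R2"]]),
               nchar(rs$ancestral_igs) + 146)
  # an 8-bp deletion between copies shortens the extra copy accordingly
  cfg2 <- sim_config(seed = 5, n_ribotypes = 2, proportions = c(0.5, 0.5),
                     snps_per_ribotype = 0,
                     duplication_spec = list(unit = 146, copies = 2,
                                             snps = 6, indel = 8))
  rs2 <- generate_ribotype_set(cfg2)
  expect_equal(nchar(rs2$ribotypes[["R2"]]),
               nchar(rs2$ancestral_igs) + 146 - 8)
})

test_that("array length and copy apportionment follow the configuration", {
  cfg <- sim_config(seed = 2, n_ribotypes = 1, proportions = 1,
                    snps_per_ribotype = 0, array_copies = 10,
                    flank_length = 0, pseudogene_fraction = 0)
  rs <- generate_ribotype_set(cfg)
  arr <- build_tandem_array(rs$ribotypes, rs$truth, cfg, rs$ancestral_cds)
  expect_equal(nchar(arr$array), (120 + 210) * 10)

  cfg2 <- sim_config(seed = 2, n_ribotypes = 2, proportions = c(0.7, 0.3),
                     array_copies = 10, pseudogene_fraction = 0)
  rs2 <- generate_ribotype_set(cfg2)
  arr2 <- build_tandem_array(rs2$ribotypes, rs2$truth, cfg2, rs2$ancestral_cds)
  counts <- table(arr2$truth$array_layout$ribotype_id)
  expect_equal(unname(counts[c("R1", "R2")]), c(7L, 3L),
               ignore_attr = TRUE)

  cfg3 <- sim_config(seed = 2, n_ribotypes = 2, proportions = c(0.99, 0.01),
                     array_copies = 10)
  rs3 <- generate_ribotype_set(cfg3)
  expect_error(build_tandem_array(rs3$ribotypes, rs3$truth, cfg3,
                                  rs3$ancestral_cds),
               "zero copies")
})

test_that("pseudogene copies are flagged and carry a mutated CDS", {
  cfg <- sim_config(seed = 9, pseudogene_fraction = 0.1, array_copies = 20)
  rs <- generate_ribotype_set(cfg)
  arr <- build_tandem_array(rs$ribotypes, rs$truth, cfg, rs$ancestral_cds)
  lay <- arr$truth$array_layout
  expect_equal(sum(lay$pseudogene), 2L)
  for (i in which(lay$pseudogene)) {
    expect_false(arr$truth$cds_variants[i] == rs$ancestral_cds)
  }
  for (i in which(!lay$pseudogene)) {
    expect_identical(arr$truth$cds_variants[i], rs$ancestral_cds)
  }
})

test_that("read count follows coverage and error-free reads are array substrings", {
  sim <- quick_sim(seed = 4, error_rate = 0)
  L <- nchar(sim$arr$array)
  expect_equal(length(sim$lib$reads),
               round(sim$cfg$coverage * L / sim$cfg$read_length))
  # oracle: brute-force substring search on the array and its reverse
  # complement, for a subsample
  rc_arr <- revcomp(sim$arr$array)
  idx <- seq(1, length(sim$lib$reads), by = 97)
  for (i in idx) {
    rd <- sim$lib$reads[i]
    expect_true(grepl(rd, sim$arr$array, fixed = TRUE) ||
                  grepl(rd, rc_arr, fixed = TRUE))
  }
})

test_that("substitution errors match the binomial expectation", {
  cfg <- sim_config(seed = 13, error_rate = 0.01, coverage = 50,
                    read_length = 100, array_copies = 5, flank_length = 0,
                    n_ribotypes = 1, proportions = 1, snps_per_ribotype = 0,
                    pseudogene_fraction = 0)
  rs <- generate_ribotype_set(cfg)
  arr <- build_tandem_array(rs$ribotypes, rs$truth, cfg, rs$ancestral_cds)
  lib <- simulate_reads(arr$array, cfg)
  # recount mismatches against the true source positions
  mm <- 0L
  for (i in seq_along(lib$reads)) {
    src <- substr(arr$array, lib$meta$pos[i], lib$meta$pos[i] + 99)
    if (lib$meta$strand[i] == "-") src <- revcomp(src)
    mm <- mm + sum(seq_chars(lib$reads[i]) != seq_chars(src))
  }
  n_bases <- sum(nchar(lib$reads))
  expected <- n_bases * 0.01
  sigma <- sqrt(n_bases * 0.01 * 0.99)
  expect_true(abs(mm - expected) < 3 * sigma)
})

test_that("realized IGS base composition tracks the target GC", {
  # a single 210-bp draw has binomial sd ~0.035, so the composition bound
  # is checked on the mean over seeds, with motif planting off (the
  # planted AT-rich promoter elements shift GC slightly by design)
  gc <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 100 + s, igs_length = 210, igs_gc = 0.5,
                      plant_promoter_motifs = FALSE)
    rs <- generate_ribotype_set(cfg)
    gc_content(rs$ancestral_igs, percent = FALSE)
  }, numeric(1))
  expect_true(abs(mean(gc) - 0.5) <= 0.03)

  gc6 <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 200 + s, igs_length = 210, igs_gc = 0.6,
                      plant_promoter_motifs = FALSE)
    rs <- generate_ribotype_set(cfg)
    gc_content(rs$ancestral_igs, percent = FALSE)
  }, numeric(1))
  expect_true(abs(mean(gc6) - 0.6) <= 0.03)
})

test_that("truth sets survive a disk round trip", {
  sim <- quick_sim(seed = 21)
  path <- file.path(withr::local_tempdir(), "truth.tsv")
  write_truthset(sim$arr$truth, path)
  back <- read_truthset(path)
  expect_identical(back$ribotype_sequences, sim$arr$truth$ribotype_sequences)
  expect_equal(back$true_proportions, sim$arr$truth$true_proportions)
  expect_equal(back$array_layout$ribotype_id,
               sim$arr$truth$array_layout$ribotype_id)
  expect_equal(back$array_layout$pseudogene,
               sim$arr$truth$array_layout$pseudogene)
  expect_equal(back$seed, sim$arr$truth$seed)
})

test_that("paired layout keeps mates in register and validates insert size", {
  cfg <- sim_config(seed = 6, layout = "paired", insert_size = 400)
  rs <- generate_ribotype_set(cfg)
  arr <- build_tandem_array(rs$ribotypes, rs$truth, cfg, rs$ancestral_cds)
  lib <- simulate_reads(arr$array, cfg)
  expect_equal(length(lib$reads), length(lib$reads2))
  cfg_bad <- sim_config(seed = 6, layout = "paired", insert_size = 100,
                        read_length = 150)
  expect_error(simulate_reads(arr$array, cfg_bad), "insert size")
})

test_that("FASTQ and config files round-trip", {
  sim <- quick_sim(seed = 31, coverage = 5)
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "reads.fastq")
  write_fastq(sim$lib, fq)
  back <- read_fastq(fq)
  expect_identical(back$reads, sim$lib$reads)
  yml <- file.path(dir, "config.yaml")
  write_sim_config(sim$cfg, yml)
  cfg2 <- read_sim_config(yml)
  expect_equal(cfg2$seed, sim$cfg$seed)
  expect_equal(cfg2$proportions, sim$cfg$proportions)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(proportions = c(0.5, 0.4), n_ribotypes = 2),
               "sum to 1")
  expect_error(sim_config(igs_gc = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(proportions = c(0.5, 0.5, 0.5), n_ribotypes = 2),
               "one entry per ribotype")
})
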