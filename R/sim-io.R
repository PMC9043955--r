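#' Write a read library as FASTQ (Sanger Phred+33)
#'
#' Qualities are constant (default Q35) because the simulator's error model
#' is substitution-only. Paired libraries are written as `_R1`/`_R2` files.
#'
#' @param lib a `read_library`.
#' @param path output FASTQ path (paired: base path; `_R1.fastq` and
#'   `_R2.fastq` suffixes are appended).
#' @param quality constant Phred quality score.
#' @return the path(s) written, invisibly.
#' @export
write_fastq <- function(lib, path, quality = 35L) {
  qchar <- rawToChar(as.raw(quality + 33L))
  write_one <- function(reads, ids, p) {
    qs <- Biostrings::PhredQuality(strrep(qchar, nchar(reads)))
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(reads, ids)), qs)
    Biostrings::writeQualityScaledXStringSet(x, filepath = p)
    p
  }
  if (lib$layout == "paired") {
    base <- sub("\\.(fastq|fq)(\\.gz)?$", "", path)
    p1 <- write_one(lib$reads, paste0(lib$ids, "/1"), paste0(base, "_R1.fastq"))
    p2 <- write_one(lib$reads2, paste0(lib$ids, "/2"), paste0(base, "_R2.fastq"))
    return(invisible(c(p1, p2)))
  }
  invisible(write_one(lib$reads, lib$ids, path))
}

#' Read a FASTQ file into a read library
#'
#' @param path FASTQ file (single-end), or two paths for a paired library.
#' @export
read_fastq <- function(path) {
  x1 <- Biostrings::readDNAStringSet(path[1], format = "fastq")
  reads <- as.character(x1)
  if (length(path) == 2) {
    x2 <- Biostrings::readDNAStringSet(path[2], format = "fastq")
    return(new_read_library(unname(reads), names(reads), "paired",
                            max(nchar(reads)), NA_real_,
                            reads2 = unname(as.character(x2))))
  }
  new_read_library(unname(reads), names(reads), "single",
                   max(nchar(reads)), NA_real_)
}

#' Write a simulation truth set to tab-separated files
#'
#' The main table has one row per ribotype (ribotype_id, sequence,
#' proportion); the array layout (copy_index, ribotype_id, pseudogene) is
#' written alongside with suffix `.layout.tsv`.
#'
#' @param truth a `truth_set`.
#' @param path output TSV path.
#' @export
write_truthset <- function(truth, path) {
  tab <- data.frame(
    ribotype_id = names(truth$ribotype_sequences),
    sequence = unname(truth$ribotype_sequences),
    proportion = unname(truth$true_proportions[names(truth$ribotype_sequences)]),
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth$array_layout)) {
    write.table(truth$array_layout,
                paste0(path, ".layout.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(as.character(truth$seed), paste0(path, ".seed"))
  invisible(path)
}

#' Read a truth set written by [write_truthset()]
#'
#' @param path TSV path used at write time.
#' @export
read_truthset <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  layout_path <- paste0(path, ".layout.tsv")
  layout <- if (file.exists(layout_path)) {
    read.delim(layout_path, stringsAsFactors = FALSE)
  } else NULL
  seed_path <- paste0(path, ".seed")
  seed <- if (file.exists(seed_path)) as.integer(readLines(seed_path)) else NA_integer_
  structure(list(
    ribotype_sequences = setNames(tab$sequence, tab$ribotype_id),
    true_proportions = setNames(tab$proportion, tab$ribotype_id),
    array_layout = layout,
    seed = seed
  ), class = "truth_set")
}

#' Write / read a simulation config as YAML
#'
#' @param config a [sim_config()].
#' @param path YAML path.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals[setdiff(names(vals), character(0))])
}
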