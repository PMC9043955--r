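#' IGS feature report for a ribotype catalog
#'
#' One summary row per sample in the style of per-species survey tables:
#' number of sequences, GC range, IGS length range and intragenomic
#' similarity range.
#'
#' @param catalog a `ribotype_catalog` or character vector of IGS
#'   sequences.
#' @param label sample label.
#' @param opts a [similarity_options()].
#' @return a one-row data.frame: label, n_sequences, gc_min/mean/max,
#'   igs_len_min/max, sim_min/max.
#' @export
igs_feature_report <- function(catalog, label = "sample",
                               opts = similarity_options()) {
  seqs <- if (inherits(catalog, "ribotype_catalog")) {
    catalog$catalog$igs_seq
  } else as.character(catalog)
  if (!length(seqs)) {
    return(data.frame(label = label, n_sequences = 0L,
                      gc_min = NA_real_, gc_mean = NA_real_, gc_max = NA_real_,
                      igs_len_min = NA_integer_, igs_len_max = NA_integer_,
                      sim_min = NA_real_, sim_max = NA_real_,
                      stringsAsFactors = FALSE))
  }
  gc <- vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE)
  sim <- if (length(seqs) >= 2) similarity_range(seqs, opts) else {
    list(min = NA_real_, max = NA_real_)
  }
  data.frame(label = label, n_sequences = length(seqs),
             gc_min = min(gc), gc_mean = round(mean(gc), 1), gc_max = max(gc),
             igs_len_min = min(nchar(seqs)), igs_len_max = max(nchar(seqs)),
             sim_min = round(sim$min, 1), sim_max = round(sim$max, 1),
             stringsAsFactors = FALSE)
}

write_catalog_outputs <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cat_df <- result$catalog$catalog
  ab <- result$abundance
  if (nrow(cat_df)) {
    headers <- sprintf("%s class=%s content=%.4f",
                       ab$id, ab$abundance_class, ab$relative_content)
    write_fasta(setNames(cat_df$igs_seq, headers),
                file.path(output_dir, "ribotype_catalog.fasta"))
    write.table(as.data.frame(ab)[c("id", "assigned_weight",
                                    "relative_content", "abundance_class")],
                file.path(output_dir, "abundance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (nrow(result$catalog$pseudogenes)) {
    write.table(result$catalog$pseudogenes[
      c("id", "igs_seq", "cds_seq", "source_contig")],
      file.path(output_dir, "pseudogenes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(result$features, file.path(output_dir, "igs_features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$motifs, file.path(output_dir, "motif_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$network)) {
    write_network(result$network, file.path(output_dir, "network.graphml"))
    write_cluster_tsv(result$network, result$clusters,
                      file.path(output_dir, "clusters.tsv"))
  }
  jsonlite::write_json(result$report, file.path(output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' Run the full simulate - filter - assemble - call - features - network
#' pipeline
#'
#' Executes every stage in order on a synthetic array generated from
#' `config`; identical config and seed give identical outputs. The run
#' report collects per-stage record counts (reads kept/discarded, contigs,
#' units, ribotypes per class).
#'
#' @param config a [sim_config()] (the seed lives here).
#' @param assembly an [assembly_config()].
#' @param integrity an [integrity_config()].
#' @param classes a [classification_config()].
#' @param probe_length CDS probe length for read filtering.
#' @param output_dir optional directory for TSV/FASTA/GraphML/JSON outputs.
#' @return a list of class `pipeline_result`: truth, read library,
#'   filtered library, contigs, units, catalog, abundance, features,
#'   motifs, duplications, network, clusters, report.
#' @export
run_pipeline <- function(config = sim_config(),
                         assembly = assembly_config(),
                         integrity = integrity_config(),
                         classes = classification_config(),
                         probe_length = 20L,
                         output_dir = NULL) {
  stage <- "simulate"
  result <- tryCatch({
    rs <- generate_ribotype_set(config)
    arr <- build_tandem_array(rs$ribotypes, rs$truth, config,
                              rs$ancestral_cds)
    lib <- simulate_reads(arr$array, config)

    stage <- "filter"
    probes <- make_probes(rs$ancestral_cds, probe_length)
    flib <- suppressMessages(filter_reads(lib, probes))
    fstats <- attr(flib, "filter_stats")

    stage <- "assemble"
    graph <- build_graph(flib, assembly)
    contigs <- prune_and_assemble(graph, assembly)
    resolved <- resolve_repeat_paths(graph, flib, rs$ancestral_cds, assembly,
                                     support_reads = lib)
    units <- extract_repeat_units(resolved, rs$ancestral_cds,
                                  assembly$max_cds_mismatches)

    stage <- "call"
    empty_catalog <- nrow(units) == 0
    if (empty_catalog) {
      warning("no repeat units assembled; catalog is empty")
      catalog <- suppressWarnings(dedup_ribotypes(units, integrity))
      abundance <- NULL
    } else {
      catalog <- dedup_ribotypes(units, integrity)
      catalog <- suppressMessages(drop_unsupported_ribotypes(catalog, flib))
      abundance <- classify_abundance(
        estimate_abundance(catalog, lib), classes)
    }

    stage <- "features"
    features <- igs_feature_report(catalog, label = sprintf("sim_seed%d",
                                                            config$seed))
    motifs <- if (!empty_catalog && nrow(catalog$catalog)) {
      scan_promoter_motifs(catalog$catalog$igs_seq[1])
    } else scan_promoter_motifs("")[0, ]
    duplications <- if (!empty_catalog) {
      calls <- lapply(catalog$catalog$unit_seq, find_tandem_duplication,
                      cds_length = nchar(catalog$cds_consensus))
      calls[!vapply(calls, is.null, logical(1))]
    } else list()

    stage <- "network"
    network <- NULL
    clusters <- NULL
    if (!empty_catalog && nrow(catalog$catalog) >= 2) {
      aln <- align_small(setNames(catalog$catalog$igs_seq,
                                  catalog$catalog$id))
      network <- mj_network(aln)
      clusters <- cluster_by_threshold(network)
    }

    class_counts <- if (!is.null(abundance)) {
      s <- attr(abundance, "summary")
      c(major = s$n_major, minor = s$n_minor, rare = s$n_rare)
    } else c(major = 0L, minor = 0L, rare = 0L)
    report <- list(
      seed = config$seed,
      n_reads = length(lib$reads),
      reads_kept = unname(fstats["kept"]),
      reads_discarded = unname(fstats["discarded"]),
      n_contigs = nrow(contigs),
      n_unit_paths = nrow(resolved),
      n_units = nrow(units),
      n_ribotypes = if (!empty_catalog) nrow(catalog$catalog) else 0L,
      n_pseudogene_records = if (!empty_catalog) nrow(catalog$pseudogenes) else 0L,
      class_counts = as.list(class_counts),
      cumulative_major_minor = if (!is.null(abundance)) {
        attr(abundance, "summary")$cumulative_major_minor
      } else NA_real_
    )
    structure(list(truth = arr$truth, reads = lib, filtered = flib,
                   contigs = contigs, resolved = resolved, units = units,
                   catalog = catalog, abundance = abundance,
                   features = features, motifs = motifs,
                   duplications = duplications, network = network,
                   clusters = clusters, report = report),
              class = "pipeline_result")
  }, error = function(e) {
    if (!is.null(output_dir)) {
      dir.create(file.path(output_dir, "failed"), showWarnings = FALSE,
                 recursive = TRUE)
      writeLines(c(stage, conditionMessage(e)),
                 file.path(output_dir, "failed", "MARKER"))
    }
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(output_dir)) write_catalog_outputs(result, output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("pipeline run (seed %d)\n", r$seed))
  cat(sprintf("  reads: %d simulated, %d kept by probe filter\n",
              r$n_reads, r$reads_kept))
  cat(sprintf("  assembly: %d contigs, %d resolved unit paths, %d units\n",
              r$n_contigs, r$n_unit_paths, r$n_units))
  cat(sprintf("  catalog: %d ribotypes (%d major / %d minor / %d rare), %d pseudogene records\n",
              r$n_ribotypes, r$class_counts$major, r$class_counts$minor,
              r$class_counts$rare, r$n_pseudogene_records))
  invisible(x)
}
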