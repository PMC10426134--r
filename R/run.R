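#' Assemble and validate a run configuration
#'
#' @param genome Reference FASTA path.
#' @param peptide_file Peptide query file (see [parse_peptides()]).
#' @param samples Data frame: `sample_name`, `bam`, and optional `layout`,
#'   `chemistry`, `strandedness` columns (defaults paired_end / forward /
#'   stranded).
#' @param output_dir Report directory (created if absent).
#' @param gtf,ere_bed,vcf Optional annotation / repeat / SNV catalog paths.
#' @param max_mismatch Cap on SNV-licensed mismatches per placement.
#' @param threshold RPHM threshold carried into prioritization (default 8.55).
#' @param em_tol,em_max_iter EM convergence controls.
#' @param stranded_annotation Strict-strand biotype overlap (default
#'   unstranded matching).
#' @param fragment_collapse Count fragments instead of reads.
#' @param cohorts Optional named list of sample-name vectors for per-cohort
#'   biotype summaries.
#' @param threads Worker processes for per-sample counting (results are
#'   independent of the worker count).
#' @return A validated `RunConfig` list.
#' @export
run_config <- function(genome, peptide_file, samples, output_dir,
                       gtf = NULL, ere_bed = NULL, vcf = NULL,
                       max_mismatch = 3L, threshold = 8.55,
                       em_tol = 1e-8, em_max_iter = 10000L,
                       stranded_annotation = FALSE,
                       fragment_collapse = FALSE, cohorts = NULL,
                       threads = 1L) {
  for (p in c(genome, peptide_file, gtf, ere_bed, vcf, samples$bam))
    if (!file.exists(p)) stop("Path does not exist: ", p)
  if (threshold <= 0) stop("threshold must be > 0")
  stopifnot(all(c("sample_name", "bam") %in% names(samples)))
  structure(list(genome = genome, peptide_file = peptide_file,
                 samples = samples, output_dir = output_dir, gtf = gtf,
                 ere_bed = ere_bed, vcf = vcf,
                 max_mismatch = as.integer(max_mismatch),
                 threshold = threshold, em_tol = em_tol,
                 em_max_iter = as.integer(em_max_iter),
                 stranded_annotation = stranded_annotation,
                 fragment_collapse = fragment_collapse, cohorts = cohorts,
                 threads = as.integer(threads)),
            class = "RunConfig")
}

locate_query <- function(q, genome, annotation, snvs, max_mismatch) {
  if (q$mode == "manual") {
    return(resolve_manual(q, genome, snvs))
  }
  locs <- locate_set(q$mcs_set[[1]], genome, snvs, max_mismatch)
  if (!is.null(annotation)) {
    spliced <- do.call(rbind, lapply(q$mcs_set[[1]], locate_spliced,
                                     genome = genome,
                                     annotation_index = annotation,
                                     snv_catalog = snvs,
                                     max_mismatch = max_mismatch))
    locs <- sort_locations(rbind(locs, spliced))
  }
  locs
}

#' Run the full expression and biotype pipeline
#'
#' Expands every query into its coding-sequence pool, finds all perfect
#' genomic placements (contiguous, spliced across annotated junctions, and
#' manual), counts exactly-spanning primary reads in every sample, normalizes
#' to RPHM/log-RPHM, and (when annotations are supplied) attributes biotypes
#' by EM.  Reports are written to the output directory: `expression.tsv`,
#' `per_location.tsv`, `locations.bed`, `mcs_pool.fastq`,
#' `biotype_report.tsv` (+ per-cohort files) and `run_log.txt`.  Reruns with
#' the same configuration are byte-identical.
#'
#' @param config A `RunConfig`.
#' @return List with `queries`, `locations`, `records`, `per_location`,
#'   `biotype` (or `NULL`), `log` (invisibly returned components are also on
#'   disk).
#' @export
run_query <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  queries <- parse_peptides(config$peptide_file)
  queries <- expand_queries(queries)
  note("queries: ", nrow(queries))

  genome <- load_genome(config$genome)
  annotation <- if (!is.null(config$gtf))
    load_annotations(config$gtf, config$ere_bed) else NULL
  snvs <- if (!is.null(config$vcf)) load_snvs(config$vcf) else NULL

  emit_mcs_fastq(queries, file.path(config$output_dir, "mcs_pool.fastq"))
  note("mcs pool size: ", sum(vapply(queries$mcs_set, length, integer(1))))

  peptide_locations <- lapply(seq_len(nrow(queries)), function(i)
    locate_query(queries[i, , drop = FALSE], genome, annotation, snvs,
                 config$max_mismatch))
  names(peptide_locations) <- queries$name
  n_loc <- vapply(peptide_locations, nrow, integer(1))
  note("queries with at least one location: ", sum(n_loc > 0L), " of ",
       nrow(queries))

  all_locs <- do.call(rbind, lapply(names(peptide_locations), function(p) {
    l <- peptide_locations[[p]]
    if (nrow(l)) cbind(data.frame(peptide = p, stringsAsFactors = FALSE), l)
    else NULL
  }))
  if (!is.null(all_locs))
    locations_to_bed(all_locs, file.path(config$output_dir, "locations.bed"),
                     names = paste(all_locs$peptide, all_locs$loc_id, sep = "::"))

  count_one_sample <- function(s) {
    count_samples(peptide_locations, config$samples[s, , drop = FALSE],
                  fragment_collapse = config$fragment_collapse)
  }
  per_sample <- if (config$threads > 1L) {
    parallel::mclapply(seq_len(nrow(config$samples)), count_one_sample,
                       mc.cores = config$threads)
  } else {
    lapply(seq_len(nrow(config$samples)), count_one_sample)
  }
  records <- do.call(rbind, lapply(per_sample, `[[`, "records"))
  per_location <- do.call(rbind, lapply(per_sample, function(x) x$per_location))
  note("samples counted: ", nrow(config$samples))
  note("queries with zero locations reported with status no_location: ",
       sum(n_loc == 0L))

  exp_out <- records[, c("peptide", "sample_name", "tr", "rphm", "log_rphm",
                         "n_locations", "no_location")]
  exp_out$rphm <- round(exp_out$rphm, 4)
  exp_out$log_rphm <- round(exp_out$log_rphm, 4)
  utils::write.table(exp_out, file.path(config$output_dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(per_location)) {
    pl_out <- per_location[, c("peptide", "sample_name", "loc_id", "chrom",
                               "strand", "start", "end", "n_blocks",
                               "snv_pos", "snv_alt", "spliced", "count")]
    utils::write.table(pl_out, file.path(config$output_dir, "per_location.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  biotype <- NULL
  if (!is.null(annotation) && !is.null(all_locs)) {
    biotyped <- biotype_classify(
      cbind(all_locs), annotation, stranded = config$stranded_annotation)
    counts_long <- per_location[, c("peptide", "loc_id", "sample_name", "count")]
    total_reads <- sum(counts_long$count)
    if (total_reads > 0) {
      biotype <- biotype_profile(biotyped, counts_long,
                                 cohorts = config$cohorts,
                                 tol = config$em_tol,
                                 max_iter = config$em_max_iter)
      if (!is.null(biotype$global)) {
        g <- biotype$global
        num <- vapply(g, is.numeric, logical(1))
        g[num] <- round(g[num], 4)
        g <- merge(g, biotype$best, by = "peptide")
        utils::write.table(g, file.path(config$output_dir, "biotype_report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      note("biotype EM: ", biotype$em$iterations, " iteration(s), converged: ",
           biotype$em$converged)
    } else {
      note("biotype EM skipped: no reads at any location")
    }
  }

  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  invisible(list(queries = queries, locations = peptide_locations,
                 records = records, per_location = per_location,
                 biotype = biotype, log = log_lines))
}
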