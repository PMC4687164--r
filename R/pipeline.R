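#' Audit configuration
#'
#' Collects the inputs and thresholds of a full audit run. Inputs may be
#' in-memory objects ([genome_record()], feature tables, read data.frames /
#' alignment data.frames) or file paths (FASTA / GFF3 / FASTQ / SAM); paths
#' are validated at construction time.
#'
#' @param reference reference genome (GenomeRecord or FASTA path).
#' @param annotation its CDS annotation (features or GFF3 path).
#' @param reads paired reads (data.frame, or c(fastq1, fastq2) paths);
#'   mutually exclusive with \code{sam}.
#' @param sam pre-computed alignments (data.frame or SAM path).
#' @param related_genome,related_annotation optional related genome for
#'   cross-validation.
#' @param min_depth,min_alt_fraction caller thresholds.
#' @param breadth_min_depth CDS-breadth threshold (default 40).
#' @param flank cross-validation window flank (default 250 bp).
#' @param min_combined annotation-transfer acceptance threshold.
#' @param out_dir optional report directory.
#' @param seed integer seed (mapper is deterministic; recorded for
#'   provenance and derived streams).
#' @param verbose log stage progress.
#' @return an \code{AuditConfig} list.
#' @export
audit_config <- function(reference, annotation = NULL, reads = NULL,
                         sam = NULL, related_genome = NULL,
                         related_annotation = NULL, min_depth = 10L,
                         min_alt_fraction = 0.8, breadth_min_depth = 40L,
                         flank = 250L, min_combined = 0.25, out_dir = NULL,
                         seed = 1L, verbose = TRUE) {
  chk_path <- function(x, what) {
    if (is.character(x) && !all(file.exists(x)))
      stop("audit_config: ", what, " path does not exist: ",
           paste(x[!file.exists(x)], collapse = ", "))
    x
  }
  if (is.null(reads) && is.null(sam))
    stop("audit_config: provide reads or sam")
  if (!is.null(reads) && !is.null(sam))
    stop("audit_config: reads and sam are mutually exclusive")
  if (min_alt_fraction <= 0.5)
    stop("audit_config: min_alt_fraction must exceed 0.5")
  structure(list(reference = chk_path(reference, "reference"),
                 annotation = chk_path(annotation, "annotation"),
                 reads = chk_path(reads, "reads"), sam = chk_path(sam, "sam"),
                 related_genome = chk_path(related_genome, "related_genome"),
                 related_annotation = chk_path(related_annotation,
                                               "related_annotation"),
                 min_depth = as.integer(min_depth),
                 min_alt_fraction = min_alt_fraction,
                 breadth_min_depth = as.integer(breadth_min_depth),
                 flank = as.integer(flank), min_combined = min_combined,
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "AuditConfig")
}

#' Read an audit configuration from YAML
#'
#' @param path YAML file whose keys mirror the [audit_config()] arguments
#'   (paths relative to the YAML file's directory).
#' @return an \code{AuditConfig}.
#' @export
read_audit_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  do.call(audit_config, c(
    list(reference = rel(y$reference), annotation = rel(y$annotation),
         reads = rel(unlist(y$reads)), sam = rel(y$sam),
         related_genome = rel(y$related_genome),
         related_annotation = rel(y$related_annotation)),
    y[setdiff(names(y), c("reference", "annotation", "reads", "sam",
                          "related_genome", "related_annotation"))]))
}

load_genome_input <- function(x, circular = FALSE) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "GenomeRecord")) return(x)
  read_fasta(x, circular = circular)[[1]]
}

load_features_input <- function(x) {
  if (is.null(x)) return(empty_features())
  if (is.data.frame(x)) return(x)
  read_gff3(x)
}

#' Run the full genome audit
#'
#' Orchestrates mapping (or SAM import), pileup construction, consensus
#' discrepancy calling with left-normalization, homopolymer and region
#' annotation, the large-INDEL screen, correction with annotation liftover,
#' coding-impact classification, optional cross-validation against a related
#' genome, coverage statistics, and report writing.
#'
#' @param config an [audit_config()].
#' @return a \code{GenomeAudit} bundle: the inputs, alignments, pileup,
#'   annotated discrepancies, summary, corrected genome + map, lifted
#'   features, impacts, cross-validation table, coverage summary and depth.
#' @export
run_audit <- function(config) {
  stopifnot(inherits(config, "AuditConfig"))
  v <- config$verbose
  set.seed(config$seed)
  ga_log("audit start (seed ", config$seed, ")", verbose = v)
  reference <- load_genome_input(config$reference)
  features <- load_features_input(config$annotation)
  if (nrow(features) && any(features$end > reference$length))
    stop("run_audit: annotation exceeds reference bounds [stage: inputs]")
  if (!is.null(config$sam)) {
    alignments <- if (is.data.frame(config$sam)) config$sam else
      read_sam(config$sam, reference)
    ga_log("imported ", nrow(alignments), " alignments", verbose = v)
  } else {
    reads <- if (is.data.frame(config$reads)) config$reads else
      read_fastq(config$reads[1], if (length(config$reads) > 1)
        config$reads[2] else NULL)
    ga_log("mapping ", nrow(reads), " fragments", verbose = v)
    index <- build_index(reference)
    alignments <- map_reads(reads, index, verbose = v)
    ga_log("mapped ", nrow(alignments), " reads", verbose = v)
  }
  pileup <- build_pileup(alignments, reference)
  ga_log("pileup built; mean depth ", round(mean(pileup$depth), 1),
         verbose = v)
  disc <- call_discrepancies(pileup, reference, config$min_depth,
                             config$min_alt_fraction)
  disc <- annotate_homopolymers(disc, reference)
  disc <- annotate_regions(disc, features)
  ga_log(nrow(disc), " discrepancies called", verbose = v)
  large <- screen_large_indels(pileup)
  summary <- summarize_discrepancies(disc)
  corr <- apply_corrections(reference, disc)
  lifted <- lift_features(features, corr$map)
  if (nrow(lifted)) lifted$genome_id <- corr$genome$id
  impacts <- assess_impact(reference, corr$genome, features, disc)
  cv <- NULL
  if (!is.null(config$related_genome)) {
    related <- load_genome_input(config$related_genome)
    related_feats <- load_features_input(config$related_annotation)
    ga_log("cross-validating against '", related$id, "'", verbose = v)
    cv <- cross_validate(disc, reference, related, related_feats, impacts,
                         flank = config$flank)
  }
  depth <- pileup$depth
  coverage <- cds_breadth(depth, features, config$breadth_min_depth,
                          alignments)
  verdicts <- if (!is.null(cv)) table(factor(cv$verdict,
    levels = c("confirms_corrected", "confirms_reference", "neither",
               "not_found"))) else NULL
  audit <- structure(list(
    reference = reference, features = features, alignments = alignments,
    pileup = pileup, discrepancies = disc, summary = summary,
    large_indels = large, corrected = corr$genome, map = corr$map,
    lifted_features = lifted, impacts = impacts, crossval = cv,
    verdict_counts = verdicts, coverage = coverage, depth = depth,
    config = config, seed = config$seed,
    version = as.character(utils::packageVersion("genaudit"))),
    class = "GenomeAudit")
  if (!is.null(config$out_dir)) {
    write_reports(audit, config$out_dir)
    ga_log("reports written to ", config$out_dir, verbose = v)
  }
  ga_log("audit complete", verbose = v)
  audit
}

#' @export
print.GenomeAudit <- function(x, ...) {
  cat(sprintf("Genome audit of '%s' (%d bp -> %d bp corrected)\n",
              x$reference$id, x$reference$length, x$corrected$length))
  print(x$summary)
  if (!is.null(x$verdict_counts)) {
    vc <- x$verdict_counts
    cat(sprintf("Cross-validation: %d confirm corrected, %d confirm reference, %d neither, %d not found\n",
                vc[["confirms_corrected"]], vc[["confirms_reference"]],
                vc[["neither"]], vc[["not_found"]]))
  }
  invisible(x)
}

#' Write a complete synthetic dataset to disk
#'
#' Convenience wrapper over [simulate_genome()], [corrupt_assembly()] and
#' [simulate_reads()] that writes \code{genome.fasta}, \code{assembly.fasta},
#' \code{annotation.gff3}, \code{truth.tsv}, \code{reads_1.fastq} and
#' \code{reads_2.fastq}.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory.
#' @return invisibly, the in-memory bundle (genome, features, assembly,
#'   truth, reads).
#' @export
write_simulation <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  cor <- corrupt_assembly(sim$genome, sim$features, config)
  reads <- simulate_reads(sim$genome, config)
  write_fasta(sim$genome, file.path(out_dir, "genome.fasta"))
  write_fasta(cor$assembly, file.path(out_dir, "assembly.fasta"))
  write_gff3(cor$features, file.path(out_dir, "annotation.gff3"))
  write.table(cor$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_read_pairs(reads, file.path(out_dir, "reads_1.fastq"),
                   file.path(out_dir, "reads_2.fastq"))
  invisible(list(genome = sim$genome, features = sim$features,
                 assembly = cor$assembly, truth = cor$truth,
                 assembly_features = cor$features, reads = reads))
}
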